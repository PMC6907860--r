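Package: bulkdecon
Title: Complete Deconvolution of Bulk RNA-Seq by Latent Dirichlet
    Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference-free ("complete") deconvolution of bulk RNA-Seq
    read counts. From a genes-by-samples count matrix alone, the package
    simultaneously estimates cell-type-specific gene expression profiles
    and sample-specific cell-type proportions using a collapsed Gibbs
    sampler for an extended latent Dirichlet allocation model with
    effective-gene-length and per-cell-type RNA-yield (cell size)
    corrections.  It selects the number of cell types by maximizing the
    collapsed log posterior over a grid, matches the anonymous estimated
    cell types to named reference expression profiles by optimal
    one-to-one (Hungarian) assignment on Pearson or Kullback-Leibler
    similarity, supports a count-dilution speedup and a quasi-unsupervised
    mode that appends pure cell-line profiles as extra samples, and ships
    a generative simulator that produces benchmark mixtures with known
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tools,
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
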