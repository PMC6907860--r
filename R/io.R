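# Readers and writers for the tabular interchange formats, plus the two
# count-matrix preprocessing steps (dilution and the quasi-unsupervised
# append of pure profiles).  All tables are plain TSV/CSV with genes as
# rows; sparse counts may come as MatrixMarket .mtx with two sidecar id
# files (<stem>_genes.txt, <stem>_samples.txt, one id per line).

.format_from_path <- function(path) {
  switch(tolower(tools::file_ext(path)),
         tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
         stop(sprintf("cannot infer format from '%s'; pass format=", path),
              call. = FALSE))
}

.mtx_sidecars <- function(path) {
  stem <- sub("\\.mtx$", "", path)
  c(genes = paste0(stem, "_genes.txt"), samples = paste0(stem, "_samples.txt"))
}

#' Read a genes x samples count matrix
#'
#' TSV/CSV files must have a header row and gene ids in the first column;
#' MatrixMarket files need the two sidecar id files described above.
#' Inputs that look transposed (far more columns than rows) are rejected
#' rather than silently flipped.  Non-integer values are an error unless
#' `allow_rounding = TRUE`, in which case they are rounded half away from
#' zero and the total mass changed is reported.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"mtx"`.
#' @param allow_rounding round non-integer values instead of erroring.
#' @return validated integer count matrix with gene/sample dimnames.
#' @export
read_count_matrix <- function(path, format = "auto", allow_rounding = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") format <- .format_from_path(path)
  if (format == "mtx") {
    side <- .mtx_sidecars(path)
    if (!all(file.exists(side)))
      stop(sprintf("missing sidecar id files: %s",
                   paste(side[!file.exists(side)], collapse = ", ")),
           call. = FALSE)
    mat <- as.matrix(Matrix::readMM(path))
    rownames(mat) <- readLines(side["genes"])
    colnames(mat) <- readLines(side["samples"])
  } else {
    df <- if (format == "csv") utils::read.csv(path, check.names = FALSE)
          else read.delim(path, check.names = FALSE)
    if (ncol(df) < 2L)
      stop(sprintf("%s: need a gene id column plus >= 1 sample column", path),
           call. = FALSE)
    ids <- as.character(df[[1]])
    dup <- ids[duplicated(ids)]
    if (length(dup) > 0L)
      stop(sprintf("%s: duplicate gene ids (first at line %d): %s", path,
                   which(duplicated(ids))[1] + 1L,
                   paste(utils::head(unique(dup), 3), collapse = ", ")),
           call. = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(mat))
      stop(sprintf("%s: non-numeric values in the sample columns", path),
           call. = FALSE)
    rownames(mat) <- ids
  }
  if (ncol(mat) > 10L * nrow(mat))
    stop("input has many more samples than genes; it looks transposed (genes must be rows)",
         call. = FALSE)
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 rownames(mat)[bad[1]], colnames(mat)[bad[2]]), call. = FALSE)
  }
  if (!all(.is_wholenumber(mat))) {
    if (!allow_rounding)
      stop("non-integer counts; re-export raw counts, use allow_rounding = TRUE, or apply dilute_counts() to integers only",
           call. = FALSE)
    rounded <- .round_half_away(mat)
    message(sprintf("rounded non-integer counts: total mass changed by %.3f",
                    sum(abs(rounded - mat))))
    mat <- rounded
  }
  storage.mode(mat) <- "integer"
  .validate_counts(mat)
}

#' Write a count matrix (TSV/CSV/MTX)
#'
#' Round-trip companion of [read_count_matrix()].
#'
#' @param counts genes x samples integer matrix.
#' @param path output path; the extension selects the format.
#' @export
write_count_matrix <- function(counts, path) {
  counts <- .validate_counts(counts)
  format <- .format_from_path(path)
  if (format == "mtx") {
    side <- .mtx_sidecars(path)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), side["genes"])
    writeLines(colnames(counts), side["samples"])
  } else {
    df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
    write.table(df, path, sep = if (format == "csv") "," else "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Dilute read counts to speed up sampling
#'
#' Divides every entry by `factor` and rounds half away from zero, shrinking
#' the number of read tokens (hence per-sweep cost) roughly `factor`-fold at
#' a modest accuracy cost.  Zeros stay zero.
#'
#' @param counts integer count matrix.
#' @param factor dilution factor >= 1 (1 = identity).
#' @return diluted integer count matrix.
#' @export
dilute_counts <- function(counts, factor) {
  counts <- .validate_counts(counts)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1)
    stop("dilution factor must be a single number >= 1", call. = FALSE)
  if (factor == 1) return(counts)
  out <- .round_half_away(counts / factor)
  storage.mode(out) <- "integer"
  message(sprintf("dilution by %g: total reads %d -> %d", factor,
                  sum(counts), sum(out)))
  out
}

#' Append pure cell-line profiles as extra samples (quasi-unsupervised mode)
#'
#' Column-concatenates pure-profile libraries onto the bulk matrix so the
#' factorization is guided toward the appended types.  The sampler treats
#' the extra columns like any other sample; the returned matrix carries a
#' `sample_type` attribute (`"bulk"`/`"pure"`) so downstream output can
#' separate real-sample proportion estimates from the appended columns.
#'
#' @param bulk genes x M bulk count matrix.
#' @param pure genes x W pure-profile count matrix on the same gene registry.
#' @return genes x (M + W) count matrix with attribute `sample_type`.
#' @export
append_pure_profiles <- function(bulk, pure) {
  bulk <- .validate_counts(bulk)
  if (is.null(pure) || ncol(pure) == 0L) {
    attr(bulk, "sample_type") <- rep("bulk", ncol(bulk))
    return(bulk)
  }
  pure <- .validate_counts(pure)
  if (!identical(rownames(bulk), rownames(pure))) {
    if (setequal(rownames(bulk), rownames(pure))) {
      pure <- pure[rownames(bulk), , drop = FALSE]
    } else {
      only_b <- setdiff(rownames(bulk), rownames(pure))
      only_p <- setdiff(rownames(pure), rownames(bulk))
      stop(sprintf("gene registries differ: %d genes only in bulk (e.g. %s), %d only in pure (e.g. %s)",
                   length(only_b), paste(utils::head(only_b, 3), collapse = ", "),
                   length(only_p), paste(utils::head(only_p, 3), collapse = ", ")),
           call. = FALSE)
    }
  }
  out <- cbind(bulk, pure)
  attr(out, "sample_type") <- c(rep("bulk", ncol(bulk)), rep("pure", ncol(pure)))
  out
}

#' Read a per-gene length table
#'
#' Two-column TSV (gene id, length in bases) with a header.  The table is
#' intersected with the analysis gene registry and returned in registry
#' order; genes missing beyond `max_missing_frac` are an error, otherwise
#' missing genes get the median length with a message.
#'
#' @param path TSV path.
#' @param genes character vector, the frozen gene registry (row order of the
#'   count matrix).
#' @param read_length sequenced read length in bases (default 100).
#' @param max_missing_frac tolerated fraction of registry genes absent from
#'   the table (default 0.05).
#' @return a [gene_length_table()] in registry order.
#' @export
read_gene_lengths <- function(path, genes, read_length = 100L,
                              max_missing_frac = 0.05) {
  df <- read.delim(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("length table needs two columns: gene id, length",
                          call. = FALSE)
  len <- setNames(as.numeric(df[[2]]), as.character(df[[1]]))
  if (any(is.na(len)) || any(len <= 0))
    stop(sprintf("%s: lengths must be positive numbers", path), call. = FALSE)
  missing <- setdiff(genes, names(len))
  if (length(missing) > max_missing_frac * length(genes))
    stop(sprintf("%d of %d registry genes missing from %s (limit %.0f%%)",
                 length(missing), length(genes), path,
                 100 * max_missing_frac), call. = FALSE)
  extra <- length(setdiff(names(len), genes))
  if (extra > 0L)
    message(sprintf("dropped %d length entries not in the gene registry", extra))
  out <- len[genes]
  if (length(missing) > 0L) {
    message(sprintf("imputed median length for %d missing genes", length(missing)))
    out[missing] <- stats::median(len)
  }
  names(out) <- genes
  gene_length_table(round(out), read_length = read_length)
}

#' Read a reference GEP panel
#'
#' Genes x named-cell-types TSV (gene ids in the first column).  Returned on
#' the intersection with the gene registry, in registry order; subset the
#' estimated GEPs to `rownames()` of the result before computing
#' similarities.
#'
#' @inheritParams read_gene_lengths
#' @return numeric matrix with named columns.
#' @export
read_reference_geps <- function(path, genes, max_missing_frac = 0.05) {
  df <- read.delim(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("reference panel needs gene ids plus >= 1 type column",
                          call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate gene ids in reference panel", call. = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(mat)))
    stop("duplicate reference type names", call. = FALSE)
  rownames(mat) <- ids
  keep <- intersect(genes, ids)
  if (length(keep) == 0L)
    stop("reference panel and count registry share no genes", call. = FALSE)
  missing <- length(genes) - length(keep)
  if (missing > max_missing_frac * length(genes))
    stop(sprintf("%d of %d registry genes missing from the reference panel (limit %.0f%%)",
                 missing, length(genes), 100 * max_missing_frac), call. = FALSE)
  if (missing > 0L)
    message(sprintf("reference panel covers %d of %d registry genes",
                    length(keep), length(genes)))
  mat[keep, , drop = FALSE]
}

#' Write deconvolution results to a directory
#'
#' Emits `theta_cell.tsv`, `theta_rna.tsv` (types x samples),
#' `gep_expression.tsv`, `gep_rpkm.tsv` (genes x types; the RPKM table
#' rescales each estimated profile to a nominal one-million-read library for
#' comparability with RPKM-normalized references), `logposterior.tsv` and
#' `assignment.tsv` when available, and `run_manifest.txt` recording the
#' settings and seed.
#'
#' @param fit a `decon_fit`.
#' @param outdir output directory (created if needed).
#' @param lengths optional [gene_length_table()]; required for the RPKM
#'   table.
#' @param assignment optional `decon_assignment` from [threshold_matches()].
#' @param selection optional `decon_model_selection`.
#' @param config optional named list echoed into the manifest.
#' @return invisibly, the paths written.
#' @export
write_results <- function(fit, outdir, lengths = NULL, assignment = NULL,
                          selection = NULL, config = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wt <- function(x, file, rowlab) {
    p <- file.path(outdir, file)
    df <- data.frame(rownames(x), x, check.names = FALSE)
    colnames(df)[1] <- rowlab
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(paths, wt(fit$theta_cell, "theta_cell.tsv", "cell_type"),
             wt(fit$theta_rna, "theta_rna.tsv", "cell_type"),
             wt(fit$phi_expression, "gep_expression.tsv", "gene_id"))
  if (!is.null(lengths))
    paths <- c(paths, wt(rpkm(fit$phi_sampling * 1e6, lengths),
                         "gep_rpkm.tsv", "gene_id"))
  if (!is.null(assignment)) {
    p <- file.path(outdir, "assignment.tsv")
    write.table(as.data.frame(assignment), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(selection)) {
    p <- file.path(outdir, "logposterior.tsv")
    write.table(data.frame(T = selection$t_grid,
                           log_posterior = selection$log_posterior),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- c(
    sprintf("bulkdecon_version: %s", as.character(packageVersion("bulkdecon"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("T: %d", fit$T),
    sprintf("alpha: %s", paste(signif(unique(fit$alpha), 6), collapse = ",")),
    sprintf("beta: %s", paste(signif(unique(fit$beta), 6), collapse = ",")),
    sprintf("eta: %s", paste(signif(fit$eta, 6), collapse = ",")),
    sprintf("n_sweeps: %d", fit$n_sweeps),
    sprintf("burn_in: %d", fit$burn_in),
    sprintf("average: %s", fit$average),
    sprintf("seed: %s", format(fit$seed)),
    vapply(names(config), function(k)
      sprintf("%s: %s", k, paste(format(config[[k]]), collapse = ",")),
      character(1)))
  mp <- file.path(outdir, "run_manifest.txt")
  writeLines(manifest, mp)
  invisible(c(paths, mp))
}
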