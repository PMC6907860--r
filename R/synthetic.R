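# Ground-truth simulator: executes the model's own generative process
# (Dirichlet GEPs and proportions; reads drawn by choosing a cell type from
# the RNA-scale proportions, then a gene from the length-weighted GEP) so
# that inference can be scored against a known answer.

.rdirichlet <- function(n, shape) {
  k <- length(shape)
  x <- matrix(rgamma(n * k, shape = shape), nrow = k)
  sweep(x, 2, colSums(x), "/")
}

#' Draw cell-type gene expression profiles
#'
#' T independent Dirichlet(beta) draws over G genes, optionally pushed apart
#' or pulled together to tune inter-type correlation:
#' * `separation > 0` mixes in weight `separation` of a disjoint
#'   high-expression marker block per type (lowers correlation);
#' * `separation < 0` mixes in weight `|separation|` of one shared baseline
#'   profile (raises correlation, the "highly correlated GEPs" stress
#'   regime);
#' * `separation = 0` (default) leaves the draws independent, which at
#'   G >= 1000 already gives near-zero pairwise correlation.
#'
#' @param G number of genes (>= T).
#' @param T number of cell types.
#' @param beta Dirichlet concentration (scalar or length-G).
#' @param seed integer seed.
#' @param separation number in \[-1, 1\], see above.
#' @return G x T matrix, columns on the simplex (expression scale).
#' @export
sample_geps <- function(G, T, beta = 0.5, seed = 1L, separation = 0) {
  if (G < T || T < 1) stop("need G >= T >= 1", call. = FALSE)
  if (abs(separation) > 1) stop("separation must lie in [-1, 1]", call. = FALSE)
  beta <- .expand_hyper(beta, G, "beta")
  set.seed(seed)
  phi <- .rdirichlet(T, beta)
  if (separation > 0) {
    block <- floor(G / T)
    markers <- matrix(0, G, T)
    for (t in seq_len(T))
      markers[((t - 1) * block + 1):(t * block), t] <- 1 / block
    phi <- (1 - separation) * phi + separation * markers
  } else if (separation < 0) {
    common <- .rdirichlet(1, beta)[, 1]
    phi <- (1 + separation) * phi + (-separation) * common
  }
  rownames(phi) <- paste0("gene_", seq_len(G))
  colnames(phi) <- paste0("true_", seq_len(T))
  phi
}

#' Draw sample-specific cell-type proportions
#'
#' M independent Dirichlet(alpha) draws over T cell types (cell scale).
#'
#' @param M number of samples.
#' @param T number of cell types.
#' @param alpha Dirichlet concentration (scalar or length-T); small values
#'   give samples dominated by few types, large values near-equal mixtures.
#' @param seed integer seed.
#' @return T x M matrix, columns on the simplex.
#' @export
sample_proportions <- function(M, T, alpha = 1, seed = 1L) {
  if (M < 1 || T < 1) stop("need M >= 1 and T >= 1", call. = FALSE)
  alpha <- .expand_hyper(alpha, T, "alpha")
  set.seed(seed)
  theta <- .rdirichlet(M, alpha)
  rownames(theta) <- paste0("true_", seq_len(T))
  colnames(theta) <- paste0("sample_", seq_len(M))
  theta
}

.sample_gene_lengths <- function(G, seed, read_length = 100L) {
  set.seed(seed)
  raw <- round(10^runif(G, log10(500), 4))
  names(raw) <- paste0("gene_", seq_len(G))
  gene_length_table(raw, read_length = read_length)
}

.make_truth <- function(phi, theta_cell, eta, lengths, depths, seed, scenario) {
  theta_rna <- apply(theta_cell, 2, cell_to_rna_proportions, eta = eta)
  theta_rna <- matrix(theta_rna, nrow = nrow(theta_cell),
                      dimnames = dimnames(theta_cell))
  structure(list(phi = phi, theta_cell = theta_cell, theta_rna = theta_rna,
                 eta = eta, lengths = lengths, depths = depths,
                 seed = seed, scenario = scenario),
            class = "decon_truth")
}

#' Simulate bulk read counts from a ground truth
#'
#' For sample i the generative process converts the cell-scale proportions
#' to RNA scale with `eta` and the expression-scale GEPs to sampling scale
#' with the effective lengths, then draws each of the `N_i` reads by
#' choosing a cell type and then a gene.  Because the per-read cell type is
#' marginalized out in the aggregated counts, the default fast path draws a
#' single multinomial per sample from the mixture gene distribution
#' `Phi_i = sum_t theta_rna[t, i] * phi_sampling[, t]`; `method = "per_read"`
#' runs the explicit two-stage draw (useful for validating the equivalence,
#' quadratic in reads so keep N small).
#'
#' @param truth a `decon_truth` from [make_benchmark()] or assembled
#'   manually.
#' @param method `"multinomial"` (fast marginalized path, default) or
#'   `"per_read"` (explicit type-then-gene draws).
#' @return genes x samples integer count matrix.
#' @export
simulate_counts <- function(truth, method = c("multinomial", "per_read")) {
  method <- match.arg(method)
  phi_s <- apply(truth$phi, 2, phi_to_sampling,
                 eff_lengths = truth$lengths$effective_length)
  phi_s <- matrix(phi_s, nrow = nrow(truth$phi), dimnames = dimnames(truth$phi))
  M <- ncol(truth$theta_cell)
  G <- nrow(truth$phi)
  set.seed(truth$seed + 1)
  counts <- matrix(0L, G, M)
  for (i in seq_len(M)) {
    if (method == "multinomial") {
      mix <- as.vector(phi_s %*% truth$theta_rna[, i])
      counts[, i] <- rmultinom(1, truth$depths[i], mix)
    } else {
      types <- sample.int(nrow(truth$theta_rna), truth$depths[i],
                          replace = TRUE, prob = truth$theta_rna[, i])
      genes <- vapply(types, function(t)
        sample.int(G, 1L, prob = phi_s[, t]), integer(1))
      counts[, i] <- tabulate(genes, nbins = G)
    }
  }
  dimnames(counts) <- list(rownames(truth$phi), colnames(truth$theta_cell))
  counts
}

# deterministic proportion grid used by the four-type mixture design:
# all 24 orderings of (10, 20, 30, 40)% plus rotations of (70, 10, 10, 10)%
# and (40, 40, 10, 10)% -- 32 samples spanning the simplex
.four_type_grid <- function() {
  perms <- function(v) {
    if (length(v) == 1L) return(matrix(v))
    out <- NULL
    for (k in seq_along(v))
      out <- rbind(out, cbind(v[k], perms(v[-k])))
    out
  }
  rot <- function(v) t(vapply(0:3, function(s) v[(seq_len(4) - 1 + s) %% 4 + 1],
                              numeric(4)))
  t(rbind(perms(c(0.1, 0.2, 0.3, 0.4)),
          rot(c(0.7, 0.1, 0.1, 0.1)),
          rot(c(0.4, 0.4, 0.1, 0.1))))
}

#' Benchmark scenarios with known ground truth
#'
#' Ready-made simulation designs:
#' * `six_type_40`: 40 samples, 6 cell types, Dirichlet(1) proportions, and
#'   unequal RNA yields `eta = (1, 1, 1, 3, 1, 2)` - two types produce 3x and
#'   2x the RNA of the others, so RNA proportions are biased away from cell
#'   proportions and the `eta` correction has a known right answer.
#' * `four_type_32`: 32 samples mixed on a fixed proportion grid over 4 cell
#'   types (all orderings of 10/20/30/40% plus dominated and two-way-split
#'   designs), equal `eta`.
#' * `pure_panel`: one pure sample per cell type (one-hot proportions),
#'   default 8 types; the estimated proportion of the matched type should
#'   approach 100%.
#' * `deep_correlated`: 20 bulk samples over (default) 8 cell types whose
#'   GEPs share an 80% common baseline (highly correlated, the hard regime);
#'   also returns one pure profile library per type in `$pure_counts` for
#'   the quasi-unsupervised strategy ([append_pure_profiles()]).
#'
#' @param scenario one of `"six_type_40"`, `"four_type_32"`, `"pure_panel"`,
#'   `"deep_correlated"`.
#' @param seed integer seed; everything downstream is deterministic in it.
#' @param G number of genes (default 1000).
#' @param depth reads per sample, `N_i` (default 1e5).
#' @param T number of cell types for the scenarios where it is free
#'   (`pure_panel`, `deep_correlated`); fixed at 6 and 4 for the first two.
#' @return list with `counts` (genes x samples integer matrix), `truth`
#'   (a `decon_truth`), and for `deep_correlated` also `pure_counts`.
#' @export
make_benchmark <- function(scenario = c("six_type_40", "four_type_32",
                                        "pure_panel", "deep_correlated"),
                           seed = 1L, G = 1000L, depth = 1e5, T = NULL) {
  scenario <- match.arg(scenario)
  lengths <- .sample_gene_lengths(G, seed + 17)
  out <- switch(scenario,
    six_type_40 = {
      Tn <- 6L
      phi <- sample_geps(G, Tn, beta = 0.5, seed = seed)
      theta <- sample_proportions(40L, Tn, alpha = 1, seed = seed + 1)
      eta <- c(1, 1, 1, 3, 1, 2)
      truth <- .make_truth(phi, theta, eta, lengths,
                           rep(as.integer(depth), 40L), seed, scenario)
      list(counts = simulate_counts(truth), truth = truth)
    },
    four_type_32 = {
      Tn <- 4L
      phi <- sample_geps(G, Tn, beta = 0.5, seed = seed)
      theta <- .four_type_grid()
      dimnames(theta) <- list(paste0("true_", seq_len(Tn)),
                              paste0("sample_", seq_len(ncol(theta))))
      truth <- .make_truth(phi, theta, rep(1, Tn), lengths,
                           rep(as.integer(depth), ncol(theta)), seed, scenario)
      list(counts = simulate_counts(truth), truth = truth)
    },
    pure_panel = {
      Tn <- if (is.null(T)) 8L else as.integer(T)
      phi <- sample_geps(G, Tn, beta = 0.5, seed = seed)
      theta <- diag(Tn)
      dimnames(theta) <- list(paste0("true_", seq_len(Tn)),
                              paste0("sample_", seq_len(Tn)))
      truth <- .make_truth(phi, theta, rep(1, Tn), lengths,
                           rep(as.integer(depth), Tn), seed, scenario)
      list(counts = simulate_counts(truth), truth = truth)
    },
    deep_correlated = {
      Tn <- if (is.null(T)) 8L else as.integer(T)
      phi <- sample_geps(G, Tn, beta = 0.5, seed = seed, separation = -0.8)
      theta <- sample_proportions(20L, Tn, alpha = 1, seed = seed + 1)
      truth <- .make_truth(phi, theta, rep(1, Tn), lengths,
                           rep(as.integer(depth), 20L), seed, scenario)
      pure_theta <- diag(Tn)
      dimnames(pure_theta) <- list(rownames(theta),
                                   paste0("pure_", seq_len(Tn)))
      pure_truth <- .make_truth(phi, pure_theta, rep(1, Tn), lengths,
                                rep(as.integer(depth), Tn), seed + 29, scenario)
      list(counts = simulate_counts(truth), truth = truth,
           pure_counts = simulate_counts(pure_truth))
    })
  out
}

#' Score a fit against a simulation ground truth
#'
#' Matches estimated types to the generating types by optimal assignment on
#' the chosen similarity and reports per-type GEP correlation and proportion
#' RMSE on both scales.
#'
#' @param fit a `decon_fit` from [run_gibbs()].
#' @param truth the matching `decon_truth`.
#' @param metric similarity metric for the matching, see
#'   [similarity_matrix()].
#' @return list: `assignment` (data.frame est/ref/score), `phi_pearson`
#'   (named per true type), `theta_rmse_cell`, `theta_rmse_rna`,
#'   `theta_cell_matched` and `theta_rna_matched` (estimates reordered to
#'   the truth's type order).
#' @details The anonymous estimated types carry no intrinsic order, so the
#'   per-type RNA yields `truth$eta` can only be applied after the types are
#'   matched: the cell-scale estimate scored here is
#'   `adjust_theta_for_cell_size()` applied to the matched RNA-scale
#'   proportions with the true `eta`, mirroring the intended workflow
#'   (deconvolve, identify types, then size-correct).
#' @export
score_against_truth <- function(fit, truth, metric = "pearson") {
  sim <- similarity_matrix(fit$phi_expression, truth$phi, metric = metric)
  asn <- munkres_assign(sim)
  asn <- asn[order(asn$ref), ]
  perm <- asn$est # estimated type matched to true type asn$ref
  phi_pearson <- setNames(
    vapply(seq_len(nrow(asn)), function(k)
      cor(fit$phi_expression[, asn$est[k]], truth$phi[, asn$ref[k]]),
      numeric(1)),
    colnames(truth$phi)[asn$ref])
  theta_rna_m <- fit$theta_rna[perm, , drop = FALSE]
  eta_m <- truth$eta[asn$ref]
  theta_cell_m <- matrix(apply(theta_rna_m, 2, adjust_theta_for_cell_size,
                               eta = eta_m), nrow = nrow(theta_rna_m))
  dimnames(theta_cell_m) <- dimnames(theta_rna_m)
  rownames(theta_cell_m) <- rownames(theta_rna_m) <- colnames(truth$phi)[asn$ref]
  list(assignment = asn,
       phi_pearson = phi_pearson,
       theta_rmse_cell = sqrt(mean((theta_cell_m - truth$theta_cell[asn$ref, ])^2)),
       theta_rmse_rna = sqrt(mean((theta_rna_m - truth$theta_rna[asn$ref, ])^2)),
       theta_cell_matched = theta_cell_m,
       theta_rna_matched = theta_rna_m)
}
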