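# Closed-form conversions between the sampler's read space and the
# biological scales: cell proportions vs RNA proportions (via cell sizes
# eta) and expression-scale vs length-weighted sampling-scale GEPs.

#' Effective gene length
#'
#' Number of positions at which a read of length `read_length` can start in a
#' gene of length `raw_length`, i.e. `raw_length - read_length + 1`.  Genes
#' shorter than the read are clamped to an effective length of 1 so that the
#' length-weighted sampling distribution stays well defined and no gene is
#' silently dropped.
#'
#' @param raw_length positive integer vector, gene length(s) in bases.
#' @param read_length positive integer scalar, sequenced read length in bases.
#' @return integer vector of effective lengths (>= 1).
#' @examples
#' effective_length(1000, 100) # 901
#' effective_length(50, 100)   # clamped to 1
#' @export
effective_length <- function(raw_length, read_length) {
  if (!is.numeric(raw_length) || any(raw_length < 1) ||
      !all(.is_wholenumber(raw_length)))
    stop("raw_length must be positive integer(s)", call. = FALSE)
  if (!is.numeric(read_length) || length(read_length) != 1L ||
      read_length < 1 || !.is_wholenumber(read_length))
    stop("read_length must be a positive integer scalar", call. = FALSE)
  pmax(as.integer(round(raw_length)) - as.integer(round(read_length)) + 1L, 1L)
}

#' Per-gene length table
#'
#' Bundles raw gene lengths (bases) with the read length and the derived
#' effective lengths used by the length-weighted read-sampling model.
#'
#' @param raw_length positive integer vector of gene lengths, named by gene
#'   id (names optional but kept when present).
#' @param read_length positive integer scalar read length in bases.
#' @return an object of class `gene_length_table`: list with `gene_id`,
#'   `raw_length`, `read_length`, `effective_length`.
#' @export
gene_length_table <- function(raw_length, read_length = 100L) {
  eff <- effective_length(raw_length, read_length)
  structure(list(gene_id = names(raw_length),
                 raw_length = as.integer(round(raw_length)),
                 read_length = as.integer(read_length),
                 effective_length = eff),
            class = "gene_length_table")
}

#' @export
print.gene_length_table <- function(x, ...) {
  cat(sprintf("gene_length_table: %d genes, read length %d b, effective lengths %d-%d\n",
              length(x$raw_length), x$read_length,
              min(x$effective_length), max(x$effective_length)))
  invisible(x)
}

#' Convert RNA-scale proportions to cell-scale proportions
#'
#' A cell of type t contributes on average `eta[t]` reads, so the fraction of
#' reads from a type overstates the fraction of cells for large-RNA types.
#' This inverts the generative weighting: `theta_cell = normalize(theta_rna / eta)`.
#' `eta` only matters up to a positive scalar.
#'
#' @param theta_rna simplex vector of RNA (read) proportions over cell types.
#' @param eta strictly positive vector of per-cell RNA yields (reads/cell).
#' @return simplex vector of cell proportions.
#' @seealso [cell_to_rna_proportions()] for the forward (generative) map.
#' @export
adjust_theta_for_cell_size <- function(theta_rna, eta) {
  if (length(theta_rna) != length(eta))
    stop("theta_rna and eta must have equal length", call. = FALSE)
  if (!is.numeric(eta) || any(eta <= 0))
    stop("eta must be strictly positive", call. = FALSE)
  .check_simplex(theta_rna, "theta_rna")
  .normalize(theta_rna / eta)
}

#' Convert cell-scale proportions to RNA-scale proportions
#'
#' The generative direction: `theta_rna = normalize(theta_cell * eta)`.
#'
#' @inheritParams adjust_theta_for_cell_size
#' @param theta_cell simplex vector of cell proportions.
#' @export
cell_to_rna_proportions <- function(theta_cell, eta) {
  if (length(theta_cell) != length(eta))
    stop("theta_cell and eta must have equal length", call. = FALSE)
  if (!is.numeric(eta) || any(eta <= 0))
    stop("eta must be strictly positive", call. = FALSE)
  .check_simplex(theta_cell, "theta_cell")
  .normalize(theta_cell * eta)
}

#' Convert a sampling-scale GEP to expression scale
#'
#' Reads are drawn in proportion to expression times effective length, so the
#' sampler estimates a length-weighted gene distribution.  Dividing by the
#' effective lengths and renormalizing recovers the expression-scale GEP.
#'
#' @param phi_sampling simplex vector over genes (length-weighted scale).
#' @param eff_lengths strictly positive vector of effective lengths.
#' @return simplex vector on expression scale.
#' @export
adjust_phi_for_length <- function(phi_sampling, eff_lengths) {
  if (length(phi_sampling) != length(eff_lengths))
    stop("phi_sampling and eff_lengths must have equal length", call. = FALSE)
  if (!is.numeric(eff_lengths) || any(eff_lengths <= 0))
    stop("eff_lengths must be strictly positive", call. = FALSE)
  .check_simplex(phi_sampling, "phi_sampling")
  .normalize(phi_sampling / eff_lengths)
}

#' Convert an expression-scale GEP to the read-sampling scale
#'
#' The generative direction: `phi_sampling = normalize(phi_expression * eff_lengths)`.
#'
#' @inheritParams adjust_phi_for_length
#' @param phi_expression simplex vector over genes (expression scale).
#' @export
phi_to_sampling <- function(phi_expression, eff_lengths) {
  if (length(phi_expression) != length(eff_lengths))
    stop("phi_expression and eff_lengths must have equal length", call. = FALSE)
  if (!is.numeric(eff_lengths) || any(eff_lengths <= 0))
    stop("eff_lengths must be strictly positive", call. = FALSE)
  .check_simplex(phi_expression, "phi_expression")
  .normalize(phi_expression * eff_lengths)
}

#' Bulk mixture GEP
#'
#' The expected gene distribution of a heterogeneous sample is the
#' proportion-weighted average of the pure cell-type GEPs:
#' `Phi[, i] = sum_t theta[t, i] * phi[, t]`.
#'
#' @param theta T x M matrix of mixing proportions, columns on the simplex.
#' @param phi G x T matrix of cell-type GEPs, columns on the simplex
#'   (any single scale; the output inherits it).
#' @return G x M matrix whose columns sum to 1.
#' @export
mixture_gep <- function(theta, phi) {
  if (!is.matrix(theta) || !is.matrix(phi))
    stop("theta and phi must be matrices", call. = FALSE)
  if (ncol(phi) != nrow(theta))
    stop(sprintf("dimension mismatch: phi has %d types, theta has %d",
                 ncol(phi), nrow(theta)), call. = FALSE)
  apply(theta, 2, .check_simplex, name = "theta column")
  apply(phi, 2, .check_simplex, name = "phi column")
  out <- phi %*% theta
  dimnames(out) <- list(rownames(phi), colnames(theta))
  out
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm[g, i] = counts[g, i] * 1e9 / (raw_length[g] * N[i])` where `N[i]` is
#' the column (library) total.  Uses raw gene length in bases, following the
#' standard definition; effective length is reserved for the generative
#' model.
#'
#' @param counts genes x samples numeric matrix (fractional values allowed,
#'   e.g. rescaled estimated profiles).
#' @param lengths a [gene_length_table()] (or positive vector of raw lengths
#'   in bases) matching the gene order of `counts`.
#' @return genes x samples matrix of RPKM values.
#' @export
rpkm <- function(counts, lengths) {
  raw <- if (inherits(lengths, "gene_length_table")) lengths$raw_length else lengths
  if (!is.numeric(raw) || any(raw <= 0))
    stop("gene lengths must be strictly positive", call. = FALSE)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (length(raw) != nrow(counts))
    stop("length table does not match the gene registry of counts", call. = FALSE)
  N <- colSums(counts)
  if (any(N <= 0)) stop("zero column sum: cannot compute RPKM", call. = FALSE)
  sweep(counts / raw, 2, N, "/") * 1e9
}

#' Estimate per-cell-type RNA yields from pure-sample read totals
#'
#' With pure (single-cell-type) libraries available, the Poisson mean read
#' yield of one cell of each type is estimated by the unweighted mean of the
#' replicate read totals, the maximum-likelihood unbiased estimator for a
#' Poisson mean.  Only the ratios between types matter downstream.
#'
#' @param per_cell_type_read_totals named list, one element per cell type,
#'   each a vector of replicate read totals (>= 1 replicate, all positive).
#' @return numeric vector `eta`, one entry per cell type (named as the list).
#' @export
estimate_eta_from_pure_counts <- function(per_cell_type_read_totals) {
  if (!is.list(per_cell_type_read_totals) ||
      length(per_cell_type_read_totals) == 0L)
    stop("provide a non-empty list of replicate read totals", call. = FALSE)
  eta <- vapply(per_cell_type_read_totals, function(x) {
    if (length(x) == 0L || !is.numeric(x) || any(x <= 0))
      stop("each cell type needs >= 1 positive replicate total", call. = FALSE)
    mean(x)
  }, numeric(1))
  eta
}
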