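# Associating anonymous estimated cell types with named reference GEPs:
# a similarity matrix (Pearson or negated symmetrized Kullback-Leibler),
# optimal one-to-one assignment, and a match threshold applied afterwards.

#' Similarity between estimated and reference GEPs
#'
#' Both metrics follow a "higher is better" convention so the same
#' maximization serves either choice:
#' * `pearson` - Pearson correlation of the expression columns;
#' * `kl` - negative symmetrized Kullback-Leibler divergence between the
#'   simplex-normalized columns, smoothed by 1e-12 (GEPs legitimately
#'   contain structural zeros) and renormalized.
#'
#' @param phi_est G x T matrix of estimated expression-scale GEPs.
#' @param panel G x R matrix of reference GEPs with named columns, on the
#'   same gene registry (identical rownames in identical order).
#' @param metric `"pearson"` or `"kl"`.
#' @return T x R similarity matrix with attribute `"metric"`.
#' @export
similarity_matrix <- function(phi_est, panel, metric = c("pearson", "kl")) {
  metric <- match.arg(metric)
  if (!is.matrix(phi_est) || !is.matrix(panel))
    stop("phi_est and panel must be matrices", call. = FALSE)
  if (nrow(phi_est) != nrow(panel) ||
      (!is.null(rownames(phi_est)) && !is.null(rownames(panel)) &&
       !identical(rownames(phi_est), rownames(panel))))
    stop("gene registries of phi_est and panel do not match", call. = FALSE)
  sim <- if (metric == "pearson") {
    cor(phi_est, panel)
  } else {
    p <- apply(phi_est, 2, function(x) .normalize(.normalize(x) + 1e-12))
    q <- apply(panel, 2, function(x) .normalize(.normalize(x) + 1e-12))
    p <- matrix(p, nrow = nrow(phi_est)); q <- matrix(q, nrow = nrow(panel))
    lp <- log(p); lq <- log(q)
    # KL(p||q)[t,r] = sum_g p lg(p) - sum_g p lg(q); symmetrize, negate
    e_p <- colSums(p * lp); e_q <- colSums(q * lq)
    kl_pq <- e_p - t(p) %*% lq          # T x R
    kl_qp <- matrix(e_q, nrow(kl_pq), ncol(kl_pq), byrow = TRUE) - t(lp) %*% q
    -(kl_pq + kl_qp)
  }
  dimnames(sim) <- list(colnames(phi_est), colnames(panel))
  structure(sim, metric = metric)
}

#' Optimal one-to-one cell-type assignment (Hungarian/Munkres)
#'
#' Finds the pairing of estimated types with reference types that maximizes
#' total similarity over `min(T, R)` pairs.  Internally solved as a
#' maximum-weight bipartite matching on positively shifted similarities
#' (shifting every entry by a constant does not change the optimal full
#' pairing).
#'
#' @param sim T x R similarity matrix (finite entries) from
#'   [similarity_matrix()].
#' @return data.frame with columns `est` and `ref` (integer indices) and
#'   `score`, one row per matched pair.
#' @export
munkres_assign <- function(sim) {
  if (!is.matrix(sim) || length(sim) == 0L)
    stop("sim must be a non-empty matrix", call. = FALSE)
  if (!all(is.finite(sim))) stop("sim must have finite entries", call. = FALSE)
  w <- unname(sim - min(sim) + 1)
  g <- igraph::graph_from_biadjacency_matrix(w, weighted = TRUE)
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight,
                                   eps = 1e-10)
  T <- nrow(sim)
  ref <- m$matching[seq_len(T)] - T
  est <- which(!is.na(ref) & ref >= 1)
  ref <- as.integer(ref[est])
  data.frame(est = as.integer(est), ref = ref,
             score = sim[cbind(est, ref)])
}

#' Apply a match threshold to an optimal assignment
#'
#' Pairs whose similarity does not exceed `threshold` are flagged unmatched:
#' the estimated type is reported as novel/unidentified rather than forced
#' onto its best reference.  Estimated types left unpaired by the assignment
#' (when T > R) are included as unmatched rows; reference types can likewise
#' remain unclaimed.
#'
#' @param assignment data.frame from [munkres_assign()].
#' @param sim the similarity matrix the assignment was computed from.
#' @param threshold similarity above which a pair counts as matched
#'   (default 0.6, a practical cutoff for Pearson correlation of GEPs).
#' @return data.frame of class `decon_assignment` with columns `est_type`,
#'   `ref_name`, `score`, `matched`; attributes `metric` and `threshold`.
#' @export
threshold_matches <- function(assignment, sim, threshold = 0.6) {
  ref_names <- colnames(sim)
  if (is.null(ref_names)) ref_names <- paste0("ref_", seq_len(ncol(sim)))
  est_names <- rownames(sim)
  if (is.null(est_names)) est_names <- paste0("type_", seq_len(nrow(sim)))
  out <- data.frame(est_type = est_names[assignment$est],
                    ref_name = ref_names[assignment$ref],
                    score = assignment$score,
                    matched = assignment$score > threshold,
                    stringsAsFactors = FALSE)
  unpaired <- setdiff(seq_len(nrow(sim)), assignment$est)
  if (length(unpaired) > 0L)
    out <- rbind(out, data.frame(est_type = est_names[unpaired],
                                 ref_name = NA_character_,
                                 score = NA_real_, matched = FALSE))
  out <- out[order(match(out$est_type, est_names)), ]
  rownames(out) <- NULL
  structure(out, metric = attr(sim, "metric"), threshold = threshold,
            class = c("decon_assignment", "data.frame"))
}
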