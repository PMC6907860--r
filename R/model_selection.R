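# Choosing the number of cell types T.  Each candidate T is scored by a
# Laplace (BIC-style) approximation to its log marginal likelihood: the
# observed-data log likelihood of the fitted mixture at the point estimates,
# minus 0.5 * k_T * log(total reads), with k_T the number of free mixture
# parameters.  Averaged over replicate chains; the maximum estimates T.
#
# Why this quantity and not a collapsed-likelihood trace: the complete-data
# joint log P(g, c) pays N*log(k) in its allocation part to split a merged
# type into k equal parts, exactly cancelling the gene-side entropy gain, so
# it decreases monotonically in T on mixed samples; conversely the gene part
# log P(g | c) alone can always be inflated by splitting a type by gene
# support, shifting entropy into the (unscored) allocations, so it increases
# monotonically.  The observed-data likelihood depends on the latent types
# only through the fitted mixture, which makes it immune to both artifacts:
# it rises steeply while added types capture real structure and plateaus at
# the truth, where the dimension penalty takes over.

#' Penalized log-posterior score for a candidate number of cell types
#'
#' Runs `n_replicates` independent collapsed Gibbs chains at the given `T`
#' and scores each by the observed-data log likelihood of its fitted
#' mixture, `sum(counts * log(phi_sampling %*% theta_rna))`, minus the
#' Laplace/BIC dimension penalty `0.5 * (T*(G-1) + M*(T-1)) * log(sum(counts))`;
#' the returned score is the mean over replicates.  Requires raw integer
#' counts: the multinomial read model that the score is built on is only
#' meaningful on the read-count scale.
#'
#' @inheritParams run_gibbs
#' @param n_replicates independent chains to average (>= 1; replicates guard
#'   against a single poorly mixed chain distorting the curve).
#' @return scalar score, with the per-replicate scores in attribute
#'   `"replicates"`.
#' @export
log_posterior_for_T <- function(counts, T, alpha = 5, beta = 0.5,
                                n_sweeps = 300L, n_replicates = 3L, seed = 1L) {
  if (!all(.is_wholenumber(counts)))
    stop("raw integer counts are required for estimating the number of cell types",
         call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  counts <- .validate_counts(counts)
  penalty <- 0.5 * (T * (nrow(counts) - 1) + ncol(counts) * (T - 1)) *
    log(sum(counts))
  scores <- vapply(seq_len(n_replicates), function(r) {
    fit <- run_gibbs(counts, T = T, alpha = alpha, beta = beta,
                     n_sweeps = n_sweeps, burn_in = 0L,
                     seed = .chain_seed(seed, T, r))
    sum(counts * log(fit$phi_sampling %*% fit$theta_rna)) - penalty
  }, numeric(1))
  structure(mean(scores), replicates = scores)
}

# derived chain seeds; kept below 2^31 and distinct across (T, replicate)
.chain_seed <- function(seed, T, r) {
  (as.double(seed) + 1000003 * (r - 1) + 7919 * T) %% 2^31
}

#' Estimate the number of cell types
#'
#' Evaluates [log_posterior_for_T()] over a grid of candidate cell-type
#' numbers and returns the argmax together with the full score curve (useful
#' for plotting; near-ties between neighbouring T are common, so inspect the
#' curve rather than trusting `best_T` blindly).  Exact ties are broken
#' toward the smaller T (parsimony) with a warning.
#'
#' @inheritParams log_posterior_for_T
#' @param t_grid strictly increasing integer vector of candidate T (min >= 1).
#' @return object of class `decon_model_selection`: list with `t_grid`,
#'   `log_posterior`, `best_T`, and the `replicate_scores` matrix
#'   (replicates x grid).
#' @examples
#' bench <- make_benchmark("pure_panel", seed = 1, G = 50, depth = 1500, T = 2)
#' sel <- estimate_num_cell_types(bench$counts, t_grid = 2:3,
#'                                n_sweeps = 40, n_replicates = 1, seed = 1)
#' sel$best_T
#' @export
estimate_num_cell_types <- function(counts, t_grid, alpha = 5, beta = 0.5,
                                    n_sweeps = 300L, n_replicates = 3L,
                                    seed = 1L) {
  if (length(t_grid) == 0L || any(t_grid < 1) ||
      any(diff(t_grid) <= 0) || !all(.is_wholenumber(t_grid)))
    stop("t_grid must be a non-empty strictly increasing integer vector (min >= 1)",
         call. = FALSE)
  counts <- .validate_counts(counts)
  rep_scores <- vapply(t_grid, function(T) {
    s <- log_posterior_for_T(counts, T, alpha = alpha, beta = beta,
                             n_sweeps = n_sweeps, n_replicates = n_replicates,
                             seed = seed)
    attr(s, "replicates")
  }, numeric(n_replicates))
  rep_scores <- matrix(rep_scores, nrow = n_replicates,
                       dimnames = list(NULL, paste0("T", t_grid)))
  lp <- colMeans(rep_scores)
  if (sum(lp == max(lp)) > 1L)
    warning("tie in log-posterior scores; choosing the smallest T", call. = FALSE)
  structure(list(t_grid = as.integer(t_grid),
                 log_posterior = unname(lp),
                 best_T = as.integer(t_grid[which.max(lp)]),
                 replicate_scores = rep_scores,
                 alpha = alpha, beta = beta,
                 n_sweeps = as.integer(n_sweeps),
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "decon_model_selection")
}

#' @export
print.decon_model_selection <- function(x, ...) {
  cat(sprintf("decon_model_selection over T in {%s}\n",
              paste(x$t_grid, collapse = ", ")))
  tab <- data.frame(T = x$t_grid, log_posterior = x$log_posterior)
  print(tab, row.names = FALSE)
  cat(sprintf("best_T = %d (argmax of the log posterior)\n", x$best_T))
  invisible(x)
}
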