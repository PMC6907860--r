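# Token-level collapsed Gibbs sampler.  The Dirichlet parameters phi and
# theta are integrated out; the chain state is the per-read cell-type
# assignment field summarized by gene x type, sample x type and type-total
# counts.  The compiled kernel lives in src/gibbs.cpp; the R functions here
# construct states, expose single sweeps for testing, and turn final counts
# into point estimates on the biological scales.

#' Expand a count matrix into read tokens
#'
#' Inverse of count aggregation: each read becomes one token carrying its
#' gene index and sample index.  Token order is deterministic: sample-major,
#' genes ascending within a sample.
#'
#' @param counts validated genes x samples integer matrix.
#' @return list with integer vectors `gene` and `sample` (1-based, one entry
#'   per read), `gene_ids`, `sample_ids`, `G`, `M`, and per-sample totals `Ni`.
#' @export
expand_counts <- function(counts) {
  counts <- .validate_counts(counts)
  G <- nrow(counts); M <- ncol(counts)
  idx <- rep.int(seq_len(G * M) - 1L, as.integer(counts))
  list(gene = idx %% G + 1L,
       sample = idx %/% G + 1L,
       gene_ids = rownames(counts),
       sample_ids = colnames(counts),
       G = G, M = M,
       Ni = as.integer(colSums(counts)))
}

.tally_state <- function(tokens, z, T) {
  G <- tokens$G; M <- tokens$M
  ngt <- matrix(tabulate((z - 1L) * G + tokens$gene, nbins = G * T), G, T)
  nit <- matrix(tabulate((z - 1L) * M + tokens$sample, nbins = M * T), M, T)
  list(ngt = ngt, nit = nit, nt = colSums(ngt))
}

#' Initialize a Gibbs chain
#'
#' Assigns every token a cell type uniformly at random (counter-based RNG, so
#' a given seed yields a bit-identical state on any platform) and tallies the
#' sufficient statistics.
#'
#' @param tokens token table from [expand_counts()].
#' @param T number of cell types (>= 1).
#' @param seed integer chain seed.
#' @return a `chain_state`: list with `ngt` (G x T), `nit` (M x T), `nt`,
#'   token table, assignments `z` (1-based), `sweep` counter, `seed`, and the
#'   accumulated log-likelihood `trace`.
#' @export
init_chain <- function(tokens, T, seed = 1L) {
  if (!is.numeric(T) || length(T) != 1L || T < 1 || !.is_wholenumber(T))
    stop("T must be a positive integer", call. = FALSE)
  T <- as.integer(T)
  z <- cpp_init_assignments(length(tokens$gene), T, as.double(seed)) + 1L
  st <- .tally_state(tokens, z, T)
  structure(list(ngt = st$ngt, nit = st$nit, nt = st$nt,
                 tokens = tokens, z = z, T = T,
                 sweep = 0L, seed = as.double(seed), trace = numeric(0),
                 trace_gene = numeric(0)),
            class = "chain_state")
}

#' Collapsed conditional distribution of one token's cell type
#'
#' Probability of each cell type for token `j` given all other assignments,
#' with the token itself removed from the counts:
#' `p(t) propto (n_gt + beta_g) / (n_t + sum(beta)) * (n_it + alpha_t)`.
#' This is the distribution the sampler draws from at every read.
#'
#' @param state a `chain_state`.
#' @param j token index (1-based position in the token table).
#' @param alpha,beta Dirichlet hyperparameters (scalar or vectors of length
#'   T and G).
#' @return simplex vector of length T.
#' @export
conditional_type_probs <- function(state, j, alpha = 5, beta = 0.5) {
  stopifnot(inherits(state, "chain_state"))
  if (j < 1 || j > length(state$z)) stop("token index out of range", call. = FALSE)
  g <- state$tokens$gene[j]; i <- state$tokens$sample[j]; told <- state$z[j]
  alpha <- .expand_hyper(alpha, state$T, "alpha")
  beta <- .expand_hyper(beta, nrow(state$ngt), "beta")
  ngt_row <- state$ngt[g, ]; nit_row <- state$nit[i, ]; nt <- state$nt
  ngt_row[told] <- ngt_row[told] - 1L
  nit_row[told] <- nit_row[told] - 1L
  nt[told] <- nt[told] - 1L
  if (ngt_row[told] < 0 || nit_row[told] < 0)
    stop("internal consistency error: negative decremented count", call. = FALSE)
  p <- (ngt_row + beta[g]) / (nt + sum(beta)) * (nit_row + alpha)
  .normalize(p)
}

#' Run Gibbs sweeps on a chain state
#'
#' Resamples every token exactly once per sweep in deterministic order
#' (sample-major, then token index).  The RNG is keyed by (seed, sweep,
#' token), so running `n_sweeps = 10` once or ten times singly yields the
#' identical trajectory.
#'
#' @param state a `chain_state`.
#' @inheritParams conditional_type_probs
#' @param n_sweeps number of full sweeps to run.
#' @return the updated `chain_state`, with the per-sweep collapsed
#'   log-likelihood appended to `state$trace`.
#' @export
gibbs_sweep <- function(state, alpha = 5, beta = 0.5, n_sweeps = 1L) {
  stopifnot(inherits(state, "chain_state"))
  alpha <- .expand_hyper(alpha, state$T, "alpha")
  beta <- .expand_hyper(beta, state$tokens$G, "beta")
  res <- cpp_gibbs_run(state$tokens$gene - 1L, state$tokens$Ni,
                       state$z - 1L, state$tokens$G, state$T,
                       alpha, beta, state$seed, state$sweep,
                       as.integer(n_sweeps), 0L, FALSE, TRUE)
  state$ngt <- res$ngt; state$nit <- res$nit; state$nt <- res$nt
  state$z <- res$z + 1L
  state$sweep <- res$sweep
  state$trace <- c(state$trace, res$loglik_gene + res$loglik_alloc)
  state$trace_gene <- c(state$trace_gene, res$loglik_gene)
  state
}

# gene part of the collapsed likelihood, log P(g | c, beta): the
# model-evidence score used when selecting the number of cell types
.gene_log_likelihood <- function(state, beta = 0.5) {
  ngt <- state$ngt; nt <- state$nt
  T <- ncol(ngt); G <- nrow(ngt)
  beta <- .expand_hyper(beta, G, "beta")
  sum(lgamma(ngt + beta)) - sum(lgamma(nt + sum(beta))) -
    T * (sum(lgamma(beta)) - lgamma(sum(beta)))
}

#' Collapsed complete-data log likelihood
#'
#' Log probability of the observed gene assignments and the current latent
#' cell-type assignments with phi and theta integrated out analytically: a
#' product of ratios of multivariate beta functions, one per cell type (over
#' genes) and one per sample (over types).  This is the model-selection score
#' traced along the chain.
#'
#' @param state a `chain_state` (or any list with `ngt`, `nit`, `nt` and a
#'   token table or `Ni`).
#' @inheritParams conditional_type_probs
#' @return scalar log likelihood.
#' @export
complete_log_likelihood <- function(state, alpha = 5, beta = 0.5) {
  ngt <- state$ngt; nit <- state$nit; nt <- state$nt
  Ni <- if (!is.null(state$tokens)) state$tokens$Ni else state$Ni
  T <- ncol(ngt); G <- nrow(ngt); M <- nrow(nit)
  alpha <- .expand_hyper(alpha, T, "alpha")
  beta <- .expand_hyper(beta, G, "beta")
  sum(lgamma(ngt + beta)) - sum(lgamma(nt + sum(beta))) -
    T * (sum(lgamma(beta)) - lgamma(sum(beta))) +
    sum(lgamma(sweep(nit, 2, alpha, "+"))) - sum(lgamma(Ni + sum(alpha))) -
    M * (sum(lgamma(alpha)) - lgamma(sum(alpha)))
}

# Point estimates from (possibly averaged) sufficient-statistic counts:
# Dirichlet-smoothed empirical frequencies on the sampling scale.
.estimates_from_counts <- function(ngt, nit, Ni, alpha, beta) {
  phi_sampling <- sweep(ngt + beta, 2, colSums(ngt) + sum(beta), "/")
  theta_rna <- t(sweep(sweep(nit, 2, alpha, "+"), 1, Ni + sum(alpha), "/"))
  list(phi_sampling = phi_sampling, theta_rna = theta_rna)
}

#' Complete deconvolution by collapsed Gibbs sampling
#'
#' Runs the collapsed Gibbs sampler on a bulk count matrix and returns point
#' estimates of the cell-type GEPs and the per-sample cell-type proportions,
#' on both the sampler's read scale and the biological scales (expression
#' scale via effective gene lengths; cell scale via the RNA-yield vector
#' `eta`).
#'
#' Defaults `alpha = 5`, `beta = 0.5` work well for typical bulk designs;
#' consider `alpha < 1` when samples are dominated by one or two cell types
#' and `beta > 1` when cell-type GEPs are expected to be highly correlated.
#'
#' @param counts genes x samples integer matrix of read counts.
#' @param T number of cell types to fit.
#' @param alpha Dirichlet prior on per-sample type proportions (scalar or
#'   length-T vector).
#' @param beta Dirichlet prior on per-type gene distributions (scalar or
#'   length-G vector).
#' @param n_sweeps total Gibbs sweeps (default 700).
#' @param burn_in sweeps to discard when `average = TRUE` (default 0).
#' @param seed integer chain seed; the whole trajectory is reproducible.
#' @param eta optional positive length-T vector of per-cell RNA yields used
#'   to convert RNA proportions to cell proportions; default (NULL) means no
#'   size differences, in which case `theta_cell` equals `theta_rna` and
#'   proportions should be read as RNA proportions.
#' @param lengths optional [gene_length_table()]; default (NULL) treats all
#'   effective lengths as equal, in which case expression and sampling scale
#'   coincide.
#' @param average if TRUE, estimate from counts averaged over post-burn-in
#'   sweeps instead of the final snapshot.  Off by default: label switching
#'   between widely separated sweeps is not corrected, so averaging is only
#'   safe for short, well-mixed stretches.
#' @return an object of class `decon_fit`: list with `phi_expression`,
#'   `phi_sampling` (G x T, columns on the simplex), `theta_cell`,
#'   `theta_rna` (T x M, columns on the simplex), per-sweep traces `log_lik`
#'   (full collapsed complete-data log likelihood) and `log_lik_gene` (its
#'   gene part, the model-evidence score used by [log_posterior_for_T()]),
#'   and the call settings.
#' @examples
#' bench <- make_benchmark("pure_panel", seed = 1, G = 60, depth = 2000, T = 3)
#' fit <- run_gibbs(bench$counts, T = 3, n_sweeps = 50, seed = 1,
#'                  lengths = bench$truth$lengths)
#' round(fit$theta_rna, 2)
#' @export
run_gibbs <- function(counts, T, alpha = 5, beta = 0.5, n_sweeps = 700L,
                      burn_in = 0L, seed = 1L, eta = NULL, lengths = NULL,
                      average = FALSE) {
  counts <- .validate_counts(counts)
  if (n_sweeps <= burn_in || burn_in < 0)
    stop("need n_sweeps > burn_in >= 0", call. = FALSE)
  tokens <- expand_counts(counts)
  G <- tokens$G; M <- tokens$M
  T <- as.integer(T)
  if (T < 1) stop("T must be >= 1", call. = FALSE)
  alpha <- .expand_hyper(alpha, T, "alpha")
  beta <- .expand_hyper(beta, G, "beta")
  if (is.null(eta)) eta <- rep(1, T)
  if (length(eta) != T || any(eta <= 0))
    stop("eta must be a strictly positive vector of length T", call. = FALSE)
  eff <- if (is.null(lengths)) rep(1, G) else {
    if (length(lengths$effective_length) != G)
      stop("length table does not match the gene registry of counts", call. = FALSE)
    lengths$effective_length
  }

  z0 <- cpp_init_assignments(length(tokens$gene), T, as.double(seed))
  res <- cpp_gibbs_run(tokens$gene - 1L, tokens$Ni, z0,
                       G, T, alpha, beta, as.double(seed),
                       0L, as.integer(n_sweeps), as.integer(burn_in),
                       average, TRUE)

  est <- if (average)
    .estimates_from_counts(res$avg_ngt, res$avg_nit, tokens$Ni, alpha, beta)
  else
    .estimates_from_counts(res$ngt, res$nit, tokens$Ni, alpha, beta)

  type_ids <- paste0("type_", seq_len(T))
  phi_sampling <- est$phi_sampling
  dimnames(phi_sampling) <- list(tokens$gene_ids, type_ids)
  phi_expression <- matrix(apply(phi_sampling, 2, adjust_phi_for_length,
                                 eff_lengths = eff), nrow = G)
  dimnames(phi_expression) <- dimnames(phi_sampling)
  theta_rna <- est$theta_rna
  dimnames(theta_rna) <- list(type_ids, tokens$sample_ids)
  theta_cell <- apply(theta_rna, 2, adjust_theta_for_cell_size, eta = eta)
  if (T == 1L) theta_cell <- matrix(theta_cell, 1L, M)
  dimnames(theta_cell) <- dimnames(theta_rna)

  structure(list(phi_expression = phi_expression,
                 phi_sampling = phi_sampling,
                 theta_cell = theta_cell,
                 theta_rna = theta_rna,
                 log_lik = res$loglik_gene + res$loglik_alloc,
                 log_lik_gene = res$loglik_gene,
                 T = T, alpha = alpha, beta = beta, eta = eta,
                 n_sweeps = as.integer(n_sweeps), burn_in = as.integer(burn_in),
                 average = average, seed = seed,
                 gene_ids = tokens$gene_ids, sample_ids = tokens$sample_ids),
            class = "decon_fit")
}

#' @export
print.decon_fit <- function(x, ...) {
  cat(sprintf("decon_fit: %d cell types, %d genes, %d samples\n",
              x$T, length(x$gene_ids), length(x$sample_ids)))
  cat(sprintf("  %d sweeps (burn-in %d, %s), alpha[1] = %g, beta[1] = %g, seed %s\n",
              x$n_sweeps, x$burn_in,
              if (x$average) "posterior-averaged" else "final snapshot",
              x$alpha[1], x$beta[1], format(x$seed)))
  cat(sprintf("  final collapsed log likelihood: %.2f\n",
              x$log_lik[length(x$log_lik)]))
  invisible(x)
}
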