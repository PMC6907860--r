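# Independent oracles used across the suite.  These deliberately avoid the
# package's closed-form code paths: the joint probability is built by the
# sequential predictive (Polya-urn) factorization, read by read.

# log P(g, c | alpha, beta) via the chain rule: for each token in order,
# p(c_j | earlier tokens of its sample) * p(g_j | earlier tokens of its type)
oracle_joint_loglik <- function(gene, samp, cvec, G, M, T, alpha, beta) {
  alpha <- rep(alpha, length.out = T)
  beta <- rep(beta, length.out = G)
  ngt <- matrix(0, G, T); nit <- matrix(0, M, T)
  nt <- rep(0, T); ni <- rep(0, M)
  ll <- 0
  for (j in seq_along(gene)) {
    g <- gene[j]; i <- samp[j]; t <- cvec[j]
    ll <- ll + log((nit[i, t] + alpha[t]) / (ni[i] + sum(alpha))) +
      log((ngt[g, t] + beta[g]) / (nt[t] + sum(beta)))
    ngt[g, t] <- ngt[g, t] + 1; nit[i, t] <- nit[i, t] + 1
    nt[t] <- nt[t] + 1; ni[i] <- ni[i] + 1
  }
  ll
}

# conditional p(c_j = t | c_-j, g) by evaluating the full joint at every t
oracle_conditional <- function(gene, samp, cvec, j, G, M, T, alpha, beta) {
  lp <- vapply(seq_len(T), function(t) {
    cc <- cvec; cc[j] <- t
    oracle_joint_loglik(gene, samp, cc, G, M, T, alpha, beta)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p / sum(p)
}

# all permutations of 1..n (for assignment enumeration)
oracle_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- oracle_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# best one-to-one assignment of rows to columns by exhaustive search;
# returns list(perm, total) where perm[r] is the column given to row r
oracle_best_assignment <- function(sim) {
  n <- nrow(sim); m <- ncol(sim)
  if (n <= m) {
    perms <- oracle_permutations(m)
    tot <- apply(perms, 1, function(p) sum(sim[cbind(seq_len(n), p[seq_len(n)])]))
    best <- perms[which.max(tot), seq_len(n)]
    list(perm = best, total = max(tot))
  } else {
    inner <- oracle_best_assignment(t(sim))
    perm <- rep(NA_integer_, n)
    perm[inner$perm] <- seq_len(m)
    list(perm = perm, total = inner$total)
  }
}

# small random count matrix with positive column sums
random_counts <- function(G, M, lambda = 3, seed = 1) {
  set.seed(seed)
  repeat {
    x <- matrix(rpois(G * M, lambda), G, M,
                dimnames = list(paste0("g", seq_len(G)),
                                paste0("s", seq_len(M))))
    if (all(colSums(x) > 0)) return(x)
  }
}

# re-aggregate a token table into a count matrix
tokens_to_counts <- function(tok) {
  out <- matrix(0L, tok$G, tok$M,
                dimnames = list(tok$gene_ids, tok$sample_ids))
  for (j in seq_along(tok$gene))
    out[tok$gene[j], tok$sample[j]] <- out[tok$gene[j], tok$sample[j]] + 1L
  out
}

# full recount of a chain state's sufficient statistics from its assignments
recount_state <- function(state) {
  G <- state$tokens$G; M <- state$tokens$M; T <- state$T
  ngt <- matrix(0L, G, T); nit <- matrix(0L, M, T)
  for (j in seq_along(state$z)) {
    ngt[state$tokens$gene[j], state$z[j]] <- ngt[state$tokens$gene[j], state$z[j]] + 1L
    nit[state$tokens$sample[j], state$z[j]] <- nit[state$tokens$sample[j], state$z[j]] + 1L
  }
  list(ngt = ngt, nit = nit, nt = colSums(ngt))
}

random_simplex <- function(n) { x <- runif(n) + 1e-3; x / sum(x) }
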