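# Collapsed Gibbs machinery: token expansion, chain state, the collapsed
# conditional, sweeps, the likelihood, and end-to-end estimation.

test_that("expand_counts round-trips and orders tokens deterministically", {
  counts <- matrix(c(2L, 1L, 0L, 3L), 2, 2,
                   dimnames = list(c("gA", "gB"), c("s1", "s2")))
  tok <- expand_counts(counts)
  expect_identical(tok$gene, c(1L, 1L, 2L, 2L, 2L, 2L))
  expect_identical(tok$sample, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_identical(tok$Ni, c(3L, 3L))

  x <- random_counts(10, 3, seed = 5)
  expect_identical(tokens_to_counts(expand_counts(x)), x)

  expect_error(expand_counts(matrix(c(1.5, 1, 1, 1), 2, 2)), "dilute|integer")
  expect_error(expand_counts(matrix(c(1L, 1L, 0L, 0L), 2, 2)), "zero column")
})

test_that("init_chain is uniform, deterministic, and internally consistent", {
  tok <- expand_counts(random_counts(8, 3, seed = 2))
  s1 <- init_chain(tok, T = 1, seed = 9)
  expect_true(all(s1$z == 1L))
  expect_identical(s1$nit[, 1], tok$Ni)

  a <- init_chain(tok, T = 4, seed = 9)
  b <- init_chain(tok, T = 4, seed = 9)
  expect_identical(a$z, b$z)
  expect_false(identical(a$z, init_chain(tok, T = 4, seed = 10)$z))

  rc <- recount_state(a)
  expect_identical(unname(a$ngt), rc$ngt)
  expect_identical(unname(a$nit), rc$nit)
  expect_identical(a$nt, rc$nt)
  expect_error(init_chain(tok, T = 0), "positive")
})

test_that("conditional_type_probs matches the joint-ratio oracle exactly", {
  # 3 genes, 2 types, 2 samples
  counts <- matrix(c(2L, 1L, 1L, 0L, 2L, 1L), 3, 2)
  tok <- expand_counts(counts)
  st <- init_chain(tok, T = 2, seed = 4)
  alpha <- c(5, 2); beta <- c(0.5, 1, 0.3)
  for (j in seq_along(st$z)) {
    p <- conditional_type_probs(st, j, alpha = alpha, beta = beta)
    o <- oracle_conditional(tok$gene, tok$sample, st$z, j,
                            G = 3, M = 2, T = 2, alpha = alpha, beta = beta)
    expect_lt(max(abs(p - o)), 1e-12)
  }
  expect_equal(conditional_type_probs(init_chain(tok, 1, 1), 1, 5, 0.5), 1)
  # symmetric state: after removing token 1 both types hold one copy of the
  # same gene, so symmetry forces (0.5, 0.5)
  sym <- expand_counts(matrix(3L, 1, 1))
  stsym <- init_chain(sym, T = 2, seed = 1)
  stsym$z <- c(1L, 1L, 2L)
  rc <- recount_state(stsym)
  stsym$ngt <- rc$ngt; stsym$nit <- rc$nit; stsym$nt <- rc$nt
  expect_equal(conditional_type_probs(stsym, 1, alpha = 5, beta = 0.5),
               c(0.5, 0.5), tolerance = 1e-12)
})

test_that("gibbs_sweep conserves counts, is chunk-invariant, and T=1 is a no-op", {
  counts <- random_counts(12, 4, lambda = 6, seed = 3)
  tok <- expand_counts(counts)

  s1 <- gibbs_sweep(init_chain(tok, T = 1, seed = 1))
  expect_true(all(s1$z == 1L))
  expect_identical(s1$sweep, 1L)

  st <- init_chain(tok, T = 3, seed = 7)
  a <- gibbs_sweep(st, n_sweeps = 5)
  b <- st
  for (k in 1:5) b <- gibbs_sweep(b)
  expect_identical(a$z, b$z)        # counter-based RNG: chunking-invariant
  expect_equal(a$trace, b$trace)

  rc <- recount_state(a)
  expect_identical(unname(a$ngt), rc$ngt)
  expect_identical(unname(a$nit), rc$nit)
  expect_identical(rowSums(a$nit), as.numeric(tok$Ni))
  expect_identical(colSums(a$ngt), colSums(a$nit))
})

test_that("the sampler's stationary distribution matches the enumerated posterior", {
  # one sample, two reads on two genes, two types: the 4 assignment states
  # are enumerable, and long-run visit frequencies must match P(c | g).
  counts <- matrix(c(1L, 1L), 2, 1)
  tok <- expand_counts(counts)
  alpha <- 2; beta <- c(0.5, 0.5)
  lp <- sapply(1:2, function(c1) sapply(1:2, function(c2)
    oracle_joint_loglik(tok$gene, tok$sample, c(c1, c2), 2, 1, 2, alpha, beta)))
  post <- exp(lp - max(lp)); post <- post / sum(post) # [c2, c1]

  st <- init_chain(tok, T = 2, seed = 123)
  n <- 6e3
  visits <- matrix(0, 2, 2)
  for (k in seq_len(n)) {
    st <- gibbs_sweep(st, alpha = alpha, beta = beta)
    visits[st$z[2], st$z[1]] <- visits[st$z[2], st$z[1]] + 1
  }
  freq <- visits / n
  # within 4 standard errors elementwise
  se <- sqrt(post * (1 - post) / n)
  expect_true(all(abs(freq - post) < 4 * se + 1e-3))
})

test_that("complete_log_likelihood equals the sequential predictive oracle", {
  # single token, T = 1: closed form log(beta_g / sum(beta))
  counts1 <- matrix(1L, 1, 1, dimnames = list("g1", "s1"))
  tok1 <- expand_counts(counts1)
  st1 <- init_chain(tok1, 1, 1)
  expect_equal(complete_log_likelihood(st1, alpha = 5, beta = 0.5),
               log(0.5 / 0.5), tolerance = 1e-12)
  g2 <- matrix(c(1L, 1L), 2, 1)
  st2 <- init_chain(expand_counts(g2), 1, 1)
  # two tokens on distinct genes: beta/(sum beta) * beta/(sum beta + 1)
  expect_equal(complete_log_likelihood(st2, alpha = 5, beta = 0.5),
               log(0.5 / 1) + log(0.5 / 2), tolerance = 1e-12)

  # 4-token instance, all assignments compared against the oracle
  counts <- matrix(c(2L, 1L, 0L, 1L), 2, 2)
  tok <- expand_counts(counts)
  alpha <- c(1.5, 3); beta <- c(0.7, 0.4)
  perms <- as.matrix(expand.grid(1:2, 1:2, 1:2, 1:2))
  for (r in seq_len(nrow(perms))) {
    st <- init_chain(tok, 2, 1)
    st$z <- as.integer(perms[r, ])
    rc <- recount_state(st)
    st$ngt <- rc$ngt; st$nit <- rc$nit; st$nt <- rc$nt
    expect_equal(complete_log_likelihood(st, alpha, beta),
                 oracle_joint_loglik(tok$gene, tok$sample, st$z,
                                     2, 2, 2, alpha, beta),
                 tolerance = 1e-10)
  }

  # the C++ per-sweep traces agree with the R formulas on the final state
  counts <- random_counts(10, 3, seed = 8)
  tokb <- expand_counts(counts)
  stb <- gibbs_sweep(init_chain(tokb, 3, seed = 2), n_sweeps = 7)
  expect_equal(stb$trace[7], complete_log_likelihood(stb), tolerance = 1e-8)
  expect_equal(stb$trace_gene[7], bulkdecon:::.gene_log_likelihood(stb),
               tolerance = 1e-8)
})

test_that("run_gibbs with T = 1 returns smoothed pooled frequencies", {
  counts <- random_counts(6, 3, lambda = 10, seed = 9)
  lt <- gene_length_table(setNames(sample(500:5000, 6), rownames(counts)))
  fit <- run_gibbs(counts, T = 1, n_sweeps = 3, seed = 1, lengths = lt)
  expect_true(all(fit$theta_cell == 1))
  expected_sampling <- (rowSums(counts) + 0.5) / (sum(counts) + 3)
  expect_equal(unname(fit$phi_sampling[, 1]), unname(expected_sampling),
               tolerance = 1e-12)
  expect_equal(unname(fit$phi_expression[, 1]),
               unname(adjust_phi_for_length(expected_sampling,
                                            lt$effective_length)),
               tolerance = 1e-12)
})

test_that("estimates are simplex-valued and label-permutation symmetric", {
  counts <- random_counts(15, 4, lambda = 8, seed = 6)
  tok <- expand_counts(counts)
  st <- gibbs_sweep(init_chain(tok, 3, seed = 3), n_sweeps = 10)
  est <- bulkdecon:::.estimates_from_counts(st$ngt, st$nit, tok$Ni,
                                            rep(5, 3), rep(0.5, 15))
  expect_equal(colSums(est$phi_sampling), rep(1, 3), tolerance = 1e-8)
  expect_equal(colSums(est$theta_rna), rep(1, 4), tolerance = 1e-8)

  perm <- c(3L, 1L, 2L)
  est_p <- bulkdecon:::.estimates_from_counts(st$ngt[, perm], st$nit[, perm],
                                              tok$Ni, rep(5, 3), rep(0.5, 15))
  expect_equal(est_p$phi_sampling, est$phi_sampling[, perm])
  expect_equal(est_p$theta_rna, est$theta_rna[perm, ])
  # permuting labels leaves the collapsed likelihood invariant
  stp <- st
  stp$ngt <- st$ngt[, perm]; stp$nit <- st$nit[, perm]; stp$nt <- st$nt[perm]
  expect_equal(complete_log_likelihood(stp), complete_log_likelihood(st))
})

test_that("run_gibbs recovers pure samples at small scale", {
  bench <- make_benchmark("pure_panel", seed = 3, G = 200, depth = 5000, T = 3)
  fit <- run_gibbs(bench$counts, T = 3, n_sweeps = 100, seed = 2,
                   lengths = bench$truth$lengths)
  sc <- score_against_truth(fit, bench$truth)
  matched <- diag(sc$theta_cell_matched[, ])
  expect_true(all(matched > 0.9))
  expect_true(all(sc$phi_pearson > 0.95))
})

test_that("run_gibbs is reproducible and validates its inputs", {
  counts <- random_counts(10, 3, lambda = 5, seed = 4)
  f1 <- run_gibbs(counts, T = 2, n_sweeps = 5, seed = 11)
  f2 <- run_gibbs(counts, T = 2, n_sweeps = 5, seed = 11)
  expect_identical(f1$theta_rna, f2$theta_rna)
  expect_identical(f1$log_lik, f2$log_lik)
  expect_error(run_gibbs(counts, T = 2, n_sweeps = 5, burn_in = 5), "burn_in")
  expect_error(run_gibbs(counts, T = 2, n_sweeps = 5, eta = c(1, -1)),
               "positive")
})
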