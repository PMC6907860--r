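# Scale conversions: effective length, cell-size and gene-length
# adjustments, mixture GEPs, RPKM, eta estimation.

test_that("effective_length follows l - m + 1 with a floor at 1", {
  expect_identical(effective_length(1000, 100), 901L)
  expect_identical(effective_length(100, 100), 1L)
  expect_identical(effective_length(50, 100), 1L) # gene shorter than read
  expect_identical(effective_length(c(1000, 100, 50), 100), c(901L, 1L, 1L))
  expect_error(effective_length(0, 100), "positive")
  expect_error(effective_length(1000, 0), "positive")
})

test_that("cell-size adjustment matches forced examples and inverts the generative map", {
  expect_equal(adjust_theta_for_cell_size(c(0.5, 0.5), c(1, 1)), c(0.5, 0.5))
  expect_equal(adjust_theta_for_cell_size(c(0.5, 0.5), c(1, 2)), c(2/3, 1/3))
  expect_equal(cell_to_rna_proportions(c(2/3, 1/3), c(1, 2)), c(0.5, 0.5))
  expect_error(adjust_theta_for_cell_size(c(0.5, 0.5), c(1, 0)), "positive")
  expect_error(cell_to_rna_proportions(c(0.7, 0.3), c(-1, 2)), "positive")

  set.seed(42)
  for (k in 1:20) {
    T <- sample(2:8, 1)
    x <- random_simplex(T)
    eta <- runif(T, 0.2, 5)
    expect_lt(max(abs(cell_to_rna_proportions(
      adjust_theta_for_cell_size(x, eta), eta) - x)), 1e-10)
    expect_equal(sum(adjust_theta_for_cell_size(x, eta)), 1, tolerance = 1e-8)
    # constant eta is the identity regardless of its level
    expect_equal(adjust_theta_for_cell_size(x, rep(3.7, T)), x, tolerance = 1e-12)
  }
})

test_that("length adjustment matches forced examples and inverts phi_to_sampling", {
  expect_equal(adjust_phi_for_length(c(0.5, 0.5), c(100, 100)), c(0.5, 0.5))
  expect_equal(adjust_phi_for_length(c(0.5, 0.5), c(100, 300)), c(0.75, 0.25))
  expect_equal(phi_to_sampling(c(0.75, 0.25), c(100, 300)), c(0.5, 0.5))
  expect_error(adjust_phi_for_length(c(0.5, 0.5), c(0, 100)), "positive")

  set.seed(7)
  for (k in 1:20) {
    G <- sample(3:30, 1)
    x <- random_simplex(G)
    len <- runif(G, 1, 1e4)
    expect_lt(max(abs(adjust_phi_for_length(
      phi_to_sampling(x, len), len) - x)), 1e-10)
    expect_equal(phi_to_sampling(x, rep(901, G)), x, tolerance = 1e-12)
  }
})

test_that("mixture_gep equals the brute-force double loop", {
  phi <- matrix(c(1, 0, 0), 3, 1)
  expect_equal(unname(mixture_gep(matrix(1, 1, 2), phi)),
               cbind(phi[, 1], phi[, 1]))

  set.seed(11)
  G <- 5; T <- 3; M <- 4
  phi <- vapply(1:T, function(t) random_simplex(G), numeric(G))
  theta <- vapply(1:M, function(i) random_simplex(T), numeric(T))
  # one-hot column picks out a single GEP
  theta[, 1] <- c(1, 0, 0)
  Phi <- mixture_gep(theta, phi)
  expect_equal(unname(Phi[, 1]), phi[, 1], tolerance = 1e-12)
  brute <- matrix(0, G, M)
  for (g in 1:G) for (i in 1:M) for (t in 1:T)
    brute[g, i] <- brute[g, i] + theta[t, i] * phi[g, t]
  expect_lt(max(abs(Phi - brute)), 1e-12)
  expect_equal(colSums(Phi), rep(1, M), tolerance = 1e-8)
  expect_error(mixture_gep(theta[1:2, ], phi), "mismatch")
})

test_that("rpkm implements counts * 1e9 / (length * depth)", {
  counts <- matrix(c(10, 999990), 2, 1,
                   dimnames = list(c("a", "b"), "s1"))
  lt <- gene_length_table(setNames(c(1000L, 2000L), c("a", "b")))
  out <- rpkm(counts, lt)
  expect_equal(out["a", 1], 10)
  expect_equal(rpkm(matrix(c(0, 100), 2, 1), c(500, 500))[1, 1], 0)
  # doubling counts only changes RPKM through the depth term
  expect_equal(rpkm(counts * 2, lt), rpkm(counts, lt))
  expect_error(rpkm(counts, c(1000)), "registry")
})

test_that("eta estimation is the per-type replicate mean and is consistent", {
  expect_equal(estimate_eta_from_pure_counts(list(t1 = 100, t2 = 200)),
               c(t1 = 100, t2 = 200))
  expect_equal(unname(estimate_eta_from_pure_counts(list(t1 = c(90, 110)))), 100)
  expect_error(estimate_eta_from_pure_counts(list()), "non-empty")
  expect_error(estimate_eta_from_pure_counts(list(t1 = numeric(0))), "replicate")

  set.seed(3)
  lambda <- 250
  totals <- rpois(1e4, lambda)
  est <- estimate_eta_from_pure_counts(list(a = totals))
  se <- sqrt(lambda / 1e4)
  expect_lt(abs(est - lambda), 3 * se)
})
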