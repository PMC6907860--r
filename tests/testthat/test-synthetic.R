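# Generative simulator: GEP and proportion draws, count simulation, and the
# benchmark scenario presets.

test_that("sample_geps draws simplex columns with controllable separation", {
  phi <- sample_geps(1000, 4, beta = 0.5, seed = 1)
  expect_equal(colSums(phi), setNames(rep(1, 4), colnames(phi)),
               tolerance = 1e-8)
  expect_true(all(phi >= 0))
  # symmetric Dirichlet: entries average 1/G
  expect_equal(mean(phi), 1 / 1000, tolerance = 1e-6)

  sep <- sample_geps(1000, 4, seed = 2, separation = 1)
  cors <- cor(sep)
  expect_lt(max(cors[upper.tri(cors)]), 0.1)

  cor8 <- cor(sample_geps(1000, 4, seed = 3, separation = -0.8))
  expect_gt(min(cor8[upper.tri(cor8)]), 0.5)
  expect_error(sample_geps(3, 5), "G >= T")
  expect_error(sample_geps(10, 2, separation = 2), "separation")
})

test_that("sample_proportions concentrates and sparsifies as alpha dictates", {
  th <- sample_proportions(30, 5, alpha = 1e4, seed = 1)
  expect_equal(colSums(th), setNames(rep(1, 30), colnames(th)),
               tolerance = 1e-8)
  expect_lt(max(abs(th - 1 / 5)), 0.01)

  sparse <- sample_proportions(50, 5, alpha = 0.1, seed = 2)
  expect_gt(mean(apply(sparse, 2, max) > 0.5), 0.6)

  expect_identical(sample_proportions(5, 3, seed = 9),
                   sample_proportions(5, 3, seed = 9))
})

test_that("simulated counts follow the mixture distribution", {
  # T = 1, uniform sampling-scale GEP over 4 genes: binomial moments
  lt <- gene_length_table(setNames(rep(1000L, 4), paste0("gene_", 1:4)))
  phi <- matrix(0.25, 4, 1, dimnames = list(paste0("gene_", 1:4), "true_1"))
  theta <- matrix(1, 1, 1, dimnames = list("true_1", "sample_1"))
  truth <- bulkdecon:::.make_truth(phi, theta, 1, lt, 40000L, 5, "adhoc")
  counts <- simulate_counts(truth)
  expect_equal(sum(counts), 40000)
  expect_true(all(abs(counts - 1e4) < 3 * sqrt(1e4 * 0.75)))

  # general case: empirical frequencies near the mixture GEP at N = 1e6
  G <- 50
  lt2 <- bulkdecon:::.sample_gene_lengths(G, seed = 4)
  phi2 <- sample_geps(G, 3, seed = 4)
  theta2 <- sample_proportions(1, 3, alpha = 2, seed = 5)
  truth2 <- bulkdecon:::.make_truth(phi2, theta2, c(1, 2, 0.5), lt2, 1e6L, 6, "adhoc")
  counts2 <- simulate_counts(truth2)
  phi_s <- apply(phi2, 2, phi_to_sampling, eff_lengths = lt2$effective_length)
  mix <- as.vector(phi_s %*% truth2$theta_rna[, 1])
  freq <- counts2[, 1] / 1e6
  # 4-sigma bound: 50 genes are checked simultaneously
  tol <- 4 * sqrt(mix * (1 - mix) / 1e6)
  expect_true(all(abs(freq - mix) <= tol + 1e-9))
  expect_gt(mean(abs(freq - mix) <= 3 * sqrt(mix * (1 - mix) / 1e6) + 1e-9), 0.9)
})

test_that("per-read and marginalized simulation paths are distribution-equal", {
  # many small iid samples; pool gene totals and compare with a chi-square
  G <- 5
  lt <- gene_length_table(setNames(c(600L, 1200L, 2500L, 5000L, 900L),
                                   paste0("gene_", 1:G)))
  phi <- sample_geps(G, 2, beta = 1, seed = 7)
  theta <- matrix(rep(c(0.3, 0.7), 200), 2, 200,
                  dimnames = list(paste0("true_", 1:2), paste0("sample_", 1:200)))
  truth <- bulkdecon:::.make_truth(phi, theta, c(1, 2), lt, rep(50L, 200), 8, "adhoc")
  fast <- rowSums(simulate_counts(truth, method = "multinomial"))
  slow <- rowSums(simulate_counts(truth, method = "per_read"))
  p <- suppressWarnings(chisq.test(cbind(fast, slow))$p.value)
  expect_gt(p, 1e-4)
})

test_that("benchmark presets honour their designs and are seed-deterministic", {
  b6 <- make_benchmark("six_type_40", seed = 2, G = 120, depth = 2000)
  expect_equal(ncol(b6$truth$theta_cell), 40L)
  expect_equal(ncol(b6$truth$phi), 6L)
  expect_equal(b6$truth$eta, c(1, 1, 1, 3, 1, 2))
  expect_identical(b6$counts,
                   make_benchmark("six_type_40", seed = 2, G = 120,
                                  depth = 2000)$counts)

  bp <- make_benchmark("pure_panel", seed = 2, G = 100, depth = 1000)
  expect_equal(dim(bp$truth$theta_cell), c(8L, 8L))
  expect_true(all(bp$truth$theta_cell %in% c(0, 1)))
  expect_equal(unname(diag(bp$truth$theta_cell)), rep(1, 8))

  b4 <- make_benchmark("four_type_32", seed = 2, G = 80, depth = 500)
  expect_equal(ncol(b4$counts), 32L)
  expect_equal(colSums(b4$truth$theta_cell),
               setNames(rep(1, 32), colnames(b4$truth$theta_cell)),
               tolerance = 1e-12)
  expect_identical(tokens_to_counts(expand_counts(b4$counts)), b4$counts)

  bd <- make_benchmark("deep_correlated", seed = 2, G = 150, depth = 1000)
  expect_equal(ncol(bd$pure_counts), 8L)
  cc <- cor(bd$truth$phi)
  expect_gt(min(cc[upper.tri(cc)]), 0.5)
  expect_error(make_benchmark("nope"), "six_type_40")
})
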