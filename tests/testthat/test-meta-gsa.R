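test_that("weighted Fisher statistic evaluates Eq arithmetic exactly", {
  expect_equal(weighted_fisher(c(0.05, 0.05), c(1, 1)), -4 * log(0.05))
  expect_equal(weighted_fisher(c(0.05, 0.05), c(1, 1)), 11.9829, tolerance = 1e-4)
  expect_equal(weighted_fisher(rep(0.05, 4), rep(0.25, 4)), -2 * log(0.05))
  expect_equal(weighted_fisher(rep(0.05, 4), rep(0.25, 4)), 5.9915, tolerance = 1e-4)
  # a study at p = 1 contributes nothing regardless of weight
  expect_equal(weighted_fisher(c(1, 0.05), c(50, 1)),
               weighted_fisher(0.05, 1))
  # negative weights make M negative
  expect_lt(weighted_fisher(c(0.01, 0.9), c(-1, 0.2)), 0)
  expect_error(weighted_fisher(c(0.5, 0.5), 1), "length")
  expect_error(weighted_fisher(c(0, 0.5), c(1, 1)))
  # accepts a study_weights object directly
  w <- pca_weights(matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(weighted_fisher(c(0.1, 0.2), w),
               -2 * sum(0.375 * log(c(0.1, 0.2))))
})

test_that("unit-weight Fisher equals the SPP statistic", {
  set.seed(101)
  p <- runif(10)
  expect_equal(weighted_fisher(p, rep(1, 10)), spp(p)$m)
  expect_equal(pchisq(weighted_fisher(p, rep(1, 10)), df = 20,
                      lower.tail = FALSE),
               spp(p)$p)
})

test_that("pi0-corrected p-value follows the capped product rule", {
  expect_equal(adjust_meta_p(0.0001, 421, 1), 0.0421)
  # headline consistency: pi0 ~ 0.748 turns 1e-4 into ~0.0315
  expect_equal(adjust_meta_p(0.0001, 421, 0.748), 0.0315, tolerance = 1e-3)
  expect_equal(adjust_meta_p(0.5, 421, 1), 1)
  # monotone in each argument, capped at one
  expect_lte(adjust_meta_p(0.01, 10, 0.5), adjust_meta_p(0.02, 10, 0.5))
  expect_lte(adjust_meta_p(0.01, 10, 0.5), adjust_meta_p(0.01, 20, 0.5))
  expect_lte(adjust_meta_p(0.01, 10, 0.5), adjust_meta_p(0.01, 10, 0.9))
  expect_true(all(adjust_meta_p(runif(50), 421, 1) <= 1))
})

test_that("pi0 estimation recovers known null proportions", {
  set.seed(111)
  # pure null: pi0 near 1
  expect_gt(storey_pi0(runif(2000)), 0.85)
  # everything significant: clipped to a small positive value
  pi0_small <- storey_pi0(rep(1e-6, 400))
  expect_gt(pi0_small, 0)
  expect_lt(pi0_small, 0.01)
  # 50/50 mixture of uniform and near-zero point mass
  p_mix <- c(runif(1000), rep(1e-5, 1000))
  expect_equal(storey_pi0(p_mix), 0.5, tolerance = 0.05)
  expect_error(storey_pi0(numeric(0)))
})

test_that("permutation p-value has the add-one floor and null-evidence limit", {
  set.seed(121)
  universe <- random_profiles(40, 4, lam = 0)
  # M0 above every permuted statistic: p = 1/(n_perm + 1)
  pp <- permutation_pvalue(1e6, universe, 10, n_perm = 999)
  expect_equal(pp$p_permut, 1 / 1000)
  expect_equal(pp$n_perm_used, 999)
  # observed p_GS = 1 in all studies gives M0 = 0: p_permut near 1
  m0 <- weighted_fisher(rep(1, 4), rep(0.25, 4))
  expect_equal(m0, 0)
  expect_gt(permutation_pvalue(m0, universe, 10, n_perm = 999)$p_permut, 0.5)
  expect_error(permutation_pvalue(1, universe, 41, 99), "universe")
  # deterministic under a fixed seed
  set.seed(5); a <- permutation_pvalue(2, universe, 10, 499)$p_permut
  set.seed(5); b <- permutation_pvalue(2, universe, 10, 499)$p_permut
  expect_identical(a, b)
})

test_that("C++ permutation core agrees with the pure-R reference", {
  set.seed(131)
  universe <- random_profiles(30, 3, lam = 0.5)
  m_cpp <- metagsa:::perm_null_stats(universe, 8, 1500)
  m_r <- metagsa:::perm_null_r(universe, 8, 1500)
  expect_gt(suppressWarnings(ks.test(m_cpp, m_r))$p.value, 0.01)
  # degenerate draw: gs_size = n_genes makes the weights deterministic,
  # so the null mean is 2 * sum(w) (mean of -2 w ln U)
  w <- pca_weights(kendall_matrix(universe))$weights
  m_all <- metagsa:::perm_null_stats(universe, 30, 4000)
  expect_equal(mean(m_all), 2 * sum(w), tolerance = 0.05)
})

test_that("permutation p-values are uniform under the exact null", {
  set.seed(141)
  universe <- random_profiles(30, 3, lam = 0)
  n_perm <- 199
  p_obs <- vapply(1:2000, function(i) {
    m0 <- metagsa:::perm_null_stats(universe, 8, 1)
    m_null <- metagsa:::perm_null_stats(universe, 8, n_perm)
    (sum(m_null >= m0) + 1) / (n_perm + 1)
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(p_obs, "punif"))$p.value, 0.01)
  # rejection rate at 5% within the 99% binomial band
  band <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / 2000)
  expect_gt(mean(p_obs <= 0.05), band[1])
  expect_lt(mean(p_obs <= 0.05), band[2])
})

test_that("early stopping abandons clearly non-significant sets only", {
  set.seed(151)
  universe <- random_profiles(40, 4, lam = 0)
  # hopeless observed statistic: stops early with a large p
  pp <- permutation_pvalue(-5, universe, 10, n_perm = 5000, early_stop = TRUE)
  expect_lt(pp$n_perm_used, 5000)
  expect_gt(pp$p_permut, 0.25)
  # strong statistic: runs to completion
  pp2 <- permutation_pvalue(1e6, universe, 10, n_perm = 999, early_stop = TRUE)
  expect_equal(pp2$n_perm_used, 999)
  expect_equal(pp2$p_permut, 1 / 1000)
})

test_that("run_meta_gsa is deterministic and degrades gracefully", {
  set.seed(161)
  n_g <- 30
  ms <- do.call(rbind, lapply(paste0("s", 1:3), function(s) {
    data.frame(study = s, marker = sprintf("g%02d_m", 1:n_g),
               gene = sprintf("g%02d", 1:n_g),
               theta = rnorm(n_g, 0, 0.2), p = runif(n_g))
  }))
  sets <- list(SETA = sprintf("g%02d", 1:8), SETB = sprintf("g%02d", 11:20))
  gsa_p <- matrix(c(0.01, 0.03, 0.02, 0.8, 0.7, 0.9), nrow = 2, byrow = TRUE,
                  dimnames = list(c("SETA", "SETB"), paste0("s", 1:3)))
  r1 <- run_meta_gsa(ms, sets, gsa_p, n_perm = 199, seed = 9)
  r2 <- run_meta_gsa(ms, sets, gsa_p, n_perm = 199, seed = 9)
  expect_identical(r1, r2)
  expect_equal(r1$n_genes, c(8, 10))
  expect_true(all(r1$p_permut > 0 & r1$p_permut <= 1))
  expect_true(all(r1$p_meta <= 1))
  # two sets: pi0 estimated from the permutation p-values
  expect_true(all(r1$pi0 > 0 & r1$pi0 <= 1))
  # all observed GSA p-values at 1: no evidence, p_meta = 1
  gsa_null <- gsa_p; gsa_null[] <- 1
  r0 <- run_meta_gsa(ms, sets["SETA"], gsa_null, n_perm = 199, seed = 9)
  # M0 = 0; null statistics dip below zero only through negative weights,
  # so the permutation p is far in the non-significant range
  expect_gt(r0$p_permut, 0.5)
  expect_equal(r0$p_meta, r0$p_permut)  # n_GS = 1, pi0 = 1: no correction
  expect_equal(r0$pi0, 1)  # single set: no multiplicity correction
  # weights attribute carries per-set study weights
  expect_named(attr(r1, "weights"), c("SETA", "SETB"))
  expect_s3_class(attr(r1, "weights")$SETA, "study_weights")
})
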