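test_that("PDR combines significance and direction as d * (1 - p)", {
  expect_equal(pdr(0.05, 1), 0.95)
  expect_equal(pdr(1, -1), 0)
  expect_equal(pdr(0.2, -0.5), -0.4)
  expect_error(pdr(1.2, 1))
  expect_error(pdr(0.5, 2))
})

test_that("PDR is antisymmetric in direction and bounded", {
  set.seed(21)
  p <- runif(300)
  d <- runif(300, -1, 1)
  expect_equal(pdr(p, d), -pdr(p, -d))
  expect_true(all(abs(pdr(p, d)) <= 1))
  expect_true(all(pdr(p, 0) == 0))
})

test_that("best-marker aggregation selects the minimum p and orients by LD", {
  # same representative marker everywhere: d is the sign of theta
  st <- data.frame(study = c("s1", "s2"), marker = "mA",
                   theta = c(0.4, 0.2), p = c(0.01, 0.02))
  got <- best_marker_stat(st)
  expect_equal(got$p_g, c(0.01, 0.02))
  expect_equal(got$d_g, c(1, 1))
  # differing representatives: mean signed r with the other studies
  st <- data.frame(study = c("s1", "s2", "s3"),
                   marker = c("mA", "mB", "mC"),
                   theta = c(0.4, 0.3, 0.2), p = c(0.01, 0.02, 0.03))
  ld <- ld_table(data.frame(marker_a = c("mA", "mA", "mB"),
                            marker_b = c("mB", "mC", "mC"),
                            r = c(0.8, 0.4, 0.6)))
  got <- best_marker_stat(st, ld)
  expect_equal(got$d_g[1], +1 * mean(c(0.8, 0.4)))
  expect_equal(got$d_g[2], +1 * mean(c(0.8, 0.6)))
  # a representative in linkage equilibrium with all others: d = 0, pdr = 0
  ld0 <- ld_table(data.frame(marker_a = c("mA", "mA", "mB"),
                             marker_b = c("mB", "mC", "mC"),
                             r = c(0, 0, 0.9)))
  got0 <- best_marker_stat(st, ld0)
  expect_equal(got0$d_g[1], 0)
  expect_equal(pdr(got0$p_g[1], got0$d_g[1]), 0)
  # missing LD is an error naming the pair, not a silent r = 0
  ld_miss <- ld_table(data.frame(marker_a = "mA", marker_b = "mB", r = 0.8))
  expect_error(best_marker_stat(st, ld_miss), "mC")
  expect_error(best_marker_stat(st), "LD table")
  # p-value tie broken towards the lexicographically smallest marker id
  tie <- data.frame(study = "s1", marker = c("mB", "mA"),
                    theta = c(1, -1), p = c(0.05, 0.05))
  expect_equal(best_marker_stat(tie)$marker, "mA")
})

test_that("LD-block marker weights count independent markers", {
  full <- ld_table(data.frame(marker_a = c("a", "a", "b"),
                              marker_b = c("b", "c", "c"), r = 1))
  v <- marker_weights(c("a", "b", "c"), full)
  expect_equal(unname(v), rep(1 / 3, 3))
  expect_equal(sum(v), 1)
  # unlinked markers each count fully
  v <- marker_weights(c("a", "b"), NULL)
  expect_equal(unname(v), c(1, 1))
  # one block at r^2 = 0.5: v = 1/1.5 each
  half <- ld_table(data.frame(marker_a = "a", marker_b = "b",
                              r = sqrt(0.5)))
  v <- marker_weights(c("a", "b"), half)
  expect_equal(unname(v), c(1 / 1.5, 1 / 1.5))
  expect_equal(sum(v), 4 / 3)
  # sum of weights = number of blocks when blocks are clean
  two_blocks <- ld_table(data.frame(
    marker_a = c("a", "c"), marker_b = c("b", "d"), r = 1))
  v <- marker_weights(c("a", "b", "c", "d"), two_blocks)
  expect_equal(sum(v), 2)
})

test_that("averaging aggregation pools markers with the weighted Fisher sum", {
  # a single marker reduces to the marker itself, and agrees with the
  # best-marker strategy
  st <- data.frame(study = c("s1", "s2"), marker = "mA",
                   theta = c(0.4, -0.2), p = c(0.03, 0.2))
  avg <- averaged_gene_stat(st)
  best <- best_marker_stat(st)
  expect_equal(avg$p_g, best$p_g)
  expect_equal(avg$d_g, best$d_g)
  # two independent markers at p = 0.05: C = -2(2 ln 0.05), chi^2_4 tail
  st2 <- data.frame(study = "s1", marker = c("mA", "mB"),
                    theta = c(0.3, 0.2), p = c(0.05, 0.05))
  got <- averaged_gene_stat(st2)
  expect_equal(-2 * 2 * log(0.05), 11.98293, tolerance = 1e-4)
  expect_equal(got$p_g, pchisq(-4 * log(0.05), df = 4, lower.tail = FALSE))
  expect_equal(got$d_g, 1)
  # strict independent-markers mode references chi^2 with df = sum v
  ind <- averaged_gene_stat(st2, df_mode = "independent")
  expect_equal(ind$p_g, pchisq(-4 * log(0.05), df = 2, lower.tail = FALSE))
  # equal weights with opposite signs cancel to d = 0
  st3 <- data.frame(study = "s1", marker = c("mA", "mB"),
                    theta = c(0.3, -0.2), p = c(0.05, 0.05))
  expect_equal(averaged_gene_stat(st3)$d_g, 0)
  # promising filter that removes every marker flags the gene
  st4 <- data.frame(study = "s1", marker = c("mA", "mB"),
                    theta = c(0.3, 0.2), p = c(0.5, 0.6))
  got4 <- averaged_gene_stat(st4, promising_only = TRUE)
  expect_equal(got4$p_g, 1)
  expect_equal(got4$d_g, 0)
  expect_true(got4$flagged)
})

test_that("re-orientation aligns genes to the cross-study consensus", {
  d <- rbind(c(1, 1, -1), c(-1, -1, 1), c(1, -1, 0))
  got <- reorient_directions(d)
  expect_equal(got[1, ], c(1, 1, -1))     # positive mean: unchanged
  expect_equal(got[2, ], c(1, 1, -1))     # negative mean: negated
  expect_equal(got[3, ], c(1, -1, 0))     # zero mean: unchanged (tie rule)
  expect_true(all(rowMeans(got) >= 0))
  # idempotence on random direction matrices
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(runif(24, -1, 1), 6, 4)
    once <- reorient_directions(m)
    expect_identical(reorient_directions(once), once)
  }
})

test_that("PDR profiles are complete, sorted and order-invariant", {
  set.seed(41)
  p <- matrix(runif(40), 10, 4,
              dimnames = list(sprintf("g%02d", 10:1), paste0("s", 1:4)))
  d <- reorient_directions(matrix(sample(c(-1, 1), 40, TRUE), 10, 4,
                                  dimnames = dimnames(p)))
  prof <- build_pdr_profiles(p, d, rownames(p))
  expect_equal(dim(prof), c(10, 4))
  expect_identical(rownames(prof), sort(rownames(p)))
  # permuted input gene order gives the identical matrix
  ord <- sample(10)
  prof2 <- build_pdr_profiles(p[ord, ], d[ord, ], rownames(p))
  expect_equal(unclass(prof2), unclass(prof))
  # p = 1 everywhere gives the zero matrix
  p1 <- p; p1[] <- 1
  expect_true(all(build_pdr_profiles(p1, d, rownames(p)) == 0))
  # absent genes are dropped with a warning; all absent is an error
  expect_warning(pr <- build_pdr_profiles(p, d, c(rownames(p), "zz")),
                 "dropped")
  expect_equal(nrow(pr), 10)
  expect_error(build_pdr_profiles(p, d, c("zz", "yy")), "no gene")
  # incomplete profiles (gene missing in one study) are an error
  p_na <- p; p_na[1, 2] <- NA
  expect_error(build_pdr_profiles(p_na, d, rownames(p)), "complete")
})

test_that("gene_level_stats assembles matrices for every strategy", {
  ms <- gene_stats_fixture()
  ms$gene <- rep("gX", nrow(ms))
  for (agg in c("best", "all", "promising")) {
    gl <- gene_level_stats(ms, ld = NULL, aggregation = agg)
    expect_equal(dim(gl$p), c(1, 3))
    expect_equal(dim(gl$d), c(1, 3))
    expect_true(all(gl$p >= 0 & gl$p <= 1, na.rm = TRUE))
  }
})
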