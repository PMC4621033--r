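# shared helpers: brute-force oracles and cached scenario runs

# brute-force Kendall tau-b: count concordant minus discordant pairs over
# all untied pairs, tie-corrected denominator
brute_kendall <- function(x, y) {
  n <- length(x)
  num <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0) tx <- tx + 1
    if (dy == 0) ty <- ty + 1
    if (dx != 0 && dy != 0) num <- num + sign(dx) * sign(dy)
  }
  n0 <- n * (n - 1) / 2
  num / sqrt((n0 - tx) * (n0 - ty))
}

# random PDR-profile matrix with a common latent pattern (concordant
# studies); lam = 0 gives independent profiles
random_profiles <- function(n_genes, n_studies, lam = 0.7) {
  common <- runif(n_genes, -1, 1)
  m <- vapply(seq_len(n_studies), function(s) {
    x <- lam * common + (1 - lam) * runif(n_genes, -1, 1)
    pmax(pmin(x, 1), -1)
  }, numeric(n_genes))
  rownames(m) <- sprintf("g%02d", seq_len(n_genes))
  m
}

# marker-stats table for multi-marker gene tests
gene_stats_fixture <- function() {
  data.frame(
    study = rep(c("s1", "s2", "s3"), each = 3),
    marker = rep(c("mA", "mB", "mC"), times = 3),
    theta = c(0.5, 0.2, -0.1, 0.4, 0.3, -0.2, 0.6, 0.1, -0.3),
    p = c(0.01, 0.20, 0.50, 0.02, 0.05, 0.40, 0.03, 0.30, 0.60))
}

# scenario runs shared between acceptance blocks (each is expensive)
.scenario_cache <- new.env(parent = emptyenv())
cached_scenario <- function(id, n_sim, n_perm = 499, seed = NULL) {
  key <- sprintf("s%d_%d_%d", id, n_sim, n_perm)
  if (is.null(.scenario_cache[[key]])) {
    spec <- scenario_registry()[[id]]$spec
    .scenario_cache[[key]] <- run_scenario(
      spec, n_sim = n_sim, n_perm = n_perm,
      seed = if (is.null(seed)) 20000 + id else seed)
  }
  .scenario_cache[[key]]
}
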