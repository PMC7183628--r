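test_that("coupling graph construction honours lattice, count and determinism", {
  g0 <- make_coupling_graph(19, 4, 0.0, seed = 3)
  expect_equal(nrow(g0$edges), 19 * 4)
  outdeg <- table(factor(g0$edges[, "source"], levels = 1:19))
  expect_true(all(outdeg == 4))
  # ring lattice: neighbours within 2 ring steps
  d <- abs(g0$edges[, 1] - g0$edges[, 2])
  expect_true(all(pmin(d, 19 - d) <= 2))

  g1 <- make_coupling_graph(19, 4, 1.0, seed = 3)
  expect_equal(nrow(g1$edges), 19 * 4)
  expect_false(identical(g0$edges, g1$edges))

  ga <- make_coupling_graph(19, 4, 0.1, seed = 11)
  gb <- make_coupling_graph(19, 4, 0.1, seed = 11)
  expect_identical(ga$edges, gb$edges)

  expect_error(make_coupling_graph(19, 20, 0.1, seed = 1), "mean_degree")
  expect_error(make_coupling_graph(19, 3, 0.1, seed = 1), "even")
})

test_that("graph_to_mvar respects sparsity, coupling weights and stability", {
  empty <- coupling_graph(4, matrix(integer(), 0, 2))
  m <- graph_to_mvar(empty, stage_profile("W"), fs = 200, seed = 5)
  for (k in seq_len(m$p)) {
    off <- m$A[, , k]; diag(off) <- 0
    expect_equal(max(abs(off)), 0)
  }

  g2 <- coupling_graph(2, matrix(c(1L, 2L), 1, 2), weights = 0.4)
  pr <- stage_profile("W", rewiring_prob = 0, coupling_strength = 1)
  m2 <- graph_to_mvar(g2, pr, order = 1, fs = 200, seed = 1)
  expect_equal(m2$A[2, 1, 1], 0.4)
  expect_equal(m2$A[1, 2, 1], 0)

  set.seed(99)
  for (r in 1:100) {
    st <- sample(c("W", "3", "4", "REM"), 1)
    g <- make_coupling_graph(sample(5:19, 1), 4, stats::runif(1), seed = NULL)
    mm <- graph_to_mvar(g, stage_profile(st,
                          coupling_strength = stats::runif(1, 0, 0.6)),
                        fs = 200, stability_margin = 0.95)
    expect_lte(var_spectral_radius(mm), 0.95 + 1e-8)
  }
})

test_that("simulated recordings have the requested layout and are seed-reproducible", {
  g <- make_coupling_graph(19, 4, 0.1, seed = 2)
  m <- graph_to_mvar(g, stage_profile("REM"), fs = 200, seed = 2)
  sim <- simulate_recording(list(REM = m), rep("REM", 9), fs = 200, seed = 7)
  expect_equal(ncol(sim$recording$samples), 180 * 200)
  expect_equal(nrow(sim$hypnogram), 9)
  expect_true(all(sim$hypnogram$stage == "REM"))

  sim2 <- simulate_recording(list(REM = m), rep("REM", 9), fs = 200, seed = 7)
  expect_identical(sim$recording$samples, sim2$recording$samples)
  expect_identical(sim$artifact_mask, sim2$artifact_mask)

  sim3 <- simulate_recording(list(REM = m), rep("REM", 5), fs = 200, seed = 1,
                             artifact_fraction = 0)
  expect_true(all(sim3$artifact_mask$clean))

  expect_error(simulate_recording(list(REM = m), c("REM", "W"), fs = 200,
                                  seed = 1), "no model for stage")
  expect_error(simulate_recording(list(REM = m), rep("REM", 4), fs = 50,
                                  seed = 1), "64")
})

test_that("BDI-13 scoring sums items and labels severity", {
  expect_equal(score_bdi(rep(3, 13))$score, 39)
  z <- score_bdi(rep(0, 13))
  expect_equal(z$score, 0)
  expect_equal(z$severity, "absence of depression")
  expect_equal(score_bdi(c(1, 1, 1, rep(0, 10)))$score, 3)
  expect_equal(score_bdi(c(rep(2, 8), rep(0, 5)))$severity, "severe")
  expect_error(score_bdi(rep(1, 12)), "13")
  expect_error(score_bdi(c(rep(1, 12), 4)), "0..3")
})

test_that("cohorts have the configured composition and are deterministic", {
  cfg <- cohort_config(seed = 5)
  co <- make_cohort(cfg, keep_signals = FALSE)
  expect_length(co, 44)
  sexes <- vapply(co, function(b) b$record$sex, "")
  expect_equal(sum(sexes == "M"), 28)
  expect_equal(sum(sexes == "F"), 16)
  expect_true(all(vapply(co, function(b) b$record$bdi, 0) %in% 0:39))
  # stage-3/4 topology identical across sexes; REM differs by sex in the mean
  sws <- vapply(co, function(b) b$record$rewire[["3"]], 0)
  expect_true(all(sws == cfg$sws_rewire))

  co2 <- make_cohort(cfg, keep_signals = FALSE)
  expect_identical(co, co2)
})

test_that("perfect rank coupling makes women's BDI monotone in REM rewiring", {
  co <- make_cohort(cohort_config(bdi_omega_rho_women = 1, seed = 9),
                    keep_signals = FALSE)
  rec <- Filter(function(b) b$record$sex == "F", co)
  p_rem <- vapply(rec, function(b) b$record$rewire[["REM"]], 0)
  bdi <- vapply(rec, function(b) b$record$bdi, 0)
  expect_true(all(diff(bdi[order(p_rem)]) >= 0))
})

test_that("rank-coupling calibration lands in the target window at n = 16", {
  hits <- 0L
  for (s in 1:50) {
    co <- make_cohort(cohort_config(seed = 1000 + s), keep_signals = FALSE)
    f <- Filter(function(b) b$record$sex == "F", co)
    rho <- suppressWarnings(stats::cor(
      vapply(f, function(b) b$record$rewire[["REM"]], 0),
      vapply(f, function(b) b$record$bdi, 0), method = "spearman"))
    if (rho > 0.2 && rho < 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 45)  # >= 90% of 50 seeds
})

test_that("a zeroed coupling gives no women BDI-topology association", {
  nonsig <- 0L
  for (s in 1:20) {
    co <- make_cohort(cohort_config(bdi_omega_rho_women = 0, seed = 3000 + s),
                      keep_signals = FALSE)
    f <- Filter(function(b) b$record$sex == "F", co)
    sc <- spearman_cor(vapply(f, function(b) b$record$rewire[["REM"]], 0),
                       vapply(f, function(b) b$record$bdi, 0))
    if (!sc$defined || sc$p > 0.05) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 18)  # >= 90% of 20 seeds under the null
})
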