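test_that("Whittle recursion recovers a VAR exactly from its autocovariance", {
  set.seed(21)
  m <- random_stable_model(3, 2)
  G <- var_autocov(m, 6)
  w <- whittle_var(G[, , 1:3])
  expect_equal(w$A, m$A, tolerance = 1e-10)
  expect_equal(w$Sigma, m$Sigma, tolerance = 1e-10)
})

test_that("multi-trial least squares is consistent at the protocol sample size", {
  set.seed(22)
  m <- random_stable_model(3, 2, sd = 0.3)
  segs <- lapply(1:12, function(i) var_simulate(m, 1000))
  fit <- fit_mvar(segs, 2)
  expect_lte(max(abs(fit$A - m$A)), 0.05)
  expect_equal(fit$n_obs_effective, 12 * 998)
  # off-diagonal coefficients of an independent-channel process stay within
  # sampling noise
  ind <- mvar_model(array(diag(3) * 0.5, c(3, 3, 1)), diag(3), fs = 100)
  segs0 <- lapply(1:12, function(i) var_simulate(ind, 1000))
  f0 <- fit_mvar(segs0, 1)
  off <- abs(f0$A[, , 1][row(diag(3)) != col(diag(3))])
  expect_lte(mean(off > 3 / sqrt(f0$n_obs_effective)), 0.05)
})

test_that("a noiseless deterministic recursion is recovered to machine precision", {
  # pure rotation over a whole number of periods: zero-mean trajectory that
  # satisfies x_t = R x_{t-1} exactly
  Tn <- 400
  th <- 2 * pi * 5 / Tn
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  X <- matrix(0, 2, Tn); X[, 1] <- c(1, 0)
  for (t in 2:Tn) X[, t] <- R %*% X[, t - 1]
  fit <- fit_mvar(list(X), 1)
  expect_lt(max(abs(fit$A[, , 1] - R)), 1e-8)
})

test_that("BIC selects the true order for strong VAR(3) data and order 1 for noise", {
  set.seed(23)
  A <- array(0, c(2, 2, 3))
  A[, , 1] <- matrix(c(0.3, 0.2, 0, 0.25), 2, 2)
  A[, , 3] <- diag(2) * 0.4
  m <- mvar_model(A, diag(2), fs = 100)
  segs <- lapply(1:12, function(i) var_simulate(m, 1000))
  expect_equal(as.integer(select_model_order(segs, 8, "BIC")), 3L)
  expect_identical(select_model_order(segs, 8, "BIC"),
                   select_model_order(segs, 8, "BIC"))

  wn <- lapply(1:12, function(i) matrix(rnorm(2 * 1000), 2))
  pw <- select_model_order(wn, 6, "BIC")
  expect_equal(as.integer(pw), 1L)
  expect_lte(max(abs(fit_mvar(wn, as.integer(pw))$A)), 0.05)
})

test_that("time-domain causality matches the population Yule-Walker value", {
  # x <- y but not y <- x, known coefficients; population oracle solved from
  # closed-form autocovariances (Lyapunov by Kronecker inversion + Toeplitz
  # Yule-Walker), an independent code path
  A <- matrix(c(0.5, 0.4, 0, 0.7), 2, 2, byrow = TRUE)
  Sig <- diag(2)
  G0 <- matrix(solve(diag(4) - kronecker(A, A), as.numeric(Sig)), 2, 2)
  q <- 40
  gx <- numeric(q + 1); Gk <- G0
  gx[1] <- G0[1, 1]
  for (k in 1:q) { Gk <- A %*% Gk; gx[k + 1] <- Gk[1, 1] }
  a <- solve(stats::toeplitz(gx[1:q]), gx[2:(q + 1)])
  F_oracle <- log(gx[1] - sum(a * gx[2:(q + 1)]))

  m <- mvar_model(array(A, c(2, 2, 1)), Sig, fs = 100)
  Ft <- gc_time_from_model(m, reduced_order = q)
  expect_equal(Ft[2, 1], F_oracle, tolerance = 1e-6)
  expect_equal(Ft[1, 2], 0)
  expect_equal(diag(unclass(Ft)), c(0, 0))
})

test_that("independent channels yield a null causality matrix", {
  set.seed(24)
  ind <- mvar_model(array(diag(4) * 0.4, c(4, 4, 1)), diag(4), fs = 100)
  segs <- lapply(1:12, function(i) var_simulate(ind, 1000))
  Ft <- gc_time_matrix(segs, 1, reduced_order = 10)
  expect_lte(max(Ft), 0.01)
  expect_true(all(unclass(Ft) >= 0))
})

test_that("Granger causality is invariant to common amplitude rescaling", {
  set.seed(25)
  m <- random_stable_model(4, 2)
  segs <- lapply(1:6, function(i) var_simulate(m, 500))
  F1 <- gc_time_matrix(segs, 2, reduced_order = 8)
  F2 <- gc_time_matrix(lapply(segs, function(s) s * 37.3), 2, reduced_order = 8)
  expect_lt(max(abs(F1 - F2)), 1e-8)
})

test_that("the MVAR spectrum has its closed forms and satisfies Parseval", {
  S0 <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  white <- mvar_model(array(0, c(2, 2, 1)), S0, fs = 100)
  sp <- mvar_spectrum(white, c(0, 10, 50), 100)
  for (k in 1:3) expect_equal(Re(sp$S[, , k]), S0, tolerance = 1e-12)

  ar1 <- mvar_model(array(0.9, c(1, 1, 1)), matrix(1, 1, 1), fs = 100)
  sp1 <- mvar_spectrum(ar1, c(0, 50), 100)
  expect_equal(Re(sp1$S[1, 1, 1]), 1 / (1 - 0.9)^2, tolerance = 1e-12)
  expect_lt(Re(sp1$S[1, 1, 2]), Re(sp1$S[1, 1, 1]))

  set.seed(26)
  m <- random_stable_model(3, 2)
  fr <- seq(0, 64, length.out = 2049)
  spm <- mvar_spectrum(m, fr, 128)
  v_spec <- vapply(1:3, function(i)
    somnonet:::trapz(fr, Re(spm$S[i, i, ])) / 64, 0)
  v_true <- diag(var_autocov(m, 0)[, , 1])
  expect_equal(v_spec, v_true, tolerance = 0.01)
})

test_that("spectral causality localizes the bivariate example and nulls reverse flow", {
  A <- array(0, c(2, 2, 1))
  A[1, 1, 1] <- 0.5; A[1, 2, 1] <- 0.4; A[2, 2, 1] <- 0.7
  m <- mvar_model(A, diag(2), fs = 100)
  sc <- gc_spectral_from_model(m, n_freqs = 256, reduced_order = 30)
  f_fwd <- sc$values[2, 1, ]   # y -> x
  expect_gt(mean(f_fwd[sc$freqs < 10]), mean(f_fwd[sc$freqs > 40]))
  expect_lte(max(sc$values[1, 2, ]), 0.01)
  expect_true(all(sc$values >= 0))
})

test_that("band integration averages correctly and tiles the full range", {
  set.seed(27)
  m <- random_stable_model(3, 2, fs = 128)
  sc <- gc_spectral_from_model(m, n_freqs = 512, reduced_order = 20)

  # constant spectrum: band mean equals the constant
  scc <- sc
  scc$values[] <- 0.37
  for (b in names(band_set()))
    expect_equal(max(abs(integrate_band(scc, b) -
                           0.37 * (1 - diag(3)))), 0, tolerance = 1e-12)

  # bandwidth-weighted band means + residual ranges = full-range integral
  full <- integrate_band(sc, c(0, 64), name = "full")
  parts <- c(list(c(0, 0.25)), unname(band_set()), list(c(32, 64)))
  acc <- matrix(0, 3, 3)
  for (b in parts)
    acc <- acc + unclass(integrate_band(sc, b)) * (b[2] - b[1])
  expect_equal(acc / 64, unclass(full), tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(integrate_band(sc, c(40, 80)), "outside")
})

test_that("frequency-integrated causality reproduces the time-domain value", {
  set.seed(28)
  m <- random_stable_model(4, 3, fs = 128)
  ro <- 24
  tm <- gc_time_from_model(m, reduced_order = ro)
  sc <- gc_spectral_from_model(m, n_freqs = 1024, reduced_order = ro)
  ck <- check_integration(sc, tm)
  expect_true(ck$pass)
  expect_lte(ck$max_rel_diff, 0.01)
})

test_that("the integration check reports offending pairs on a mismatch", {
  sc <- structure(list(freqs = seq(0, 50, length.out = 64),
                       values = array(0.2, c(2, 2, 64))),
                  class = "spectral_connectivity")
  tm <- connectivity_matrix(matrix(c(0, 0.2, 0.25, 0), 2, 2), "time")
  ck <- check_integration(sc, tm)
  expect_false(ck$pass)
  expect_equal(nrow(ck$offenders), 1)
  # null vs null passes vacuously
  sc0 <- sc; sc0$values[] <- 0
  tm0 <- connectivity_matrix(matrix(0, 2, 2), "time")
  expect_true(check_integration(sc0, tm0)$pass)
})

test_that("per-subject orchestration yields six matrices per usable stage", {
  set.seed(29)
  sub <- tiny_subject(seed = 31, stages = c("W", "REM"), epochs = 4)
  es <- list(
    W = extract_stage_epochs(sub$recording, sub$hypnogram, sub$artifact_mask,
                             "W", subject_id = "T01"),
    REM = extract_stage_epochs(sub$recording, sub$hypnogram, sub$artifact_mask,
                               "REM", subject_id = "T01"))
  conn <- connectivity_per_subject(es, settings = list(
    order = 4, reduced_order = 8, n_freqs = 128, spectral = TRUE))
  expect_setequal(names(conn$stages), c("W", "REM"))
  for (st in names(conn$stages)) {
    entry <- conn$stages[[st]]
    expect_equal(dim(entry$time), c(19, 19))
    expect_length(entry$bands, 5)
    expect_true(entry$check$pass)
  }
  # an unusable stage becomes a missing record, not a failure
  es$REM <- simpleError("bad stage")
  conn2 <- connectivity_per_subject(es, settings = list(
    order = 4, reduced_order = 4, spectral = FALSE))
  expect_equal(conn2$missing, "REM")
  expect_named(conn2$stages, "W")
})
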