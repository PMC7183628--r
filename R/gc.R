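#' Canonical EEG frequency bands
#'
#' The five classical EEG bands used for band-resolved connectivity, with
#' contiguous half-open edges `[lo, hi)` in Hz: delta \[0.25, 3), theta
#' \[3, 8), alpha \[8, 12), sigma \[12, 16), beta \[16, 32).
#'
#' @return Named list of `c(lo, hi)` intervals in Hz.
#' @export
band_set <- function() {
  list(delta = c(0.25, 3), theta = c(3, 8), alpha = c(8, 12),
       sigma = c(12, 16), beta = c(16, 32))
}

connectivity_matrix <- function(values, domain, labels = NULL) {
  diag(values) <- 0
  if (!is.null(labels)) dimnames(values) <- list(source = labels, target = labels)
  structure(values, class = c("connectivity_matrix", "matrix"),
            domain = domain)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("%dx%d Granger-causality matrix (source x target), domain '%s'\n",
              nrow(x), ncol(x), attr(x, "domain")))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))], digits = 3)
  invisible(x)
}

# Clamp small numerical negatives; anything substantially negative is a bug
# upstream and is surfaced.
clamp_nonneg <- function(x, floor = -1e-10) {
  bad <- x < floor
  x[x < 0] <- 0
  attr(x, "n_clamped_large") <- sum(bad)
  x
}

#' Time-domain conditional Granger causality from a fitted model
#'
#' For every ordered channel pair (j -> i), computes
#' \eqn{F = \ln(\Sigma'_{ii} / \Sigma_{ii})} where \eqn{\Sigma'_{ii}} is the
#' innovation variance of channel i in the reduced model with channel j's
#' past removed (conditional on all remaining channels) and
#' \eqn{\Sigma_{ii}} is the full-model innovation variance.  Reduced models
#' are derived from the full model's autocovariance sequence
#' ([var_reduced_model()]).
#'
#' @param model an `mvar_model`.
#' @param reduced_order order of the reduced-model approximation; larger
#'   values are more faithful (default `max(p, 20)`).
#' @return A `connectivity_matrix` with `values[j, i] = F(j -> i)`, diagonal 0.
#' @export
gc_time_from_model <- function(model, reduced_order = max(model$p, 20L)) {
  n <- model$n
  G <- var_autocov(model, reduced_order)
  Fm <- matrix(0, n, n)
  s2 <- diag(model$Sigma)
  for (j in seq_len(n)) {
    keep <- setdiff(seq_len(n), j)
    red <- whittle_var(G[keep, keep, , drop = FALSE])
    Fm[j, keep] <- log(diag(red$Sigma) / s2[keep])
  }
  connectivity_matrix(clamp_nonneg(Fm), "time", model$labels)
}

#' Time-domain Granger-causality connectivity matrix from epoch data
#'
#' Fits one pooled multi-trial MVAR model to the segments and evaluates
#' pairwise-conditional time-domain Granger causality.
#'
#' @inheritParams fit_mvar
#' @inheritParams gc_time_from_model
#' @return A `connectivity_matrix` (`values[source, target]`).
#' @export
gc_time_matrix <- function(es, p, reduced_order = max(p, 20L), fs = NULL) {
  gc_time_from_model(fit_mvar(es, p, fs = fs), reduced_order = reduced_order)
}

# AR polynomial A(lambda) = I - sum_k A_k z^k, z = exp(-2 pi i f k / fs),
# evaluated on a frequency grid; returns n x n x nf complex array.
var_arpoly <- function(A, freqs, fs) {
  n <- dim(A)[1]; p <- dim(A)[3]; nf <- length(freqs)
  z <- exp(-2i * pi * outer(seq_len(max(p, 1L)), freqs) / fs)  # p x nf
  out <- array(0i, c(n, n, nf))
  I <- diag(n)
  for (k in seq_len(nf)) {
    Af <- I + 0i
    for (l in seq_len(p)) Af <- Af - A[, , l] * z[l, k]
    out[, , k] <- Af
  }
  out
}

#' Transfer function and cross-spectral density of an MVAR model
#'
#' \eqn{H(\lambda) = A(\lambda)^{-1}} with
#' \eqn{A(\lambda) = I - \sum_k A_k e^{-2\pi i \lambda k / f_s}}, and
#' \eqn{S(\lambda) = H \Sigma H^*}.  `S` is Hermitian positive-semidefinite at
#' every frequency; with the two-sided normalization used here the average of
#' `S` over `[0, fs/2]` equals the process covariance.
#'
#' @param model an `mvar_model`.
#' @param freqs frequency grid in Hz, within `[0, fs/2]`.
#' @param fs sampling rate in Hz; defaults to the model's.
#' @return List with `freqs`, `H` and `S` (both `n x n x nf` complex arrays).
#' @export
mvar_spectrum <- function(model, freqs, fs = model$fs) {
  if (is.null(fs)) stop("sampling rate required", call. = FALSE)
  Ap <- var_arpoly(model$A, freqs, fs)
  n <- model$n; nf <- length(freqs)
  H <- array(0i, c(n, n, nf)); S <- array(0i, c(n, n, nf))
  for (k in seq_len(nf)) {
    Hk <- tryCatch(solve(Ap[, , k]), error = function(e)
      stop(sprintf("AR polynomial numerically singular at %.3f Hz", freqs[k]),
           call. = FALSE))
    H[, , k] <- Hk
    S[, , k] <- Hk %*% model$Sigma %*% Conj(t(Hk))
  }
  list(freqs = freqs, H = H, S = S)
}

#' Spectral (frequency-domain) conditional Granger causality
#'
#' Geweke conditional spectral causality \eqn{f_{j \to i | rest}(\lambda)}
#' for every ordered pair, computed by embedding the reduced model (channel j
#' removed) in the full model's innovation space: with reduced AR polynomial
#' \eqn{A^R(\lambda)} (identity on channel j) and
#' \eqn{Q(\lambda) = A^R(\lambda) H(\lambda)}, the spectrum of the reduced
#' innovation process is \eqn{S^w(\lambda) = Q \Sigma Q^*} and
#' \deqn{f_{j \to i|rest}(\lambda) = \ln \frac{S^w_{ii}(\lambda)}
#'   {S^w_{ii}(\lambda) - |Q_{ij}(\lambda)|^2\, \Sigma_{jj|rest}},}
#' where \eqn{\Sigma_{jj|rest} = 1/(\Sigma^{-1})_{jj}} is the partial
#' variance of channel j's innovations given all others.  Averaged over
#' `[0, fs/2]` this recovers the time-domain value (Geweke decomposition;
#' see [check_integration()]).
#'
#' @param model an `mvar_model` with a sampling rate.
#' @param n_freqs number of uniform grid points on `[0, fs/2]` (>= 64).
#' @param reduced_order order of the reduced-model approximation.
#' @param fs sampling rate in Hz.
#' @return Object of class `spectral_connectivity`: list with `freqs` (Hz)
#'   and `values`, an `n x n x n_freqs` array, `values[j, i, ]` the spectral
#'   causality j -> i (clamped at 0 from below).
#' @export
gc_spectral_from_model <- function(model, n_freqs = 1024L, fs = model$fs,
                                   reduced_order = max(model$p, 20L)) {
  if (is.null(fs)) stop("sampling rate required", call. = FALSE)
  n_freqs <- as.integer(n_freqs)
  stopifnot(n_freqs >= 64L)
  n <- model$n
  freqs <- seq(0, fs / 2, length.out = n_freqs)
  H <- mvar_spectrum(model, freqs, fs)$H
  G <- var_autocov(model, reduced_order)
  vals <- array(0, c(n, n, n_freqs))
  s2 <- diag(model$Sigma)
  for (j in seq_len(n)) {
    keep <- setdiff(seq_len(n), j)
    red <- whittle_var(G[keep, keep, , drop = FALSE])
    q <- dim(red$A)[3]
    zp <- exp(-2i * pi * outer(seq_len(q), freqs) / fs)  # q x nf
    Ar <- matrix(red$A, (n - 1L)^2, q)                   # flattened lag stack
    # Q(lambda) = AR_embedded(lambda) %*% H(lambda), all frequencies
    Q <- array(0i, c(n, n, n_freqs))
    for (k in seq_len(n_freqs)) {
      B <- diag(n) + 0i
      B[keep, keep] <- B[keep, keep] -
        matrix(Ar %*% zp[, k], n - 1L, n - 1L)
      Q[, , k] <- B %*% H[, , k]
    }
    sr <- diag(red$Sigma)
    for (idx in seq_along(keep)) {
      i <- keep[idx]
      u <- model$Sigma[, i] / s2[i]; u[i] <- 0
      Qi <- matrix(Q[i, , ], n, n_freqs)
      qt <- Q[i, i, ] + colSums(Qi * u)
      den <- Re(qt * Conj(qt)) * s2[i]
      if (any(den <= 0))
        stop(sprintf("spectral factorization failure for pair %d -> %d", j, i),
             call. = FALSE)
      vals[j, i, ] <- pmax(log(sr[idx] / den), 0)
    }
  }
  structure(list(freqs = freqs, values = vals, fs = fs,
                 labels = model$labels),
            class = "spectral_connectivity")
}

#' @export
print.spectral_connectivity <- function(x, ...) {
  cat(sprintf("Spectral Granger causality: %d pairs x %d frequencies on [0, %.1f] Hz\n",
              dim(x$values)[1] * (dim(x$values)[1] - 1L), length(x$freqs),
              max(x$freqs)))
  invisible(x)
}

#' Spectral Granger-causality matrices from epoch data
#'
#' @inheritParams fit_mvar
#' @inheritParams gc_spectral_from_model
#' @export
gc_spectral_matrix <- function(es, p, n_freqs = 1024L, fs = NULL,
                               reduced_order = max(p, 20L)) {
  m <- fit_mvar(es, p, fs = fs)
  gc_spectral_from_model(m, n_freqs = n_freqs, reduced_order = reduced_order)
}

# trapezoidal integral of y over x
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Band-average a spectral connectivity object
#'
#' Per-pair trapezoidal mean of the spectral causality over a frequency band
#' (integral divided by bandwidth).  Band edges falling between grid points
#' are handled by linear interpolation, so contiguous bands tile the full
#' range additively.
#'
#' @param sc a `spectral_connectivity`.
#' @param band numeric `c(lo, hi)` in Hz, within `[0, max(freqs)]`, or the
#'   name of a [band_set()] band.
#' @param name domain tag for the result; defaults to the band name or
#'   `"lo-hi Hz"`.
#' @return A `connectivity_matrix` tagged with the band name.
#' @export
integrate_band <- function(sc, band, name = NULL) {
  if (is.character(band)) {
    name <- if (is.null(name)) band else name
    band <- band_set()[[band]]
    if (is.null(band)) stop("unknown band name", call. = FALSE)
  }
  lo <- band[1]; hi <- band[2]
  fr <- sc$freqs
  if (hi <= lo || lo < fr[1] - 1e-9 || hi > fr[length(fr)] + 1e-9)
    stop("band outside the spectral grid", call. = FALSE)
  inner <- fr > lo & fr < hi
  grid <- c(lo, fr[inner], hi)
  n <- dim(sc$values)[1]
  out <- matrix(0, n, n)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (i == j) next
    y <- sc$values[j, i, ]
    yy <- c(stats::approx(fr, y, lo)$y, y[inner], stats::approx(fr, y, hi)$y)
    out[j, i] <- trapz(grid, yy) / (hi - lo)
  }
  if (is.null(name)) name <- sprintf("%g-%g Hz", lo, hi)
  connectivity_matrix(out, name, sc$labels)
}

#' Check the spectral-integration consistency of Granger causality
#'
#' The Geweke decomposition guarantees that the frequency average of the
#' spectral causality over the full range `[0, fs/2]` equals the time-domain
#' value.  This check reports the per-pair relative difference between the
#' two and fails if any well-resolved pair (time-domain F above
#' `f_floor`) deviates by more than `rel_tol`.
#'
#' @param sc a `spectral_connectivity`.
#' @param tm the matching time-domain `connectivity_matrix` (same model).
#' @param rel_tol maximum tolerated relative difference (default 0.01).
#' @param f_floor pairs with time-domain F below this are reported but not
#'   gated (relative error is meaningless near zero).
#' @return List with `pass`, `max_rel_diff`, per-pair `rel_diff` matrix,
#'   `freq_avg` matrix and the offending pairs (if any).
#' @export
check_integration <- function(sc, tm, rel_tol = 0.01, f_floor = 0.01) {
  n <- dim(sc$values)[1]
  fr <- sc$freqs
  favg <- matrix(0, n, n)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (i == j) next
    favg[j, i] <- trapz(fr, sc$values[j, i, ]) / (fr[length(fr)] - fr[1])
  }
  tmv <- unclass(tm)
  rel <- abs(favg - tmv) / pmax(abs(tmv), .Machine$double.eps)
  gated <- tmv > f_floor & row(tmv) != col(tmv)
  max_rel <- if (any(gated)) max(rel[gated]) else 0
  offenders <- which(gated & rel > rel_tol, arr.ind = TRUE)
  list(pass = max_rel <= rel_tol, max_rel_diff = max_rel,
       rel_diff = rel, freq_avg = favg,
       offenders = offenders, rel_tol = rel_tol, f_floor = f_floor)
}

#' Full connectivity analysis for one subject
#'
#' Orchestrates, for each sleep stage with usable epochs: model-order
#' selection, pooled MVAR fit, the time-domain matrix, the spectral matrix,
#' its integration consistency check, and the five band-averaged matrices.
#'
#' @param es_by_stage named list of [epoch_set()] objects (one per stage);
#'   entries may also be `NULL` or a condition object for unusable stages.
#' @param bands band definition list as [band_set()].
#' @param settings list of analysis settings: `criterion` ("BIC"/"AIC"),
#'   `p_max`, `order` (fixed order, overrides selection), `n_freqs`,
#'   `reduced_order` (NULL = automatic), `spectral` (logical; compute
#'   band matrices and the integration check).
#' @return List with one entry per stage, each containing `time`, `bands`
#'   (named list of `connectivity_matrix`), `check`, `order`; unusable stages
#'   are listed under `missing`.
#' @export
connectivity_per_subject <- function(es_by_stage, bands = band_set(),
                                     settings = list()) {
  s <- utils::modifyList(list(criterion = "BIC", p_max = 12L, order = NULL,
                              n_freqs = 1024L, reduced_order = NULL,
                              spectral = TRUE), settings)
  out <- list(stages = list(), missing = character())
  for (st in names(es_by_stage)) {
    es <- es_by_stage[[st]]
    if (is.null(es) || inherits(es, "condition")) {
      out$missing <- c(out$missing, st)
      next
    }
    res <- tryCatch({
      p <- if (!is.null(s$order)) as.integer(s$order) else
        select_model_order(es, p_max = s$p_max, criterion = s$criterion)
      model <- fit_mvar(es, p)
      ro <- if (!is.null(s$reduced_order)) s$reduced_order else max(p, 20L)
      tm <- gc_time_from_model(model, reduced_order = ro)
      entry <- list(time = tm, order = as.integer(p),
                    provenance = list(criterion = s$criterion,
                                      n_freqs = s$n_freqs,
                                      reduced_order = ro))
      if (isTRUE(s$spectral)) {
        sc <- gc_spectral_from_model(model, n_freqs = s$n_freqs,
                                     reduced_order = ro)
        entry$bands <- lapply(stats::setNames(names(bands), names(bands)),
                              function(b) integrate_band(sc, bands[[b]], name = b))
        entry$check <- check_integration(sc, tm)
      }
      entry
    }, somnonet_insufficient_data = function(e) e, error = function(e) e)
    if (inherits(res, "condition")) out$missing <- c(out$missing, st)
    else out$stages[[st]] <- res
  }
  out
}
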