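#' Multivariate autoregressive (MVAR) model object
#'
#' Container for a fitted or constructed vector-autoregressive model
#' \eqn{x_t = \sum_{k=1}^p A_k x_{t-k} + e_t}, \eqn{e_t \sim N(0, \Sigma)}.
#'
#' @param A numeric array `n x n x p` of autoregressive coefficient matrices
#'   (`A[i, j, k]` is the influence of channel `j` at lag `k` on channel `i`).
#' @param Sigma `n x n` residual covariance matrix (must be symmetric
#'   positive-definite).
#' @param fs sampling rate in Hz (used by spectral methods).
#' @param labels optional channel labels.
#' @param n_obs_effective number of observations that entered the fit, if any.
#'
#' @return An object of class `mvar_model`.
#' @export
mvar_model <- function(A, Sigma, fs = NULL, labels = NULL,
                       n_obs_effective = NA_integer_) {
  if (length(dim(A)) == 2L) A <- array(A, c(dim(A), 1L))
  stopifnot(length(dim(A)) == 3L, dim(A)[1] == dim(A)[2],
            nrow(Sigma) == dim(A)[1], ncol(Sigma) == dim(A)[1])
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("residual covariance must be positive-definite", call. = FALSE)
  structure(list(A = A, Sigma = Sigma, p = dim(A)[3], n = dim(A)[1],
                 fs = fs, labels = labels,
                 n_obs_effective = n_obs_effective),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("MVAR model: %d channels, order %d, spectral radius %.4f\n",
              x$n, x$p, var_spectral_radius(x$A)))
  invisible(x)
}

# companion matrix of an n x n x p coefficient array
var_companion <- function(A) {
  n <- dim(A)[1]; p <- dim(A)[3]
  np <- n * p
  Ac <- matrix(0, np, np)
  Ac[1:n, ] <- matrix(A, n, np)
  if (p > 1L) Ac[(n + 1L):np, 1:(np - n)] <- diag(np - n)
  Ac
}

#' Spectral radius of an MVAR coefficient array
#'
#' Largest eigenvalue modulus of the companion matrix; the model is
#' (covariance-) stationary iff this is strictly below 1.
#'
#' @param A `n x n x p` coefficient array (or an `mvar_model`).
#' @return The spectral radius (numeric scalar).
#' @export
var_spectral_radius <- function(A) {
  if (inherits(A, "mvar_model")) A <- A$A
  if (length(dim(A)) == 2L) A <- array(A, c(dim(A), 1L))
  if (dim(A)[3] == 0L || all(A == 0)) return(0)
  max(Mod(eigen(var_companion(A), only.values = TRUE)$values))
}

# Rescale A[, , k] by gamma^k so the companion spectral radius becomes
# `target`.  Scaling lag-k coefficients by gamma^k maps every pole z -> gamma z,
# so one shot suffices; the sparsity pattern is preserved.
var_decay <- function(A, target) {
  rho <- var_spectral_radius(A)
  if (rho <= target) return(A)
  gam <- target / rho
  p <- dim(A)[3]
  for (k in seq_len(p)) A[, , k] <- A[, , k] * gam^k
  A
}

#' Autocovariance sequence of a stable MVAR model
#'
#' Solves the companion-form discrete Lyapunov equation by doubling and
#' extends by the Yule-Walker recursion.
#'
#' @param model an `mvar_model` (must be stable).
#' @param q highest lag required.
#' @return Array `n x n x (q+1)`; slice `k+1` is
#'   \eqn{\Gamma_k = E[x_t x_{t-k}']}.
#' @export
var_autocov <- function(model, q) {
  A <- model$A; Sigma <- model$Sigma
  n <- dim(A)[1]; p <- dim(A)[3]
  G <- array(0, c(n, n, q + 1L))
  if (p == 0L || all(A == 0)) {
    G[, , 1] <- Sigma
    return(G)
  }
  if (var_spectral_radius(A) >= 1)
    stop("autocovariance requires a stable model", call. = FALSE)
  np <- n * p
  Ac <- var_companion(A)
  P <- matrix(0, np, np); P[1:n, 1:n] <- Sigma
  Ak <- Ac
  for (it in 1:64) {
    Pn <- P + Ak %*% P %*% t(Ak)
    if (max(abs(Pn - P)) < 1e-14 * max(1, max(abs(Pn)))) { P <- Pn; break }
    P <- Pn
    Ak <- Ak %*% Ak
  }
  P <- (P + t(P)) / 2
  for (k in 0:min(q, p - 1L))
    G[, , k + 1L] <- P[1:n, (k * n + 1L):((k + 1L) * n)]
  G[, , 1] <- (G[, , 1] + t(G[, , 1])) / 2
  if (q >= p) for (k in p:q) {
    S <- matrix(0, n, n)
    for (i in 1:p) S <- S + A[, , i] %*% G[, , k - i + 1L]
    G[, , k + 1L] <- S
  }
  G
}

#' Fit a VAR model to an autocovariance sequence (Whittle recursion)
#'
#' Multivariate Levinson-Durbin-Whittle recursion solving the Yule-Walker
#' equations for the VAR(q) model implied by autocovariances
#' \eqn{\Gamma_0, \dots, \Gamma_q}.
#'
#' @param G array `n x n x (q+1)` of autocovariances (as [var_autocov()]).
#' @return List with coefficient array `A` (`n x n x q`) and forward
#'   innovation covariance `Sigma`.
#' @export
whittle_var <- function(G) {
  n <- dim(G)[1]; q <- dim(G)[3] - 1L
  G0 <- (G[, , 1] + t(G[, , 1])) / 2
  if (q == 0L) return(list(A = array(0, c(n, n, 0L)), Sigma = G0))
  A <- vector("list", q); B <- vector("list", q)
  G1 <- matrix(G[, , 2], n, n)
  A[[1]] <- t(solve(G0, t(G1)))       # Gamma_1 Gamma_0^{-1}
  B[[1]] <- t(solve(G0, G1))          # Gamma_1' Gamma_0^{-1}
  Sf <- G0 - A[[1]] %*% t(G1)
  Sb <- G0 - B[[1]] %*% G1
  if (q >= 2L) for (m in 2:q) {
    D <- matrix(G[, , m + 1L], n, n)
    for (i in 1:(m - 1L)) D <- D - A[[i]] %*% matrix(G[, , m - i + 1L], n, n)
    Am <- t(solve(t(Sb), t(D)))       # D Sb^{-1}
    Bm <- t(solve(t(Sf), D))          # D' Sf^{-1}
    Aold <- A; Bold <- B
    for (i in 1:(m - 1L)) {
      A[[i]] <- Aold[[i]] - Am %*% Bold[[m - i]]
      B[[i]] <- Bold[[i]] - Bm %*% Aold[[m - i]]
    }
    A[[m]] <- Am; B[[m]] <- Bm
    Sf <- Sf - Am %*% t(D)
    Sb <- Sb - Bm %*% D
  }
  list(A = array(unlist(A), c(n, n, q)), Sigma = (Sf + t(Sf)) / 2)
}

#' Reduced MVAR model with one or more channels removed
#'
#' The subprocess of a VAR model obtained by dropping channels is not itself a
#' finite-order VAR; following the state-space/autocovariance semantics of
#' multivariate Granger-causality toolboxes, the reduced model is recovered
#' from the full model's autocovariance sequence by the Whittle recursion at a
#' chosen order rather than refit to data.
#'
#' @param model an `mvar_model`.
#' @param omit integer indices of channels to remove.
#' @param order order of the reduced VAR approximation; higher orders track
#'   the true (VARMA) subprocess more closely.  Default `max(p, 20)`.
#' @return An `mvar_model` on the remaining channels, with attribute `keep`
#'   giving their indices in the full model.
#' @export
var_reduced_model <- function(model, omit,
                              order = max(model$p, 20L)) {
  keep <- setdiff(seq_len(model$n), omit)
  if (length(keep) < 1L) stop("cannot omit every channel", call. = FALSE)
  G <- var_autocov(model, order)
  red <- whittle_var(G[keep, keep, , drop = FALSE])
  out <- mvar_model(red$A, red$Sigma, fs = model$fs,
                    labels = model$labels[keep])
  attr(out, "keep") <- keep
  out
}

# --- estimation ------------------------------------------------------------

# Coerce the various segment containers to a list of channels x time matrices.
as_segment_list <- function(x) {
  if (inherits(x, "epoch_set")) return(x$segments)
  if (is.matrix(x)) return(list(x))
  if (is.array(x) && length(dim(x)) == 3L)
    return(lapply(seq_len(dim(x)[1]), function(s) x[s, , ]))
  if (is.list(x)) return(x)
  stop("cannot interpret input as multi-trial segments", call. = FALSE)
}

#' Fit an MVAR model to multi-trial segment data
#'
#' Ordinary least squares with the segments treated as independent
#' realizations of the same stationary process: the regression is stacked
#' across segments and the first `p` samples of each segment serve only as
#' lags.  Each segment is mean-centred per channel before fitting (no
#' detrending or filtering is applied).
#'
#' @param es an [epoch_set()], a `channels x time` matrix, or a list of such
#'   matrices (one per trial/segment).
#' @param p model order (number of lags), `>= 1`.
#' @param fs sampling rate; taken from `es` when it is an epoch set.
#' @return An [mvar_model()] with `n_obs_effective` the number of stacked
#'   regression rows.
#' @export
fit_mvar <- function(es, p, fs = NULL) {
  p <- as.integer(p)
  stopifnot(p >= 1L)
  segs <- as_segment_list(es)
  if (is.null(fs) && inherits(es, "epoch_set")) fs <- es$fs
  labels <- if (inherits(es, "epoch_set")) es$channel_labels else rownames(segs[[1]])
  n <- nrow(segs[[1]])
  Ys <- vector("list", length(segs)); Zs <- vector("list", length(segs))
  for (s in seq_along(segs)) {
    X <- segs[[s]] - rowMeans(segs[[s]])
    Tn <- ncol(X)
    if (Tn <= p) stop("segment shorter than model order + 1", call. = FALSE)
    Ys[[s]] <- X[, (p + 1L):Tn, drop = FALSE]
    Zs[[s]] <- do.call(rbind, lapply(seq_len(p), function(l)
      X[, (p + 1L - l):(Tn - l), drop = FALSE]))
  }
  Y <- do.call(cbind, Ys); Z <- do.call(cbind, Zs)
  N <- ncol(Y)
  k <- n * p
  if (N <= k)
    stop(sprintf("insufficient samples: %d rows for %d regressors", N, k),
         call. = FALSE)
  ZZt <- Z %*% t(Z)
  Rz <- tryCatch(chol(ZZt), error = function(e)
    stop("rank-deficient regressor matrix in MVAR estimation", call. = FALSE))
  Bc <- Y %*% t(Z) %*% chol2inv(Rz)
  E <- Y - Bc %*% Z
  Sigma <- E %*% t(E) / (N - k)
  A <- array(Bc, c(n, n, p))
  m <- mvar_model(A, Sigma, fs = fs, labels = labels, n_obs_effective = N)
  attr(m, "Sigma_ml") <- E %*% t(E) / N
  m
}

#' Select the MVAR model order by information criterion
#'
#' Fits the pooled multi-trial regression at each candidate order and returns
#' the order minimizing AIC or BIC computed from the maximum-likelihood
#' residual covariance.
#'
#' @inheritParams fit_mvar
#' @param p_max largest candidate order.
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @return The selected order (integer), with the criterion values over
#'   `1:p_max` attached as attribute `"ic"`.
#' @export
select_model_order <- function(es, p_max = 20L, criterion = c("BIC", "AIC"),
                               fs = NULL) {
  criterion <- match.arg(criterion)
  p_max <- as.integer(p_max)
  segs <- as_segment_list(es)
  n <- nrow(segs[[1]])
  total <- sum(vapply(segs, ncol, 1L))
  if (p_max * n * n >= total)
    stop("p_max too large for the available samples", call. = FALSE)
  ic <- rep(NA_real_, p_max)
  for (p in seq_len(p_max)) {
    m <- fit_mvar(segs, p, fs = fs)
    N <- m$n_obs_effective
    ld <- determinant(attr(m, "Sigma_ml"), logarithm = TRUE)$modulus
    pen <- if (criterion == "AIC") 2 * p * n^2 / N else p * n^2 * log(N) / N
    ic[p] <- as.numeric(ld) + pen
  }
  best <- which.min(ic)
  attr(best, "ic") <- ic
  best
}

#' Simulate a stationary MVAR process
#'
#' @param model an `mvar_model`.
#' @param n_samples number of samples to return (after burn-in).
#' @param burn_in samples discarded at the start to remove transients;
#'   defaults to ten times the model order.
#' @return `n x n_samples` matrix.  Uses the current R random stream; seed
#'   with [set.seed()] for reproducibility.
#' @export
var_simulate <- function(model, n_samples, burn_in = 10L * model$p) {
  n <- model$n; p <- model$p
  L <- t(chol(model$Sigma))
  total <- n_samples + burn_in
  E <- L %*% matrix(stats::rnorm(n * total), n, total)
  if (p == 0L) return(E[, burn_in + seq_len(n_samples), drop = FALSE])
  X <- matrix(0, n, total)
  Af <- matrix(model$A, n, n * p)
  s <- rep(0, n * p)  # lag stack (x_{t-1}, ..., x_{t-p})
  for (t in seq_len(total)) {
    xt <- Af %*% s + E[, t]
    X[, t] <- xt
    if (p > 1L) s <- c(xt, s[1:(n * (p - 1L))]) else s <- xt
  }
  X[, burn_in + seq_len(n_samples), drop = FALSE]
}
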