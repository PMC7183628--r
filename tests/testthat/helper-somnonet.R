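# shared fixtures and independent oracles, built in code

# brute-force Watts-Strogatz clustering: triangles over possible triangles
# among each node's neighbours, degree < 2 contributes 0
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ])
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      tri <- tri + adj[nb[a], nb[b]]
    cc[i] <- 2 * tri / (k * (k - 1))
  }
  mean(cc)
}

# exhaustive BFS characteristic path length over connected ordered pairs
oracle_path_length <- function(adj) {
  n <- nrow(adj)
  tot <- 0; cnt <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ])) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    reach <- which(!is.na(dist) & seq_len(n) != s)
    tot <- tot + sum(dist[reach]); cnt <- cnt + length(reach)
  }
  if (cnt == 0) stop("no connected pairs")
  tot / cnt
}

# exact two-sided rank-sum p-value by full enumeration of rank splits
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  na <- length(a)
  Wobs <- sum(r[seq_len(na)])
  splits <- utils::combn(length(pooled), na)
  Ws <- apply(splits, 2, function(ix) sum(r[ix]))
  mu <- na * (length(pooled) + 1) / 2
  p <- mean(abs(Ws - mu) >= abs(Wobs - mu) - 1e-12)
  min(1, p)
}

# random stable MVAR model for property sweeps.  Innovations are diagonal by
# default: the Geweke spectral identity is exact in that regime (and it is the
# innovation structure of the synthetic study conditions); strong instantaneous
# correlation can break the decomposition's minimum-phase premise, which is a
# property of the measure, not of the estimator.
random_stable_model <- function(n, p, fs = 128, sd = 0.25, margin = 0.9,
                                correlated = FALSE) {
  A <- array(stats::rnorm(n * n * p, sd = sd), c(n, n, p))
  A <- somnonet:::var_decay(A, margin)
  S <- if (correlated)
    crossprod(matrix(stats::rnorm(n * n), n)) / n + diag(n) * 0.5
  else diag(stats::runif(n, 0.5, 2), n)
  mvar_model(A, S, fs = fs)
}

# small synthetic subject recording for structural tests
tiny_subject <- function(seed = 1, stages = c("W", "REM"), epochs = 4,
                         fs = 200) {
  rec <- list(subject_id = "T01", sex = "M", age = 30, bdi = 1,
              rewire = c(W = 0.1, `3` = 0.1, `4` = 0.1, REM = 0.1),
              seed = seed)
  simulate_subject(rec, stages = stages, epochs_per_stage = epochs, fs = fs,
                   artifact_fraction = 0)
}
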