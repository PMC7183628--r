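#' Oscillatory profile of a sleep stage
#'
#' Describes the band-structured self-dynamics and coupling used by the
#' synthetic generator for one vigilance stage.  Defaults emulate the gross
#' spectral signature of each stage: wakefulness (pre-sleep-onset) is
#' alpha-dominant with some beta, REM mixes theta and beta, and slow-wave
#' stages 3/4 are delta-dominant.
#'
#' @param stage one of `"W"`, `"3"`, `"4"`, `"REM"` (aliases `"WAKE"`,
#'   `"S3"`, `"S4"` accepted).
#' @param oscillation_bands list of `c(freq_hz, rel_power)` pairs; relative
#'   power in (0, 1\] sets how resonant (pole radius) each rhythm is.
#' @param rewiring_prob coupling-graph rewiring probability in \[0, 1\].
#' @param coupling_strength lag-1 cross-coupling coefficient per edge (>= 0).
#' @return Object of class `stage_profile`.
#' @export
stage_profile <- function(stage,
                          oscillation_bands = NULL,
                          rewiring_prob = 0.10,
                          coupling_strength = 0.3) {
  stage <- normalize_stage(stage)
  if (is.null(oscillation_bands)) {
    oscillation_bands <- switch(stage,
      W   = list(c(10, 0.9), c(20, 0.4)),
      REM = list(c(5, 0.8), c(20, 0.5)),
      `3` = list(c(1.5, 0.9), c(12, 0.3)),
      `4` = list(c(0.8, 0.95), c(12, 0.2)))
  }
  stopifnot(rewiring_prob >= 0, rewiring_prob <= 1, coupling_strength >= 0)
  structure(list(stage = stage, oscillation_bands = oscillation_bands,
                 rewiring_prob = rewiring_prob,
                 coupling_strength = coupling_strength),
            class = "stage_profile")
}

normalize_stage <- function(stage) {
  map <- c(W = "W", WAKE = "W", `3` = "3", S3 = "3", `4` = "4", S4 = "4",
           REM = "REM")
  s <- map[toupper(as.character(stage))]
  if (is.na(s)) stop(sprintf("unknown stage '%s'", stage), call. = FALSE)
  unname(s)
}

#' Build a stable band-structured MVAR model from a coupling graph
#'
#' Each channel carries damped-oscillator self-dynamics: the self
#' polynomial is the product of AR(2) factors with complex pole pairs at the
#' profile's band centres (pole radius grows with relative band power), so
#' the simulated EEG has genuine spectral peaks.  Directed graph edges enter
#' as lag-1 cross-coefficients `coupling_strength * weight`; channels with
#' no in-edges stay cross-independent.  If the companion spectral radius
#' exceeds `stability_margin` the lag-k coefficients are rescaled by
#' `gamma^k` (pole shrinkage), which preserves the sparsity pattern exactly.
#'
#' @param graph a [make_coupling_graph()] object.
#' @param profile a [stage_profile()].
#' @param order model order (>= 2 to place one oscillatory pole pair; each
#'   additional band needs two more lags).  Default fits all profile bands.
#' @param fs sampling rate (Hz); band centres must be below `fs/2`.
#' @param stability_margin target upper bound for the spectral radius.
#' @param seed integer seed for the small per-channel pole-radius jitter.
#' @param noise_sd innovation standard deviation per channel (microvolts).
#' @return An [mvar_model()].
#' @export
graph_to_mvar <- function(graph, profile, order = NULL, fs = 200,
                          stability_margin = 0.95, seed = NULL,
                          noise_sd = 5) {
  stopifnot(inherits(graph, "coupling_graph"), inherits(profile, "stage_profile"))
  if (stability_margin <= 0 || stability_margin >= 1)
    stop("stability_margin must be in (0, 1)", call. = FALSE)
  bands <- profile$oscillation_bands
  if (is.null(order)) order <- max(2L, 2L * length(bands))
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1", call. = FALSE)
  for (b in bands) if (b[1] >= fs / 2)
    stop("band centre at or above Nyquist", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- graph$n_nodes
  A <- array(0, c(n, n, order))
  n_fit <- min(length(bands), order %/% 2L)
  if (n_fit >= 1L) {
    ordb <- order(-vapply(bands, `[`, 1, 2))[seq_len(n_fit)]
    for (ch in seq_len(n)) {
      poly <- 1
      for (b in bands[ordb]) {
        r <- 0.78 + 0.15 * min(b[2], 1) + stats::runif(1, -0.02, 0.02)
        th <- 2 * pi * b[1] / fs
        # (1 - 2 r cos(th) L + r^2 L^2)
        poly <- convolve_poly(poly, c(1, -2 * r * cos(th), r^2))
      }
      coefs <- -poly[-1]                # x_t = sum coefs_k x_{t-k} + ...
      A[ch, ch, seq_along(coefs)] <- coefs
    }
  } else {
    for (ch in seq_len(n)) A[ch, ch, 1] <- 0.5
  }
  if (nrow(graph$edges) > 0) {
    src <- graph$edges[, "source"]; tgt <- graph$edges[, "target"]
    for (e in seq_along(src))
      A[tgt[e], src[e], 1] <- A[tgt[e], src[e], 1] +
        profile$coupling_strength * graph$weights[e]
  }
  A <- var_decay(A, stability_margin)
  if (var_spectral_radius(A) > stability_margin + 1e-8)
    stop("unable to stabilize generated model", call. = FALSE)
  mvar_model(A, diag(noise_sd^2, n), fs = fs)
}

# polynomial product (coefficients in increasing lag order)
convolve_poly <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i + seq_along(b) - 1L] <-
      out[i + seq_along(b) - 1L] + a[i] * b
  out
}

#' Hypnogram template
#'
#' A simple block template of 20-s scoring epochs: a pre-sleep-onset wake
#' block followed by one block per sleep stage.  Desk-scale analyses use a
#' few epochs per stage; a full night is simply a longer template.
#'
#' @param epochs_per_stage scoring epochs per stage block (default 16).
#' @param stages stage order (wake first so the pre-onset rule is
#'   meaningful).
#' @return Character vector of stage labels, one per 20-s epoch.
#' @export
make_hypnogram_template <- function(epochs_per_stage = 16L,
                                    stages = c("W", "3", "4", "REM")) {
  rep(vapply(stages, normalize_stage, ""), each = epochs_per_stage)
}

#' Simulate a stage-labelled multichannel EEG recording
#'
#' Concatenates per-stage MVAR simulations following a hypnogram template.
#' Each contiguous stage block is simulated independently with a burn-in of
#' ten model orders discarded, the hypnogram is emitted in 20-s scoring
#' epochs, and an artifact mask flags a configurable fraction of scoring
#' epochs as contaminated (independent Bernoulli draws, emulating the visual
#' artifact screening that real recordings undergo).
#'
#' @param models named list mapping each stage label in the template to an
#'   [mvar_model()].
#' @param hypnogram_template character vector of stage labels per scoring
#'   epoch ([make_hypnogram_template()]).
#' @param fs sampling rate in Hz (>= 64 so the beta band sits below
#'   Nyquist).
#' @param seed integer seed; same seed, same recording bit for bit.
#' @param artifact_fraction expected fraction of scoring epochs flagged.
#' @param scoring_epoch_s scoring epoch length in seconds (20).
#' @param labels channel labels (defaults to the 10-20 montage when the
#'   model has 19 channels).
#' @return List with `recording` (list: `samples` channels x time matrix,
#'   `fs`, `channel_labels`), `hypnogram` (data.frame: epoch_index, onset_s,
#'   stage), and `artifact_mask` (data.frame: epoch_index, clean).
#' @export
simulate_recording <- function(models, hypnogram_template, fs = 200,
                               seed = NULL, artifact_fraction = 0.1,
                               scoring_epoch_s = 20, labels = NULL) {
  if (fs < 64) stop("fs must be >= 64 Hz", call. = FALSE)
  template <- vapply(hypnogram_template, normalize_stage, "")
  if (length(template) < 1L)
    stop("template must contain at least one scoring epoch", call. = FALSE)
  miss <- setdiff(unique(template), names(models))
  if (length(miss))
    stop(sprintf("no model for stage(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- models[[template[1]]]$n
  if (is.null(labels))
    labels <- if (n == 19L) somnonet_montage() else sprintf("ch%02d", 1:n)
  spb <- as.integer(round(scoring_epoch_s * fs))
  blocks <- rle(template)
  chunks <- vector("list", length(blocks$values))
  for (b in seq_along(blocks$values)) {
    m <- models[[blocks$values[b]]]
    chunks[[b]] <- var_simulate(m, blocks$lengths[b] * spb,
                                burn_in = 10L * m$p)
  }
  samples <- do.call(cbind, chunks)
  rownames(samples) <- labels
  ne <- length(template)
  hyp <- data.frame(epoch_index = seq_len(ne) - 1L,
                    onset_s = (seq_len(ne) - 1L) * scoring_epoch_s,
                    stage = template, stringsAsFactors = FALSE)
  mask <- data.frame(epoch_index = seq_len(ne) - 1L,
                     clean = stats::runif(ne) >= artifact_fraction)
  list(recording = list(samples = samples, fs = fs, channel_labels = labels),
       hypnogram = hyp, artifact_mask = mask)
}

#' The canonical 19-channel 10-20 montage
#'
#' Channel order used throughout the package for connectivity matrices.
#'
#' @return Character vector of 19 electrode labels.
#' @export
somnonet_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}
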