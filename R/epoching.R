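#' Select the first artifact-free scoring epochs of a stage
#'
#' Returns the chronologically first `n` scoring epochs of the requested
#' stage whose artifact-mask flag is clean, as raw signal slices.  For
#' wakefulness only the period preceding sleep onset (epochs before the
#' first scored sleep epoch) is considered; sleep stages are taken
#' regardless of sleep-cycle position.  Time coordinates are 0-based,
#' half-open `[onset, onset + epoch_len)`.
#'
#' @param rec recording list (`samples` channels x time, `fs`,
#'   `channel_labels`), as produced by [simulate_recording()] or
#'   [read_edf()].
#' @param hyp hypnogram data.frame (`epoch_index`, `onset_s`, `stage`).
#' @param mask artifact-mask data.frame (`epoch_index`, `clean`); `NULL`
#'   treats every epoch as clean.
#' @param stage requested stage, one of `"W"`, `"3"`, `"4"`, `"REM"`.
#' @param n number of epochs to select (default 3).
#' @param epoch_len_s scoring-epoch length in seconds (default 20).
#' @return List of `n` channels x (epoch_len_s * fs) matrices, with the
#'   source epoch indices as attribute `epoch_ids`.  Signals an
#'   `somnonet_insufficient_data` condition naming the stage when fewer than
#'   `n` clean epochs exist.
#' @export
select_clean_epochs <- function(rec, hyp, mask, stage, n = 3L,
                                epoch_len_s = 20) {
  stage <- normalize_stage(stage)
  fs <- rec$fs
  spb <- as.integer(round(epoch_len_s * fs))
  clean <- if (is.null(mask)) rep(TRUE, nrow(hyp))
           else mask$clean[match(hyp$epoch_index, mask$epoch_index)]
  cand <- hyp$stage == stage & clean
  if (stage == "W") {
    onset <- match(TRUE, hyp$stage != "W")       # first scored sleep epoch
    if (!is.na(onset)) cand[onset:nrow(hyp)] <- FALSE
  }
  idx <- which(cand)
  idx <- idx[order(hyp$onset_s[idx])]
  if (length(idx) < n) {
    cond <- structure(class = c("somnonet_insufficient_data", "error",
                                "condition"),
                      list(message = sprintf(
                        "stage %s: only %d clean epoch(s) available, %d required",
                        stage, length(idx), n), call = sys.call()))
    stop(cond)
  }
  idx <- idx[seq_len(n)]
  out <- lapply(idx, function(i) {
    s0 <- as.integer(round(hyp$onset_s[i] * fs))
    rec$samples[, (s0 + 1L):(s0 + spb), drop = FALSE]
  })
  attr(out, "epoch_ids") <- hyp$epoch_index[idx]
  attr(out, "fs") <- fs
  attr(out, "stage") <- stage
  out
}

#' Split selected scoring epochs into fixed analysis segments
#'
#' Divides each scoring epoch into contiguous, non-overlapping segments of
#' `segment_len_s` seconds (default 5 s, so three 20-s epochs yield the
#' twelve 5-s analysis segments).  Concatenating a segment quartet
#' reproduces its source epoch exactly.
#'
#' @param epochs list of channels x samples matrices
#'   ([select_clean_epochs()] output).
#' @param segment_len_s segment length in seconds; must divide the epoch
#'   length, and `segment_len_s * fs` must be a whole number of samples.
#' @param fs sampling rate; taken from the epochs attribute if present.
#' @param subject_id,stage provenance carried into the result.
#' @return An `epoch_set`: list with `segments` (list of channels x samples
#'   matrices), `fs`, `segment_len_s`, `source_epoch_ids`, `channel_labels`.
#' @export
split_epochs <- function(epochs, segment_len_s = 5, fs = attr(epochs, "fs"),
                         subject_id = NA_character_,
                         stage = attr(epochs, "stage")) {
  if (is.null(fs)) stop("sampling rate unknown", call. = FALSE)
  seg_n <- segment_len_s * fs
  if (abs(seg_n - round(seg_n)) > 1e-9)
    stop("segment boundaries must align to whole samples", call. = FALSE)
  seg_n <- as.integer(round(seg_n))
  ids <- attr(epochs, "epoch_ids")
  segments <- list(); src <- integer()
  for (e in seq_along(epochs)) {
    Tn <- ncol(epochs[[e]])
    if (Tn %% seg_n != 0L)
      stop("epoch length not divisible by segment length", call. = FALSE)
    for (k in seq_len(Tn %/% seg_n)) {
      segments[[length(segments) + 1L]] <-
        epochs[[e]][, ((k - 1L) * seg_n + 1L):(k * seg_n), drop = FALSE]
      src <- c(src, if (is.null(ids)) e else ids[e])
    }
  }
  structure(list(subject_id = subject_id, stage = stage, segments = segments,
                 fs = fs, segment_len_s = segment_len_s,
                 source_epoch_ids = src,
                 channel_labels = rownames(epochs[[1]])),
            class = "epoch_set")
}

#' Construct an epoch set directly from segment matrices
#'
#' @param segments list of channels x samples matrices.
#' @param fs sampling rate in Hz.
#' @param subject_id,stage provenance.
#' @param segment_len_s segment length (inferred from the data when NULL).
#' @return An `epoch_set`.
#' @export
epoch_set <- function(segments, fs, subject_id = NA_character_,
                      stage = NA_character_, segment_len_s = NULL) {
  if (is.null(segment_len_s)) segment_len_s <- ncol(segments[[1]]) / fs
  structure(list(subject_id = subject_id, stage = stage, segments = segments,
                 fs = fs, segment_len_s = segment_len_s,
                 source_epoch_ids = seq_along(segments),
                 channel_labels = rownames(segments[[1]])),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set: %s / stage %s, %d segments of %.1f s at %g Hz (%d channels)\n",
              x$subject_id, x$stage, length(x$segments), x$segment_len_s,
              x$fs, nrow(x$segments[[1]])))
  invisible(x)
}

#' Spectral-power homogeneity of the analysis segments
#'
#' Computes per-segment band power (periodogram integrated over each band,
#' averaged across channels) and, per band, the coefficient of variation
#' across segments.  The report flags whether all bands fall below the
#' dispersion threshold; it never rejects segments itself, since the
#' appropriate action is protocol-dependent.
#'
#' @param es an [epoch_set()] with at least 2 segments.
#' @param bands band definitions ([band_set()]).
#' @param cv_threshold maximum coefficient of variation tolerated per band
#'   (default 0.5).
#' @return Object of class `homogeneity_report`: list with `band_power`
#'   (segment x band matrix, microvolt^2), `cv` (per band), `pass`,
#'   `cv_threshold`.
#' @export
spectral_homogeneity <- function(es, bands = band_set(), cv_threshold = 0.5) {
  stopifnot(length(es$segments) >= 2L)
  fs <- es$fs
  bp <- matrix(0, length(es$segments), length(bands),
               dimnames = list(NULL, names(bands)))
  for (s in seq_along(es$segments)) {
    X <- es$segments[[s]]
    Tn <- ncol(X)
    fr <- seq(0, fs / 2, by = fs / Tn)
    for (ch in seq_len(nrow(X))) {
      x <- X[ch, ] - mean(X[ch, ])
      pg <- Mod(stats::fft(x))^2 / (Tn * fs)      # two-sided density
      pg <- pg[seq_along(fr)]
      for (b in seq_along(bands)) {
        sel <- fr >= bands[[b]][1] & fr < bands[[b]][2]
        bp[s, b] <- bp[s, b] + sum(pg[sel]) * (fs / Tn)
      }
    }
    bp[s, ] <- bp[s, ] / nrow(X)
  }
  cv <- apply(bp, 2, function(v) if (mean(v) == 0) 0 else stats::sd(v) / mean(v))
  structure(list(band_power = bp, cv = cv, pass = all(cv <= cv_threshold),
                 cv_threshold = cv_threshold),
            class = "homogeneity_report")
}

#' @export
print.homogeneity_report <- function(x, ...) {
  cat("Spectral homogeneity (CV per band):\n")
  print(round(x$cv, 3))
  cat(sprintf("pass (all <= %.2f): %s\n", x$cv_threshold, x$pass))
  invisible(x)
}

#' Select, split and package the analysis segments for one subject-stage
#'
#' Convenience wrapper: first `n_epochs` clean scoring epochs of the stage,
#' split into 5-s segments.
#'
#' @inheritParams select_clean_epochs
#' @param n_epochs scoring epochs to select (3).
#' @param segment_len_s analysis segment length (5).
#' @param subject_id provenance.
#' @return An `epoch_set` with `n_epochs * epoch_len_s / segment_len_s`
#'   segments.
#' @export
extract_stage_epochs <- function(rec, hyp, mask, stage, n_epochs = 3L,
                                 epoch_len_s = 20, segment_len_s = 5,
                                 subject_id = NA_character_) {
  ep <- select_clean_epochs(rec, hyp, mask, stage, n = n_epochs,
                            epoch_len_s = epoch_len_s)
  split_epochs(ep, segment_len_s = segment_len_s, subject_id = subject_id)
}
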