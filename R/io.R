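pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' Minimal EDF (16-bit) writer: one data record per second, physical range
#' per channel set from the signal extrema, so the round-trip error is
#' bounded by one quantization step per channel.
#'
#' @param rec recording list (`samples` channels x time, `fs`,
#'   `channel_labels`).
#' @param path output file.
#' @param patient,recording_id free-text header fields.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path, patient = "X", recording_id = "synthetic") {
  X <- rec$samples
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  n_sig <- nrow(X)
  n_rec <- ncol(X) %/% fs
  if (n_rec * fs != ncol(X))
    stop("recording length must be a whole number of seconds", call. = FALSE)
  pmin_ <- apply(X, 1, min); pmax_ <- apply(X, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb"); on.exit(close(con))
  writeChar(paste0(
    pad_field("0", 8), pad_field(patient, 80), pad_field(recording_id, 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + 256 * n_sig, 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(n_sig, 4)),
    con, eos = NULL)
  lab <- rec$channel_labels
  writeChar(paste0(
    paste0(vapply(lab, pad_field, "", 16), collapse = ""),
    paste0(rep(pad_field("", 80), n_sig), collapse = ""),
    paste0(rep(pad_field("uV", 8), n_sig), collapse = ""),
    paste0(vapply(sprintf("%.6g", pmin_), pad_field, "", 8), collapse = ""),
    paste0(vapply(sprintf("%.6g", pmax_), pad_field, "", 8), collapse = ""),
    paste0(rep(pad_field(dmin, 8), n_sig), collapse = ""),
    paste0(rep(pad_field(dmax, 8), n_sig), collapse = ""),
    paste0(rep(pad_field("", 80), n_sig), collapse = ""),
    paste0(rep(pad_field(fs, 8), n_sig), collapse = ""),
    paste0(rep(pad_field("", 32), n_sig), collapse = "")),
    con, eos = NULL)
  # digitize per channel
  D <- matrix(0L, n_sig, ncol(X))
  for (s in seq_len(n_sig)) {
    g <- (dmax - dmin) / (pmax_[s] - pmin_[s])
    D[s, ] <- as.integer(pmin(dmax, pmax(dmin,
      round((X[s, ] - pmin_[s]) * g + dmin))))
  }
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(D[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording and canonicalize the montage
#'
#' Parses EDF/EDF+ (16-bit continuous signals), keeps the 19 channels of the
#' standard 10-20 montage, reorders them to the canonical order
#' ([somnonet_montage()]), and drops any extra channels with a note.  All
#' montage channels must share one sampling rate.
#'
#' @param path EDF file.
#' @param montage required channel labels in canonical order.
#' @return Recording list (`samples`, `fs`, `channel_labels`) with attribute
#'   `dropped_channels`.
#' @export
read_edf <- function(path, montage = somnonet_montage()) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  fld <- function(x, from, len) trimws(substr(x, from, from + len - 1))
  n_rec <- as.integer(fld(hdr, 237, 8))
  rec_dur <- as.numeric(fld(hdr, 245, 8))
  n_sig <- as.integer(fld(hdr, 253, 4))
  sh <- readChar(con, 256 * n_sig, useBytes = TRUE)
  # per-signal header blocks: all signals' label fields, then all transducer
  # fields, etc.; offsets are in bytes from the start of the signal header
  off <- c(label = 0, transducer = 16, dim = 96, pmin = 104, pmax = 112,
           dmin = 120, dmax = 128, prefilter = 136, ns = 216)
  grab <- function(name, width)
    vapply(seq_len(n_sig), function(s)
      fld(sh, off[[name]] * n_sig + (s - 1) * width + 1, width), "")
  labels <- grab("label", 16)
  pmin_ <- as.numeric(grab("pmin", 8))
  pmax_ <- as.numeric(grab("pmax", 8))
  dmin  <- as.numeric(grab("dmin", 8))
  dmax  <- as.numeric(grab("dmax", 8))
  ns    <- as.integer(grab("ns", 8))
  total <- sum(ns)
  raw <- readBin(con, "integer", n = n_rec * total, size = 2,
                 endian = "little", signed = TRUE)
  sig <- vector("list", n_sig)
  for (s in seq_len(n_sig)) sig[[s]] <- numeric(n_rec * ns[s])
  pos <- cumsum(c(0, ns))
  for (r in seq_len(n_rec)) {
    base <- (r - 1L) * total
    for (s in seq_len(n_sig)) {
      d <- raw[(base + pos[s] + 1L):(base + pos[s + 1L])]
      sig[[s]][((r - 1L) * ns[s] + 1L):(r * ns[s])] <-
        (d - dmin[s]) * (pmax_[s] - pmin_[s]) / (dmax[s] - dmin[s]) + pmin_[s]
    }
  }
  idx <- match(toupper(montage), toupper(labels))
  if (anyNA(idx))
    stop(sprintf("EDF missing montage channel(s): %s",
                 paste(montage[is.na(idx)], collapse = ", ")), call. = FALSE)
  fs_all <- ns[idx] / rec_dur
  if (length(unique(fs_all)) != 1L)
    stop("heterogeneous sampling rates across montage channels", call. = FALSE)
  X <- do.call(rbind, sig[idx])
  rownames(X) <- montage
  out <- list(samples = X, fs = fs_all[1], channel_labels = montage)
  attr(out, "dropped_channels") <- setdiff(labels, labels[idx])
  out
}

#' Write / read the CSV sidecar formats
#'
#' Hypnogram (`epoch_index, onset_s, stage`), artifact mask
#' (`epoch_index, clean`), and subjects (`subject_id, sex, age, bdi`) files.
#'
#' @param x data.frame to write.
#' @param path CSV path.
#' @return `write_*` return the path invisibly; `read_*` return data.frames.
#' @name sidecar_io
NULL

#' @rdname sidecar_io
#' @export
write_hypnogram_csv <- function(x, path) {
  utils::write.csv(x[, c("epoch_index", "onset_s", "stage")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname sidecar_io
#' @export
read_hypnogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$stage <- as.character(df$stage)
  df
}

#' @rdname sidecar_io
#' @export
write_artifact_csv <- function(x, path) {
  utils::write.csv(x[, c("epoch_index", "clean")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname sidecar_io
#' @export
read_artifact_csv <- function(path) utils::read.csv(path)

#' @rdname sidecar_io
#' @export
write_subjects_csv <- function(x, path) {
  utils::write.csv(x[, c("subject_id", "sex", "age", "bdi")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname sidecar_io
#' @export
read_subjects_csv <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(subject_id = "character", sex = "character"))

#' Write a connectivity matrix with provenance sidecar
#'
#' CSV with channel labels as header/rownames plus a JSON sidecar recording
#' subject, stage, domain and analysis settings.
#'
#' @param cm a `connectivity_matrix`.
#' @param path CSV path (sidecar gets `.json` appended).
#' @param meta named list of provenance fields.
#' @return Invisibly, the CSV path.
#' @export
write_connectivity_csv <- function(cm, path, meta = list()) {
  M <- unclass(cm)
  utils::write.csv(M, path, row.names = TRUE)
  meta <- c(meta, list(domain = attr(cm, "domain"),
                       package_version = as.character(utils::packageVersion("somnonet"))))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
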