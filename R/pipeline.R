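#' Deterministic child seed derivation
#'
#' One master seed drives every stage of the pipeline; per-module and
#' per-subject seeds are derived by a fixed integer hash of the master seed
#' and a label, so stages are independently rerunnable yet globally
#' reproducible.
#'
#' @param master integer master seed.
#' @param label character label of the consumer.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  h <- as.double(master) %% 2147483647
  for (b in utf8ToInt(as.character(label)))
    h <- (h * 31 + b) %% 2147483647
  as.integer(h + 1)
}

#' Assemble and validate a pipeline configuration
#'
#' @param out_dir output directory.
#' @param cohort a [cohort_config()].
#' @param stages stages to analyse (default REM and slow-wave stages plus
#'   pre-onset wake).
#' @param epochs_per_stage scoring epochs simulated per stage block.
#' @param fs sampling rate (Hz).
#' @param n_epochs clean scoring epochs selected per stage (3).
#' @param epoch_len_s scoring-epoch length (20 s).
#' @param segment_len_s analysis segment length (5 s).
#' @param artifact_fraction expected flagged fraction of scoring epochs.
#' @param mvgc connectivity settings (see [connectivity_per_subject()]).
#' @param network list: `density`, `n_surrogates`.
#' @param stats list: `alpha`, `band_family`.
#' @param seed master seed.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("somnonet_run_"),
                            cohort = cohort_config(),
                            stages = c("W", "3", "4", "REM"),
                            epochs_per_stage = 6L, fs = 200,
                            n_epochs = 3L, epoch_len_s = 20,
                            segment_len_s = 5, artifact_fraction = 0.1,
                            mvgc = list(), network = list(), stats = list(),
                            seed = 1L) {
  stages <- vapply(stages, normalize_stage, "")
  if (fs <= 64) stop("fs must exceed 64 Hz", call. = FALSE)
  if ((epoch_len_s %% segment_len_s) != 0)
    stop("epoch length must be divisible by segment length", call. = FALSE)
  network <- utils::modifyList(list(density = 0.2, n_surrogates = 20L), network)
  if (network$density <= 0 || network$density >= 1)
    stop("network density must be in (0, 1)", call. = FALSE)
  stats <- utils::modifyList(list(alpha = 0.05, band_family = 5L), stats)
  mvgc <- utils::modifyList(list(criterion = "BIC", p_max = 8L, order = NULL,
                                 n_freqs = 1024L, reduced_order = NULL,
                                 spectral = FALSE), mvgc)
  structure(list(out_dir = out_dir, cohort = cohort, stages = unname(stages),
                 epochs_per_stage = as.integer(epochs_per_stage), fs = fs,
                 n_epochs = as.integer(n_epochs), epoch_len_s = epoch_len_s,
                 segment_len_s = segment_len_s,
                 artifact_fraction = artifact_fraction,
                 mvgc = mvgc, network = network, stats = stats,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys mirror the [pipeline_config()]
#'   arguments, with `cohort` a mapping of [cohort_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) y$cohort <- do.call(cohort_config, y$cohort)
  do.call(pipeline_config, y)
}

#' Network metrics of one subject's connectivity results
#'
#' Thresholds every available matrix (time domain and bands) and computes
#' the small-world coefficient with seeded surrogate ensembles.
#'
#' @param conn [connectivity_per_subject()] result.
#' @param subject_id subject identifier for the output rows.
#' @param density,n_surrogates network parameters.
#' @param seed integer seed for the surrogate ensembles.
#' @return Data frame: subject_id, stage, domain, C, L, C_latt, L_rand, swc,
#'   density, n_surrogates, seed.
#' @export
network_metrics_table <- function(conn, subject_id, density = 0.2,
                                  n_surrogates = 20L, seed = 1L) {
  rows <- list()
  for (st in names(conn$stages)) {
    entry <- conn$stages[[st]]
    mats <- c(list(time = entry$time), entry$bands)
    for (dm in names(mats)) {
      sd_ <- derive_seed(seed, paste(subject_id, st, dm))
      nm <- small_world_coefficient(mats[[dm]], density = density,
                                    n_surrogates = n_surrogates, seed = sd_)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject_id, stage = st, domain = dm,
        C = nm$C, L = nm$L, C_latt = nm$C_latt, L_rand = nm$L_rand,
        swc = nm$swc, density = density, n_surrogates = n_surrogates,
        seed = sd_)
    }
  }
  do.call(rbind, rows)
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulate -> epoch -> connectivity -> network metrics -> group statistics,
#' writing per-subject metrics, the four report tables, and a provenance
#' manifest to `config$out_dir`.  Subjects are simulated and processed one
#' at a time, so memory stays flat in the cohort size; per-subject stage
#' failures (insufficient clean epochs) are recorded and skipped, not
#' fatal.
#'
#' @param config a [pipeline_config()].
#' @param write_output write CSV outputs and the manifest (default TRUE);
#'   FALSE returns results in memory only.
#' @return Invisibly, list with `metrics` (per-subject data.frame),
#'   `subjects`, `tables` ([build_report()] output), `failures`, `paths`.
#' @export
run_pipeline <- function(config, write_output = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort_cfg <- config$cohort
  cohort_cfg$seed <- derive_seed(config$seed, "cohort")
  bundles <- make_cohort(cohort_cfg, keep_signals = FALSE)
  metrics <- list(); failures <- list()
  subjects <- do.call(rbind, lapply(bundles, function(b)
    data.frame(subject_id = b$record$subject_id, sex = b$record$sex,
               age = b$record$age, bdi = b$record$bdi)))
  for (b in bundles) {
    rec <- b$record
    sim <- simulate_subject(rec, stages = config$stages,
                            epochs_per_stage = config$epochs_per_stage,
                            fs = config$fs,
                            artifact_fraction = config$artifact_fraction,
                            coupling_strength = cohort_cfg$coupling_strength)
    es_by_stage <- list()
    for (st in config$stages) {
      es_by_stage[[st]] <- tryCatch(
        extract_stage_epochs(sim$recording, sim$hypnogram, sim$artifact_mask,
                             st, n_epochs = config$n_epochs,
                             epoch_len_s = config$epoch_len_s,
                             segment_len_s = config$segment_len_s,
                             subject_id = rec$subject_id),
        somnonet_insufficient_data = function(e) e)
    }
    conn <- connectivity_per_subject(es_by_stage, settings = config$mvgc)
    if (length(conn$missing))
      failures[[rec$subject_id]] <- conn$missing
    metrics[[rec$subject_id]] <- network_metrics_table(
      conn, rec$subject_id, density = config$network$density,
      n_surrogates = config$network$n_surrogates,
      seed = derive_seed(config$seed, paste0("network/", rec$subject_id)))
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  have_both <- !is.null(metrics) && nrow(metrics) > 0 &&
    all(c("M", "F") %in% subjects$sex[subjects$subject_id %in%
                                        metrics$subject_id])
  tables <- if (have_both)
    build_report(metrics, subjects, alpha = config$stats$alpha,
                 band_family = config$stats$band_family)
  else NULL
  paths <- NULL
  if (write_output) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    mp <- file.path(config$out_dir, "metrics.csv")
    utils::write.csv(metrics, mp, row.names = FALSE)
    sp <- file.path(config$out_dir, "subjects.csv")
    write_subjects_csv(subjects, sp)
    rp <- if (!is.null(tables)) write_report(tables, config$out_dir)
          else character()
    cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "cohort")],
                                 auto_unbox = TRUE)
    tf <- tempfile(); writeLines(cfg_json, tf)
    manifest <- list(
      seed = config$seed,
      config_hash = unname(tools::md5sum(tf)),
      package_version = as.character(utils::packageVersion("somnonet")),
      n_subjects = nrow(subjects),
      failures = failures,
      outputs = basename(c(mp, sp, rp)))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    paths <- c(mp, sp, rp, file.path(config$out_dir, "manifest.json"))
  }
  invisible(list(metrics = metrics, subjects = subjects, tables = tables,
                 failures = failures, paths = paths))
}
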