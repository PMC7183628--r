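#' Score the 13-item short-form Beck Depression Inventory
#'
#' Sums 13 item responses, each scored 0-3, giving a total in \[0, 39\], and
#' attaches the conventional severity label: 0-4 absence of depression, 5-7
#' subclinical, 8-15 moderate, >= 16 severe.
#'
#' @param item_responses integer vector of exactly 13 responses in
#'   `{0, 1, 2, 3}`.
#' @return List with `score` (integer) and `severity` (character).
#' @export
score_bdi <- function(item_responses) {
  if (length(item_responses) != 13L)
    stop("BDI-13 requires exactly 13 item responses", call. = FALSE)
  if (any(is.na(item_responses)) || any(item_responses %% 1 != 0) ||
      any(item_responses < 0) || any(item_responses > 3))
    stop("BDI items must be integers in 0..3", call. = FALSE)
  s <- as.integer(sum(item_responses))
  sev <- if (s <= 4) "absence of depression" else if (s <= 7) "subclinical"
         else if (s <= 15) "moderate" else "severe"
  list(score = s, severity = sev)
}

#' Configuration of a synthetic cohort
#'
#' Defaults emulate the study conditions the generator is calibrated to:
#' 28 men and 16 women; women's REM coupling graphs are rewired more strongly
#' (0.15 vs 0.05), which raises their REM small-world coefficient; within
#' women, the depression score is rank-coupled to the REM rewiring
#' probability (target Spearman rho 0.6) via a Gaussian copula, while men's
#' scores are independent of topology.  Stage-3/4 and wake graph parameters
#' are identical across sexes.
#'
#' @param n_men,n_women group sizes (>= 1).
#' @param rem_rewire_men,rem_rewire_women mean REM rewiring probability per
#'   sex; the gap realizes the women-minus-men REM omega shift.
#' @param sws_rewire rewiring probability for stages 3, 4 and wake (both
#'   sexes).
#' @param bdi_omega_rho_women target Spearman correlation between women's
#'   BDI and their REM rewiring probability (|rho| <= 1).
#' @param coupling_strength lag-1 coupling per edge for every stage model.
#' @param seed master integer seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_men = 28L, n_women = 16L,
                          rem_rewire_men = 0.05, rem_rewire_women = 0.15,
                          sws_rewire = 0.10,
                          bdi_omega_rho_women = 0.6,
                          coupling_strength = 0.3,
                          seed = 1L) {
  stopifnot(n_men >= 1L, n_women >= 1L, abs(bdi_omega_rho_women) <= 1,
            rem_rewire_men >= 0, rem_rewire_men <= 1,
            rem_rewire_women >= 0, rem_rewire_women <= 1)
  structure(list(n_men = as.integer(n_men), n_women = as.integer(n_women),
                 rem_rewire_men = rem_rewire_men,
                 rem_rewire_women = rem_rewire_women,
                 sws_rewire = sws_rewire,
                 bdi_omega_rho_women = bdi_omega_rho_women,
                 coupling_strength = coupling_strength,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# map a uniform quantile to an integer BDI score with the sex-specific shape
# (men: median ~1, IQR 0-3; women: median ~4, IQR 3-6, per healthy-cohort
# demographics)
bdi_quantile <- function(u, sex) {
  x <- if (sex == "F") stats::qgamma(u, shape = 3.4, rate = 0.75)
       else stats::qgamma(u, shape = 0.75, rate = 0.55)
  pmin(39L, pmax(0L, as.integer(round(x))))
}

#' Generate a synthetic cohort
#'
#' Draws subject metadata (sex, age, BDI) and per-subject, per-stage coupling
#' topology; optionally simulates the full stage-labelled EEG recording for
#' each subject.  Everything is reproducible from the config seed; each
#' subject carries its own derived seed so recordings can be re-simulated
#' lazily with [simulate_subject()].
#'
#' @param config a [cohort_config()].
#' @param keep_signals simulate and attach recordings now (`TRUE`) or return
#'   metadata bundles only (`FALSE`, cheap).
#' @param stages stages to simulate.
#' @param epochs_per_stage scoring epochs per stage block.
#' @param fs sampling rate in Hz.
#' @param artifact_fraction expected fraction of flagged scoring epochs.
#' @param order MVAR order of the generating models.
#' @return List of subject bundles; each has `record` (subject_id, sex, age,
#'   bdi, per-stage rewiring probabilities, seed) and, when `keep_signals`,
#'   `recording`, `hypnogram`, `artifact_mask`, `graphs`.
#' @export
make_cohort <- function(config, keep_signals = TRUE,
                        stages = c("W", "3", "4", "REM"),
                        epochs_per_stage = 16L, fs = 200,
                        artifact_fraction = 0.1, order = 4L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_tot <- config$n_men + config$n_women
  sexes <- rep(c("M", "F"), c(config$n_men, config$n_women))
  rho_g <- 2 * sin(pi * config$bdi_omega_rho_women / 6)  # copula calibration
  bundles <- vector("list", n_tot)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  for (i in seq_len(n_tot)) {
    sex <- sexes[i]
    t_lat <- stats::rnorm(1)                      # latent topology factor
    mu <- if (sex == "F") config$rem_rewire_women else config$rem_rewire_men
    conc <- 40
    p_rem <- stats::qbeta(stats::pnorm(t_lat), mu * conc, (1 - mu) * conc)
    if (sex == "F") {
      b_lat <- rho_g * t_lat + sqrt(max(0, 1 - rho_g^2)) * stats::rnorm(1)
      bdi <- bdi_quantile(stats::pnorm(b_lat), "F")
      age <- round(stats::qlnorm(stats::runif(1), log(22.5), 0.12))
    } else {
      bdi <- bdi_quantile(stats::runif(1), "M")
      age <- round(stats::qlnorm(stats::runif(1), log(25), 0.22))
    }
    rewire <- c(W = config$sws_rewire, `3` = config$sws_rewire,
                `4` = config$sws_rewire, REM = p_rem)
    bundles[[i]] <- list(record = list(
      subject_id = sprintf("S%02d", i), sex = sex, age = age, bdi = bdi,
      rewire = rewire, latent_topology = t_lat, seed = subj_seeds[i]))
  }
  if (keep_signals) {
    for (i in seq_len(n_tot)) {
      sim <- simulate_subject(bundles[[i]]$record, stages = stages,
                              epochs_per_stage = epochs_per_stage, fs = fs,
                              artifact_fraction = artifact_fraction,
                              order = order,
                              coupling_strength = config$coupling_strength)
      bundles[[i]] <- c(bundles[[i]], sim)
    }
  }
  attr(bundles, "config") <- config
  bundles
}

#' Simulate one subject's recording from its cohort record
#'
#' Deterministic given the record's seed: builds the per-stage coupling
#' graphs and MVAR models, simulates the stage-labelled recording, and draws
#' the artifact mask.
#'
#' @param record the `record` element of a [make_cohort()] bundle.
#' @inheritParams make_cohort
#' @param coupling_strength lag-1 coupling per edge.
#' @param mean_degree coupling-graph out-degree.
#' @return List with `recording`, `hypnogram`, `artifact_mask`, `graphs`
#'   (per-stage `coupling_graph`s), `models`.
#' @export
simulate_subject <- function(record, stages = c("W", "3", "4", "REM"),
                             epochs_per_stage = 16L, fs = 200,
                             artifact_fraction = 0.1, order = 4L,
                             coupling_strength = 0.3, mean_degree = 4L) {
  set.seed(record$seed)
  stages <- vapply(stages, normalize_stage, "")
  graphs <- list(); models <- list()
  for (st in stages) {
    pr <- stage_profile(st, rewiring_prob = record$rewire[[st]],
                        coupling_strength = coupling_strength)
    g <- make_coupling_graph(19L, mean_degree, pr$rewiring_prob, seed = NULL)
    graphs[[st]] <- g
    models[[st]] <- graph_to_mvar(g, pr, order = order, fs = fs)
  }
  template <- make_hypnogram_template(epochs_per_stage, stages)
  sim <- simulate_recording(models, template, fs = fs, seed = NULL,
                            artifact_fraction = artifact_fraction)
  c(sim, list(graphs = graphs, models = models))
}
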