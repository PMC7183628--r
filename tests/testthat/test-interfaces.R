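test_that("EDF round-trip error stays within one quantization step", {
  sub <- tiny_subject(seed = 51, stages = "REM", epochs = 2, fs = 128)
  rec <- sub$recording
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_identical(back$channel_labels, somnonet_montage())
  expect_equal(back$fs, 128)
  step <- (apply(rec$samples, 1, max) - apply(rec$samples, 1, min)) / 65535
  err <- apply(abs(back$samples - rec$samples), 1, max)
  expect_true(all(err <= step + 1e-9))
})

test_that("EDF reader canonicalizes channel order and names missing channels", {
  sub <- tiny_subject(seed = 52, stages = "REM", epochs = 2, fs = 128)
  rec <- sub$recording
  set.seed(52)
  perm <- sample(19)
  scrambled <- list(samples = rec$samples[perm, , drop = FALSE], fs = rec$fs,
                    channel_labels = rec$channel_labels[perm])
  path <- tempfile(fileext = ".edf")
  write_edf(scrambled, path)
  back <- read_edf(path)
  expect_identical(back$channel_labels, somnonet_montage())
  expect_lt(max(abs(back$samples["Cz", ] - rec$samples["Cz", ])), 0.05)

  nopz <- list(samples = rec$samples[-15, , drop = FALSE], fs = rec$fs,
               channel_labels = rec$channel_labels[-15])
  path2 <- tempfile(fileext = ".edf")
  write_edf(nopz, path2)
  expect_error(read_edf(path2), "Pz")
})

test_that("EDF reader rejects heterogeneous sampling rates", {
  sub <- tiny_subject(seed = 53, stages = "REM", epochs = 2, fs = 128)
  path <- tempfile(fileext = ".edf")
  write_edf(sub$recording, path)
  # corrupt one channel's samples-per-record header field
  raw <- readBin(path, "raw", file.size(path))
  off <- 256 + 216 * 19  # start of the ns block in the signal header
  raw[(off + 1):(off + 8)] <- charToRaw(formatC("64", width = -8))
  writeBin(raw, path)
  expect_error(read_edf(path), "heterogeneous")
})

test_that("sidecar CSVs round-trip", {
  sub <- tiny_subject(seed = 54, stages = "REM", epochs = 2, fs = 128)
  hp <- tempfile(fileext = ".csv"); ap <- tempfile(fileext = ".csv")
  write_hypnogram_csv(sub$hypnogram, hp)
  write_artifact_csv(sub$artifact_mask, ap)
  expect_equal(read_hypnogram_csv(hp), sub$hypnogram)
  expect_equal(read_artifact_csv(ap), sub$artifact_mask)

  subj <- data.frame(subject_id = "S01", sex = "F", age = 24, bdi = 4)
  sp <- tempfile(fileext = ".csv")
  write_subjects_csv(subj, sp)
  expect_equal(read_subjects_csv(sp), subj)
})

test_that("seed derivation is deterministic, label-sensitive and in range", {
  s1 <- derive_seed(7, "cohort"); s2 <- derive_seed(7, "cohort")
  expect_identical(s1, s2)
  expect_false(derive_seed(7, "network") == s1)
  expect_false(derive_seed(8, "cohort") == s1)
  for (m in c(1, 1000, 2^30)) {
    s <- derive_seed(m, "x")
    expect_true(s >= 1 && s <= 2^31 - 1)
  }
})

test_that("configuration validation rejects bad parameters before compute", {
  expect_error(pipeline_config(stages = c("REM", "NREMX")), "unknown stage")
  expect_error(pipeline_config(epoch_len_s = 20, segment_len_s = 7),
               "divisible")
  expect_error(pipeline_config(network = list(density = 1.2)), "density")
  expect_error(pipeline_config(fs = 50), "64")
})

test_that("pipeline configs round-trip through YAML", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c(
    "stages: [REM, '3']",
    "epochs_per_stage: 4",
    "fs: 128",
    "seed: 9",
    "cohort:",
    "  n_men: 3",
    "  n_women: 3",
    "  seed: 2"), y)
  cfg <- read_pipeline_config(y)
  expect_s3_class(cfg, "pipeline_config")
  expect_equal(cfg$stages, c("REM", "3"))
  expect_equal(cfg$cohort$n_men, 3L)
  expect_equal(cfg$fs, 128)
})

test_that("the end-to-end pipeline runs, writes outputs and is reproducible", {
  cfg <- pipeline_config(
    out_dir = tempfile("run_"),
    cohort = cohort_config(n_men = 3, n_women = 3, seed = 11),
    stages = "REM", epochs_per_stage = 5, fs = 128,
    mvgc = list(order = 4, reduced_order = 4, spectral = FALSE),
    network = list(density = 0.2, n_surrogates = 4),
    seed = 77)
  res <- run_pipeline(cfg)
  expect_equal(nrow(res$metrics), 6)
  expect_true(all(res$metrics$swc >= -1 & res$metrics$swc <= 1))
  expect_true(file.exists(file.path(cfg$out_dir, "manifest.json")))
  expect_true(all(file.exists(file.path(cfg$out_dir,
    c("metrics.csv", "subjects.csv", "table2.csv", "report.txt")))))
  man <- jsonlite::read_json(file.path(cfg$out_dir, "manifest.json"))
  expect_equal(man$n_subjects, 6)
  expect_equal(man$seed, 77)

  cfg2 <- cfg; cfg2$out_dir <- tempfile("run2_")
  res2 <- run_pipeline(cfg2)
  expect_identical(res$metrics, res2$metrics)
  expect_identical(readLines(file.path(cfg$out_dir, "metrics.csv")),
                   readLines(file.path(cfg2$out_dir, "metrics.csv")))
})

test_that("per-stage failures are recorded without aborting the pipeline", {
  cfg <- pipeline_config(
    cohort = cohort_config(n_men = 3, n_women = 3, seed = 13),
    stages = "REM", epochs_per_stage = 4, fs = 128,
    artifact_fraction = 0.5,
    mvgc = list(order = 3, reduced_order = 3, spectral = FALSE),
    network = list(n_surrogates = 4),
    seed = 5)
  res <- run_pipeline(cfg, write_output = FALSE)
  expect_gt(length(res$failures), 0)
  done <- unique(res$metrics$subject_id)
  expect_equal(sort(c(done, names(res$failures))),
               sort(res$subjects$subject_id))
})
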