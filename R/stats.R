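#' Median and quartiles
#'
#' Median with 25th and 75th percentiles by linear interpolation of order
#' statistics (quantile type 7), the convention used for all "median
#' (P25-P75)" summaries in cohort reports.
#'
#' @param values numeric vector, `n >= 1`.
#' @return Named numeric vector `c(median, p25, p75)`.
#' @export
median_iqr <- function(values) {
  if (!length(values)) stop("empty input", call. = FALSE)
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], p25 = q[2], p75 = q[3])
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test for independent groups.  The null distribution is
#' enumerated exactly when the pooled sample is small (`n_a + n_b <= 12`)
#' and tie-free; otherwise the normal approximation with tie and continuity
#' corrections is used.  The method actually applied is recorded.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return List with `statistic` (Mann-Whitney U for the first sample),
#'   `p` (two-sided), `method` ("exact" or "normal-approx"), `n_a`, `n_b`.
#' @export
wilcoxon_ranksum <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal-approx",
       n_a = length(a), n_b = length(b))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged); the two-sided p-value
#' uses the t approximation.  Binary variables (e.g. sex coded woman = 1)
#' are rank-coded like any other variable.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @param stratum optional label recorded in the result.
#' @return List with `rho`, `p`, `n`, `stratum`, `defined` (FALSE when
#'   either variable has zero variance, in which case `rho`/`p` are NA).
#' @export
spearman_cor <- function(x, y, stratum = "all") {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, stratum = stratum,
                defined = FALSE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n, stratum = stratum,
       defined = TRUE)
}

#' Bonferroni significance flags for a family of tests
#'
#' @param pvals numeric p-values.
#' @param m declared family size, `m >= length(pvals)`, `m >= 1`.
#' @param alpha family-wise level (default 0.05).
#' @return Data frame with `p`, `significant` (p < alpha/m), `m`, `alpha`.
#' @export
bonferroni_family <- function(pvals, m = length(pvals), alpha = 0.05) {
  if (m < 1) stop("family size must be >= 1", call. = FALSE)
  if (m < length(pvals)) stop("family smaller than number of tests", call. = FALSE)
  data.frame(p = pvals, significant = pvals < alpha / m, m = m, alpha = alpha)
}

#' Build the cohort comparison and correlation tables
#'
#' Produces the standard report from a per-subject network-metrics table and
#' subject metadata:
#' * `table1`: demographics (age, BDI) by sex, median (P25-P75) + rank-sum p;
#' * `table2`: per stage x domain, group medians (P25-P75), rank-sum p, and
#'   a Bonferroni flag whose family is the five band tests within each
#'   stage (time-domain tests are judged at the raw level; the family size
#'   is configurable and always recorded);
#' * `table3`: Spearman correlation of sex (woman = 1) with the small-world
#'   coefficient, all subjects;
#' * `table4`: Spearman correlation of BDI with the small-world coefficient,
#'   stratified by sex.
#'
#' @param metrics data.frame with columns `subject_id`, `stage`, `domain`,
#'   `swc` (one row per subject x stage x domain).
#' @param subjects data.frame with columns `subject_id`, `sex` ("M"/"F"),
#'   `age`, `bdi`.
#' @param alpha significance level (0.05).
#' @param band_family Bonferroni family size for the per-stage band tests
#'   (default 5, the number of EEG bands).
#' @return Object of class `stats_tables`: list of data.frames `table1` ..
#'   `table4` plus `meta` (quartile convention, alpha, family size).
#' @export
build_report <- function(metrics, subjects, alpha = 0.05, band_family = 5L) {
  req <- c("subject_id", "stage", "domain", "swc")
  if (!all(req %in% names(metrics)))
    stop("metrics must have columns subject_id, stage, domain, swc", call. = FALSE)
  df <- merge(metrics, subjects, by = "subject_id")
  fmt_mi <- function(v) sprintf("%.3f (%.3f-%.3f)", v[1], v[2], v[3])

  ## table 1: demographics
  t1 <- do.call(rbind, lapply(c("age", "bdi"), function(var) {
    m <- subjects[[var]][subjects$sex == "M"]
    w <- subjects[[var]][subjects$sex == "F"]
    data.frame(variable = var,
               men = fmt_mi(median_iqr(m)), women = fmt_mi(median_iqr(w)),
               p = wilcoxon_ranksum(m, w)$p)
  }))

  ## table 2: group comparison per stage x domain
  combos <- unique(df[, c("stage", "domain")])
  combos <- combos[order(combos$stage, combos$domain != "time", combos$domain), ]
  t2 <- do.call(rbind, lapply(seq_len(nrow(combos)), function(r) {
    st <- combos$stage[r]; dm <- combos$domain[r]
    sub <- df[df$stage == st & df$domain == dm, ]
    m <- sub$swc[sub$sex == "M"]; w <- sub$swc[sub$sex == "F"]
    if (!length(m) || !length(w)) return(NULL)
    wt <- wilcoxon_ranksum(m, w)
    fam <- if (dm == "time") 1L else as.integer(band_family)
    data.frame(stage = st, domain = dm,
               men = fmt_mi(median_iqr(m)), women = fmt_mi(median_iqr(w)),
               men_median = median_iqr(m)[1], women_median = median_iqr(w)[1],
               p = wt$p, bonferroni_m = fam,
               significant = wt$p < alpha / fam)
  }))
  rownames(t2) <- NULL

  ## table 3: sex (woman = 1) vs SWC, all subjects
  t3 <- do.call(rbind, lapply(seq_len(nrow(combos)), function(r) {
    st <- combos$stage[r]; dm <- combos$domain[r]
    sub <- df[df$stage == st & df$domain == dm, ]
    sc <- spearman_cor(as.numeric(sub$sex == "F"), sub$swc)
    data.frame(stage = st, domain = dm, rho = sc$rho, p = sc$p, n = sc$n)
  }))
  rownames(t3) <- NULL

  ## table 4: BDI vs SWC within sex
  t4 <- do.call(rbind, lapply(c("M", "F"), function(sx)
    do.call(rbind, lapply(seq_len(nrow(combos)), function(r) {
      st <- combos$stage[r]; dm <- combos$domain[r]
      sub <- df[df$stage == st & df$domain == dm & df$sex == sx, ]
      if (nrow(sub) < 3L) return(NULL)
      sc <- spearman_cor(sub$bdi, sub$swc, stratum = sx)
      data.frame(sex = sx, stage = st, domain = dm, rho = sc$rho, p = sc$p,
                 n = sc$n)
    }))))
  rownames(t4) <- NULL

  structure(list(table1 = t1, table2 = t2, table3 = t3, table4 = t4,
                 meta = list(alpha = alpha, band_family = band_family,
                             quartiles = "linear interpolation (type 7)",
                             sex_coding = "woman = 1, man = 0")),
            class = "stats_tables")
}

#' @export
print.stats_tables <- function(x, ...) {
  cat("Cohort report\n== Demographics ==\n"); print(x$table1)
  cat("== Network comparison (men vs women) ==\n")
  print(x$table2[, c("stage", "domain", "men", "women", "p", "significant")])
  cat("== Sex vs SWC (Spearman) ==\n"); print(x$table3)
  cat("== BDI vs SWC by sex (Spearman) ==\n"); print(x$table4)
  invisible(x)
}

#' Write the report tables to a directory
#'
#' Emits `table1.csv` .. `table4.csv` plus a human-readable `report.txt`.
#' Output is byte-deterministic for identical inputs.
#'
#' @param tables a `stats_tables` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in c("table1", "table2", "table3", "table4")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  rp <- file.path(dir, "report.txt")
  con <- file(rp, "w"); sink(con); print(tables); sink(); close(con)
  invisible(c(paths, rp))
}
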