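#' Indicator classification thresholds
#'
#' Bands for the three genetic-diversity indicators: annual reduction in
#' a diversity metric (<= 0.05%/yr Acceptable, 0.06-0.3%/yr Warning,
#' > 0.3%/yr Alarm), effective population size (Ne >= 500 Acceptable,
#' 50 < Ne < 500 Warning, Ne <= 50 Alarm) and change in expected
#' migrants Nm (migration reduced by 25% / 50% -> Warning / Alarm;
#' increased by 50% / 100% -> Warning / Alarm).
#'
#' @param annual_warning,annual_alarm annual-loss band edges (%/yr).
#' @param ne_low,ne_high Ne band edges.
#' @param migration_warning,migration_alarm relative Nm-change band
#'   edges (fractions).
#' @param alpha significance level for the gating tests.
#' @return list of class `indicator_thresholds`.
#' @export
indicator_thresholds <- function(annual_warning = 0.05, annual_alarm = 0.3,
                                 ne_low = 50, ne_high = 500,
                                 migration_warning = 0.25,
                                 migration_alarm = 0.5,
                                 alpha = 0.05) {
  stopifnot(annual_warning < annual_alarm, ne_low < ne_high,
            migration_warning < migration_alarm, alpha > 0, alpha < 1)
  structure(list(annual_warning = annual_warning,
                 annual_alarm = annual_alarm,
                 ne_low = ne_low, ne_high = ne_high,
                 migration_warning = migration_warning,
                 migration_alarm = migration_alarm, alpha = alpha),
            class = "indicator_thresholds")
}

#' Annualised percent change of a metric
#'
#' Linear annual change: `100 * (m2 - m1) / (m1 * years)` percent per
#' year (total proportional change divided by the period, not compound).
#'
#' @param m1 metric at the earlier time point (positive).
#' @param m2 metric at the later time point.
#' @param years length of the period (positive).
#' @return percent change per year (negative = loss of the metric).
#' @export
annual_change <- function(m1, m2, years) {
  if (any(m1 <= 0)) stop("m1 must be positive")
  if (any(years <= 0)) stop("years must be positive")
  100 * (m2 - m1) / (m1 * years)
}

#' Classify temporal change in a within-population diversity metric
#'
#' Two-sample t-test and Wilcoxon rank-sum test compare per-sample
#' metric values between the time points. A non-significant difference
#' (t-test at `alpha`; a concordance flag records whether the Wilcoxon
#' test agrees) is Acceptable regardless of magnitude. Otherwise the
#' annualised loss rate — the annual change in the metric's loss
#' direction — is classified against the annual-reduction bands.
#'
#' @param values_t1,values_t2 per-sample metric values at the two time
#'   points (>= 2 each).
#' @param years period between the time points.
#' @param direction "loss-when-decreasing" (heterozygosity, pi) or
#'   "loss-when-increasing" (F_ROH, where a rise means erosion).
#' @param name indicator name for the report.
#' @param thresholds an [indicator_thresholds()] object.
#' @return list of class `indicator_report`.
#' @export
classify_delta_h <- function(values_t1, values_t2, years,
                             direction = c("loss-when-decreasing",
                                           "loss-when-increasing"),
                             name = "deltaH",
                             thresholds = indicator_thresholds()) {
  direction <- match.arg(direction)
  if (length(values_t1) < 2 || length(values_t2) < 2)
    stop("need >= 2 samples per time point")
  m1 <- mean(values_t1); m2 <- mean(values_t2)
  tt <- stats::t.test(values_t1, values_t2)
  wt <- suppressWarnings(stats::wilcox.test(values_t1, values_t2))
  sig_t <- tt$p.value < thresholds$alpha
  sig_w <- wt$p.value < thresholds$alpha
  ac <- annual_change(m1, m2, years)
  loss <- if (direction == "loss-when-decreasing") -ac else ac
  status <- if (!sig_t) "Acceptable"
  else if (loss <= thresholds$annual_warning) "Acceptable"
  else if (loss <= thresholds$annual_alarm) "Warning"
  else "Alarm"
  structure(list(indicator = name, period_years = years,
                 metric_t1 = m1, metric_t2 = m2,
                 annual_change_pct = ac, loss_pct_per_year = loss,
                 t_p = tt$p.value, wilcoxon_p = wt$p.value,
                 concordant = sig_t == sig_w,
                 status = status),
            class = "indicator_report")
}

#' Classify effective population size
#'
#' Ne >= 500 is Acceptable, 50 < Ne < 500 Warning, Ne <= 50 Alarm (the
#' boundary Ne = 50 falls to Alarm, Ne = 500 to Acceptable).
#'
#' @param ne effective population size (positive), e.g. an LD-based
#'   estimate for the most recent generation.
#' @param thresholds an [indicator_thresholds()] object.
#' @return "Acceptable", "Warning" or "Alarm".
#' @export
classify_ne <- function(ne, thresholds = indicator_thresholds()) {
  if (any(ne <= 0)) stop("ne must be positive")
  ifelse(ne >= thresholds$ne_high, "Acceptable",
         ifelse(ne > thresholds$ne_low, "Warning", "Alarm"))
}

#' Convert F_ST to expected number of migrants
#'
#' Wright's island-model relation `Nm = (1 - F_ST) / (4 F_ST)`. Note the
#' island-model assumptions (many equal-sized demes at equilibrium)
#' rarely hold exactly; Nm is used as a relative gene-flow scale.
#'
#' @param fst F_ST value(s) strictly inside (0, 1).
#' @return expected migrants per generation.
#' @export
fst_to_migrants <- function(fst) {
  if (any(fst <= 0 | fst >= 1)) stop("fst must be in (0, 1)")
  (1 - fst) / (4 * fst)
}

#' Classify temporal change in between-population differentiation
#'
#' A paired Wilcoxon signed-rank test over shared windows gates the
#' indicator: population extinction is Alarm outright; no significant
#' window-level change is Acceptable; otherwise genome-wide mean F_ST at
#' each time point is converted to expected migrants Nm and the relative
#' Nm change classified (decrease >= 50% or increase >= 100% Alarm;
#' decrease >= 25% or increase >= 50% Warning).
#'
#' @param track_t1,track_t2 `diversity_track`s with identical window
#'   coordinates (>= 10 shared non-missing windows).
#' @param populations_maintained FALSE if any population went extinct
#'   over the monitoring period (forces Alarm).
#' @param summary_fun genome-wide summary fed to the Nm conversion
#'   (default mean; median available).
#' @param thresholds an [indicator_thresholds()] object.
#' @return list of class `indicator_report`.
#' @export
classify_delta_fst <- function(track_t1, track_t2,
                               populations_maintained = TRUE,
                               summary_fun = mean,
                               thresholds = indicator_thresholds()) {
  if (!populations_maintained) {
    return(structure(list(indicator = "deltaFST", status = "Alarm",
                          reason = "population extinct"),
                     class = "indicator_report"))
  }
  if (nrow(track_t1) != nrow(track_t2) ||
      any(track_t1$chrom != track_t2$chrom) ||
      any(track_t1$start != track_t2$start))
    stop("tracks must share window coordinates")
  ok <- !is.na(track_t1$value) & !is.na(track_t2$value)
  if (sum(ok) < 10) stop("fewer than 10 shared windows")
  v1 <- track_t1$value[ok]; v2 <- track_t2$value[ok]
  wt <- suppressWarnings(stats::wilcox.test(v1, v2, paired = TRUE))
  f1 <- summary_fun(v1); f2 <- summary_fun(v2)
  base <- list(indicator = "deltaFST", fst_t1 = f1, fst_t2 = f2,
               wilcoxon_p = wt$p.value)
  if (wt$p.value >= thresholds$alpha) {
    return(structure(c(base, list(status = "Acceptable")),
                     class = "indicator_report"))
  }
  nm1 <- fst_to_migrants(f1); nm2 <- fst_to_migrants(f2)
  rel <- (nm2 - nm1) / nm1
  # decrease bands use the stated fractions; increase bands are twice them
  # (reduced 25%/50% -> Warning/Alarm; increased 50%/100% -> Warning/Alarm)
  status <- if (rel <= -thresholds$migration_alarm ||
                rel >= 2 * thresholds$migration_alarm) "Alarm"
  else if (rel <= -thresholds$migration_warning ||
           rel >= 2 * thresholds$migration_warning) "Warning"
  else "Acceptable"
  structure(c(base, list(nm_t1 = nm1, nm_t2 = nm2,
                         nm_change_pct = 100 * rel, status = status)),
            class = "indicator_report")
}

#' @export
print.indicator_report <- function(x, ...) {
  cat(sprintf("indicator %s: %s\n", x$indicator, x$status))
  for (f in setdiff(names(x), c("indicator", "status")))
    cat(sprintf("  %s: %s\n", f,
                paste(format(x[[f]], digits = 5), collapse = " ")))
  invisible(x)
}
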