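# Consensus CGM outcome metrics, insulin totals, and paired nonparametric
# comparison of delivery arms.

#' Consensus CGM metrics for one episode
#'
#' Computes the standardized CGM outcome set: mean/median/max/min glucose,
#' coefficient of variation, glucose management indicator
#' (GMI = 3.31 + 0.02392 x mean), the band percentages for
#' <54, 54-69, 70-140, 70-180, 141-180, 181-250 and >250 mg/dL, and the
#' glycemia risk index
#' GRI = 3.0(<54) + 2.4(54-69) + 1.6(>250) + 0.8(181-250), capped at 100.
#'
#' @param trace episode trace data.frame (column \code{cgm}) or a numeric
#'   CGM vector on the 5-min grid
#' @return object of class \code{metrics_report} (named list)
#' @export
cgm_metrics <- function(trace) {
  g <- if (is.data.frame(trace)) trace$cgm else as.numeric(trace)
  if (length(g) == 0) stop("empty CGM trace")
  pct <- function(cond) 100 * mean(cond)
  below54 <- pct(g < 54)
  b54to69 <- pct(g >= 54 & g < 70)
  b70to140 <- pct(g >= 70 & g <= 140)
  b141to180 <- pct(g > 140 & g <= 180)
  b181to250 <- pct(g > 180 & g <= 250)
  above250 <- pct(g > 250)
  gri <- min(100, 3.0 * below54 + 2.4 * b54to69 +
               1.6 * above250 + 0.8 * b181to250)
  structure(list(
    mean = mean(g), median = stats::median(g), max = max(g), min = min(g),
    cv = 100 * stats::sd(g) / mean(g),
    gmi = 3.31 + 0.02392 * mean(g),
    below54 = below54, b54to69 = b54to69,
    b70to140 = b70to140, tir70_180 = b70to140 + b141to180,
    b141to180 = b141to180, b181to250 = b181to250, above250 = above250,
    tbr = below54 + b54to69, tar = b181to250 + above250,
    gri = gri), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("CGM: mean %.1f, median %.1f, CV %.1f%%, GMI %.2f%%\n",
              x$mean, x$median, x$cv, x$gmi))
  cat(sprintf("TIR 70-180: %.1f%%  TBR <70: %.1f%%  TAR >180: %.1f%%  GRI %.1f\n",
              x$tir70_180, x$tbr, x$tar, x$gri))
  if (!is.null(x$basal_per_day))
    cat(sprintf("Insulin: basal %.1f U/day, bolus %.1f U/day, TDI %.1f U\n",
                x$basal_per_day, x$bolus_per_day, x$tdi_per_day))
  invisible(x)
}

#' Insulin totals per day
#'
#' Time-integral of the continuous (basal + PD) infusion rate plus the sum
#' of boluses, each divided by the number of days; their sum is the
#' delivered TDI.
#'
#' @param trace episode trace with columns \code{basal_U_per_h},
#'   \code{bolus_U} on the 5-min grid
#' @param dt sample period (min)
#' @return list(basal_per_day, bolus_per_day, tdi_per_day)
#' @export
insulin_totals <- function(trace, dt = 5) {
  days <- nrow(trace) * dt / 1440
  basal <- sum(trace$basal_U_per_h) * dt / 60 / days
  bolus <- sum(trace$bolus_U) / days
  list(basal_per_day = basal, bolus_per_day = bolus,
       tdi_per_day = basal + bolus)
}

#' Hypoglycemia events in a CGM trace
#'
#' An event is at least 15 consecutive minutes (3 consecutive 5-min
#' samples) below 70 mg/dL; a new event starts after a return above 70.
#'
#' @param cgm CGM vector on the 5-min grid
#' @param threshold event threshold (mg/dL)
#' @param min_samples minimum consecutive samples below threshold
#' @return number of events
#' @export
hypo_events <- function(cgm, threshold = 70, min_samples = 3L) {
  below <- cgm < threshold
  r <- rle(below)
  sum(r$values & r$lengths >= min_samples)
}

#' Paired comparison of two arms
#'
#' Two-sided Wilcoxon signed-rank test per metric on per-patient paired
#' reports, with median (IQR) summaries per arm.
#'
#' @param reports_A,reports_B lists of \code{metrics_report} (same patients,
#'   same order)
#' @param metrics metric names to compare
#' @return data.frame: metric, median/IQR per arm, p.value
#' @export
paired_compare <- function(reports_A, reports_B,
                           metrics = c("mean", "median", "cv", "gmi",
                                       "tir70_180", "tbr", "tar", "gri")) {
  stopifnot(length(reports_A) == length(reports_B))
  n <- length(reports_A)
  if (n < 6) warning("fewer than 6 pairs: exact Wilcoxon p-values are coarse")
  rows <- lapply(metrics, function(m) {
    a <- vapply(reports_A, function(r) r[[m]], numeric(1))
    b <- vapply(reports_B, function(r) r[[m]], numeric(1))
    p <- if (all(a == b)) 1 else
      suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
    qa <- stats::quantile(a, c(.25, .5, .75), names = FALSE)
    qb <- stats::quantile(b, c(.25, .5, .75), names = FALSE)
    data.frame(metric = m,
               A = sprintf("%.1f (%.1f - %.1f)", qa[2], qa[1], qa[3]),
               B = sprintf("%.1f (%.1f - %.1f)", qb[2], qb[1], qb[3]),
               p.value = p)
  })
  do.call(rbind, rows)
}
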