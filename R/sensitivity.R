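#' Temperature coefficient Q10
#'
#' `Q10 = (R2 / R1)^(10 / (T2 - T1))`: the factor by which a rate changes
#' per 10 degC. Symmetric in direction -- swapping the (rate, temperature)
#' pairs gives the identical value.
#'
#' @param r1,r2 Rates at `t1` and `t2` (> 0).
#' @param t1,t2 Temperatures, degC (`t1 != t2`). Vectorised.
#' @return Q10 value(s); NA with a warning where a rate is non-positive.
#' @examples
#' q10(40, 100, 2, 8)  # (2.5)^(10/6) = 4.605
#' @export
q10 <- function(r1, r2, t1, t2) {
  if (any(t1 == t2)) stop("t1 and t2 must differ")
  bad <- r1 <= 0 | r2 <= 0
  if (any(bad, na.rm = TRUE))
    warning("Q10 undefined for non-positive rates; returning NA")
  out <- (r2 / r1)^(10 / (t2 - t1))
  out[bad] <- NA_real_
  out
}

#' Percent change of performance with cooling
#'
#' Signed percent change of the mean value from the warm end of an
#' interval to the cold end: `100 * (mean_low - mean_high) / mean_high`.
#' Negative values are performance losses with cooling. Unlike Q10, this
#' is meaningful for non-rate metrics (chase duration, recovery time,
#' responsiveness).
#'
#' @param mean_low Group mean at the low temperature.
#' @param mean_high Group mean at the high temperature (reference; != 0).
#' @return Percent change; NA with a warning where the reference is 0.
#' @examples
#' percent_change(40, 100)  # -60
#' @export
percent_change <- function(mean_low, mean_high) {
  bad <- mean_high == 0
  if (any(bad, na.rm = TRUE))
    warning("percent change undefined for zero reference mean; returning NA")
  out <- 100 * (mean_low - mean_high) / mean_high
  out[bad] <- NA_real_
  out
}

#' Default acute/acclimated temperature intervals
#'
#' The three acute intervals (14-20, 14-8, 8-2 degC) and two acclimated
#' intervals (14-8, 8-2 degC) bracketing a winter dormancy threshold of
#' about 8 degC; no acclimated 14-20 interval exists because fish are not
#' acclimated above 14 degC.
#'
#' @return Data frame with columns `treatment`, `t_low`, `t_high`, `label`.
#' @export
default_intervals <- function() {
  out <- data.frame(
    treatment = c("acute", "acute", "acute", "acclimated", "acclimated"),
    t_low = c(14, 8, 2, 8, 2),
    t_high = c(20, 14, 8, 14, 8),
    stringsAsFactors = FALSE)
  out$label <- sprintf("%s %g-%g", out$treatment, out$t_high, out$t_low)
  out
}

#' Omnibus summary of per-metric sensitivity values
#'
#' Arithmetic mean and dispersion (SD, s.e.m., quartiles) of the
#' per-metric Q10 or percent-change values for one temperature interval
#' and treatment.
#'
#' @param values Numeric vector of per-metric values (NAs dropped).
#' @return List: `mean`, `sd`, `sem`, `median`, `q25`, `q75`, `n`.
#' @examples
#' omnibus(c(2.5, 3.0, 1.5, 3.8, 4.0, 4.9))$mean  # 3.283
#' @export
omnibus <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values to summarise")
  qs <- unname(quantile(values, c(0.25, 0.5, 0.75)))
  list(mean = mean(values),
       sd = if (length(values) > 1) sd(values) else 0,
       sem = if (length(values) > 1) sd(values) / sqrt(length(values)) else 0,
       median = qs[2], q25 = qs[1], q75 = qs[3], n = length(values))
}

.check_performance_table <- function(table) {
  need <- c("metric", "value", "temperature", "treatment", "is_rate")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop(sprintf("performance table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  invisible(table)
}

#' Interval-wise thermal sensitivity of a performance table
#'
#' The core statistic engine: for every metric x treatment x temperature
#' interval it computes Q10 from the arithmetic group means at the two
#' endpoint temperatures (different fish are tested at each temperature,
#' so means -- not individual pairs -- are the only valid basis) and the
#' percent change of the mean with cooling. Q10 is restricted to rate
#' metrics with positive endpoint means; percent change covers all
#' metrics. Omnibus summaries per interval x treatment then average the
#' per-metric Q10s of rate metrics and the percent changes of all metrics,
#' excluding metrics named in `omnibus_exclude` (by default SMR, a
#' maintenance cost rather than a performance).
#'
#' @param table Tidy performance table: columns `metric`, `value`,
#'   `temperature`, `treatment`, `is_rate` (and optionally `fish_id`).
#' @param intervals Interval definition as from [default_intervals()].
#' @param omnibus_exclude Metric names excluded from omnibus summaries
#'   (default `"smr"`, case-insensitive).
#' @return Object of class `thermal_sensitivity` with elements `q10`
#'   (per-metric Q10 table), `percent_change`, `omnibus` (one row per
#'   interval x treatment x mode), `intervals`, `omnibus_exclude`.
#' @export
thermal_sensitivity <- function(table, intervals = default_intervals(),
                                omnibus_exclude = "smr") {
  .check_performance_table(table)
  table$treatment <- as.character(table$treatment)

  gm <- stats::aggregate(value ~ metric + treatment + temperature + is_rate,
                         data = table, FUN = mean)
  q10_rows <- list(); pct_rows <- list()
  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, ]
    sub <- gm[gm$treatment == iv$treatment, , drop = FALSE]
    for (m in unique(sub$metric)) {
      lo <- sub$value[sub$metric == m & sub$temperature == iv$t_low]
      hi <- sub$value[sub$metric == m & sub$temperature == iv$t_high]
      if (!length(lo) || !length(hi)) {
        warning(sprintf(
          "metric '%s', %s: missing group mean at an endpoint; skipped",
          m, iv$label))
        next
      }
      is_rate <- sub$is_rate[sub$metric == m][1]
      pct_rows[[length(pct_rows) + 1L]] <- data.frame(
        metric = m, treatment = iv$treatment, label = iv$label,
        t_low = iv$t_low, t_high = iv$t_high, mean_low = lo, mean_high = hi,
        percent_change = percent_change(lo, hi), is_rate = is_rate,
        stringsAsFactors = FALSE)
      if (isTRUE(is_rate) && lo > 0 && hi > 0) {
        q10_rows[[length(q10_rows) + 1L]] <- data.frame(
          metric = m, treatment = iv$treatment, label = iv$label,
          t_low = iv$t_low, t_high = iv$t_high, r_low = lo, r_high = hi,
          q10 = q10(lo, hi, iv$t_low, iv$t_high),
          stringsAsFactors = FALSE)
      }
    }
  }
  q10_tab <- if (length(q10_rows)) do.call(rbind, q10_rows) else
    data.frame(metric = character(0), treatment = character(0),
               label = character(0), t_low = numeric(0), t_high = numeric(0),
               r_low = numeric(0), r_high = numeric(0), q10 = numeric(0))
  pct_tab <- do.call(rbind, pct_rows)

  excl <- tolower(omnibus_exclude)
  omni <- list()
  for (lab in unique(intervals$label)) {
    qv <- q10_tab$q10[q10_tab$label == lab &
                        !tolower(q10_tab$metric) %in% excl]
    pv <- pct_tab$percent_change[pct_tab$label == lab &
                                   !tolower(pct_tab$metric) %in% excl]
    for (mode in c("q10_rates_only", "percent_change_all")) {
      vals <- if (mode == "q10_rates_only") qv else pv
      if (!length(vals)) next
      s <- omnibus(vals)
      omni[[length(omni) + 1L]] <- data.frame(
        label = lab, mode = mode, omnibus_mean = s$mean,
        omnibus_sd = s$sd, omnibus_sem = s$sem, median = s$median,
        q25 = s$q25, q75 = s$q75, n_metrics = s$n,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(q10 = q10_tab, percent_change = pct_tab,
                 omnibus = do.call(rbind, omni), intervals = intervals,
                 omnibus_exclude = omnibus_exclude),
            class = "thermal_sensitivity")
}

#' @export
print.thermal_sensitivity <- function(x, digits = 3, ...) {
  cat("Thermal sensitivity analysis\n\nPer-metric Q10 (rate metrics):\n")
  q <- x$q10
  if (nrow(q)) {
    q$q10 <- signif(q$q10, digits)
    print(q[, c("metric", "label", "q10")], row.names = FALSE)
  } else cat("  (none)\n")
  cat("\nOmnibus summaries:\n")
  o <- x$omnibus
  o$omnibus_mean <- signif(o$omnibus_mean, digits)
  o$omnibus_sd <- signif(o$omnibus_sd, digits)
  print(o[, c("label", "mode", "omnibus_mean", "omnibus_sd", "n_metrics")],
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.thermal_sensitivity <- function(object, ...) {
  print(object, ...)
  cat("\nPercent change (all metrics, cooling direction):\n")
  p <- object$percent_change
  p$percent_change <- signif(p$percent_change, 3)
  print(p[, c("metric", "label", "percent_change")], row.names = FALSE)
  invisible(object)
}

#' Plot per-metric thermal sensitivity
#'
#' Strip chart of per-metric Q10 (or percent change) by interval, the
#' standard way acute and acclimated thermal-sensitivity contrasts are
#' displayed.
#'
#' @param x A `thermal_sensitivity` object.
#' @param mode `"q10"` or `"percent_change"`.
#' @param ... Passed to [graphics::stripchart()].
#' @export
plot.thermal_sensitivity <- function(x, mode = c("q10", "percent_change"),
                                     ...) {
  mode <- match.arg(mode)
  if (mode == "q10") {
    tab <- x$q10; val <- tab$q10; ylab <- "Q10"; hline <- c(1, 3)
  } else {
    tab <- x$percent_change; val <- tab$percent_change
    ylab <- "% change with cooling"; hline <- 0
  }
  graphics::stripchart(val ~ factor(tab$label, unique(x$intervals$label)),
                       vertical = TRUE, pch = 16, method = "jitter",
                       ylab = ylab, xlab = "", las = 2, ...)
  abline(h = hline, lty = 3, col = "grey50")
  invisible(x)
}
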