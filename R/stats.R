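#' Two-way ANOVA of a performance metric (temperature x treatment)
#'
#' Tests the effects of temperature, acclimation status (acute vs
#' acclimated) and their interaction on one metric over the temperature
#' range shared by both treatments, with Tukey HSD post hoc comparisons at
#' alpha = 0.05. Type-II sums of squares are used to tolerate the mild
#' imbalance typical of these designs (group n varies).
#'
#' @param table Tidy performance table (see [thermal_sensitivity()]).
#' @param metric Metric name to analyse.
#' @param temperatures Temperatures included (default 14, 11, 8, 5, 2).
#' @return Object of class `perf_anova`: `anova_table` (term, df, F, p),
#'   `tukey` (list of pairwise tables), `fit` (the underlying `aov`).
#' @export
two_way_anova <- function(table, metric, temperatures = c(14, 11, 8, 5, 2)) {
  .check_performance_table(table)
  d <- table[table$metric == metric & table$temperature %in% temperatures, ]
  d <- d[!is.na(d$value), ]
  d$temperature <- factor(d$temperature)
  d$treatment <- factor(d$treatment)
  cells <- base::table(d$temperature, d$treatment)
  if (nrow(cells) < 2 || ncol(cells) < 2)
    stop("need at least 2 temperatures x 2 treatments")
  if (any(cells < 2)) {
    bad <- which(cells < 2, arr.ind = TRUE)
    stop(sprintf("cell(s) with <2 observations: %s",
                 paste(sprintf("%s degC/%s", rownames(cells)[bad[, 1]],
                               colnames(cells)[bad[, 2]]), collapse = ", ")))
  }
  fit <- aov(value ~ temperature * treatment, data = d)
  a2 <- car::Anova(fit, type = 2)
  terms <- rownames(a2)[rownames(a2) != "Residuals"]
  tab <- data.frame(term = terms, df = a2$Df[seq_along(terms)],
                    F = a2$`F value`[seq_along(terms)],
                    p = a2$`Pr(>F)`[seq_along(terms)],
                    stringsAsFactors = FALSE)
  tab$F[is.na(tab$F)] <- 0
  tab$p[is.na(tab$p)] <- 1
  tk <- TukeyHSD(fit)
  structure(list(anova_table = tab, tukey = lapply(tk, as.data.frame),
                 fit = fit, metric = metric), class = "perf_anova")
}

#' One-way ANOVA of a performance metric across temperatures
#'
#' For the broad acute series (conventionally 26-2 degC) measured on
#' warm-acclimated fish only; Tukey HSD post hoc comparisons included.
#'
#' @inheritParams two_way_anova
#' @param treatment Treatment level analysed (default `"acute"`).
#' @param temperatures Temperatures included (default 26 to 2 by 3).
#' @return Object of class `perf_anova`.
#' @export
one_way_anova <- function(table, metric, treatment = "acute",
                          temperatures = seq(26, 2, by = -3)) {
  .check_performance_table(table)
  d <- table[table$metric == metric & table$treatment == treatment &
               table$temperature %in% temperatures, ]
  d <- d[!is.na(d$value), ]
  d$temperature <- factor(d$temperature)
  counts <- base::table(d$temperature)
  if (length(counts) < 2 || any(counts < 2))
    stop("need >=2 groups with >=2 observations each")
  fit <- aov(value ~ temperature, data = d)
  s <- summary(fit)[[1]]
  Fv <- s$`F value`[1]; pv <- s$`Pr(>F)`[1]
  if (is.na(Fv)) { Fv <- 0; pv <- 1 }
  tab <- data.frame(term = "temperature", df = s$Df[1], F = Fv, p = pv,
                    stringsAsFactors = FALSE)
  tk <- TukeyHSD(fit)
  structure(list(anova_table = tab, tukey = lapply(tk, as.data.frame),
                 fit = fit, metric = metric), class = "perf_anova")
}

#' @export
print.perf_anova <- function(x, digits = 4, ...) {
  cat(sprintf("ANOVA for metric '%s'\n", x$metric))
  tab <- x$anova_table
  tab$F <- signif(tab$F, digits); tab$p <- signif(tab$p, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA of omnibus thermal sensitivities across intervals
#'
#' Treats the per-metric Q10 (or percent-change) values as replicates and
#' tests whether mean thermal sensitivity differs among the
#' interval-treatment levels (acute 14-20, acute 14-8, acute 8-2,
#' acclimated 14-8, acclimated 8-2), with Tukey HSD post hoc tests.
#'
#' @param sens A `thermal_sensitivity` object, or a data frame with
#'   columns `label` and a value column.
#' @param mode `"q10"` (rate metrics) or `"percent_change"` (all metrics).
#' @return Object of class `perf_anova`.
#' @export
sensitivity_anova <- function(sens, mode = c("q10", "percent_change")) {
  mode <- match.arg(mode)
  if (inherits(sens, "thermal_sensitivity")) {
    excl <- tolower(sens$omnibus_exclude)
    d <- if (mode == "q10") {
      tab <- sens$q10[!tolower(sens$q10$metric) %in% excl, ]
      data.frame(label = tab$label, value = tab$q10)
    } else {
      tab <- sens$percent_change[
        !tolower(sens$percent_change$metric) %in% excl, ]
      data.frame(label = tab$label, value = tab$percent_change)
    }
  } else {
    d <- data.frame(label = sens$label, value = sens$value)
  }
  d <- d[!is.na(d$value), ]
  counts <- table(d$label)
  if (length(counts) < 2 || any(counts < 2))
    stop("need >=2 interval levels with >=2 metrics each")
  d$label <- factor(d$label)
  fit <- aov(value ~ label, data = d)
  s <- summary(fit)[[1]]
  Fv <- s$`F value`[1]; pv <- s$`Pr(>F)`[1]
  if (is.na(Fv)) { Fv <- 0; pv <- 1 }
  tab <- data.frame(term = "interval", df = s$Df[1], F = Fv, p = pv,
                    stringsAsFactors = FALSE)
  structure(list(anova_table = tab,
                 tukey = lapply(TukeyHSD(fit), as.data.frame),
                 fit = fit, metric = paste("omnibus", mode)),
            class = "perf_anova")
}

#' Levene's test of homogeneity of variances
#'
#' Mean-centred Levene test: a one-way ANOVA on the absolute deviations of
#' each observation from its group mean.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector (>= 2 groups with >= 2 observations).
#' @return List: `W` (the test statistic, an F ratio), `df` (length 2),
#'   `p`.
#' @export
levene <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  counts <- table(groups)
  if (length(counts) < 2 || any(counts < 2))
    stop("Levene's test needs >=2 groups with >=2 observations each")
  lt <- car::leveneTest(values, groups, center = mean)
  list(W = lt$`F value`[1], df = c(lt$Df[1], lt$Df[2]),
       p = lt$`Pr(>F)`[1])
}

#' Effort-EPOC regression with slope comparison
#'
#' Ordinary least squares of mean total EPOC on mean exhaustive exercise
#' effort, per treatment, across the temperature range common to acute and
#' acclimated exposures; the treatments' slopes are compared via the
#' effort x treatment interaction of a pooled model.
#'
#' @param effort_epoc Data frame with columns `effort` (BL), `epoc`
#'   (mg O2 kg^-1) and `treatment`, one row per temperature x treatment
#'   group mean; >= 3 points per treatment.
#' @return Object of class `effort_epoc_reg`: `per_treatment` (slope,
#'   intercept, r2, p per treatment), `slope_difference_p` (interaction p),
#'   `pooled_fit`, `fits`.
#' @export
effort_epoc_regression <- function(effort_epoc) {
  stopifnot(all(c("effort", "epoc", "treatment") %in% names(effort_epoc)))
  d <- effort_epoc[!is.na(effort_epoc$effort) & !is.na(effort_epoc$epoc), ]
  counts <- table(d$treatment)
  if (any(counts < 3))
    stop("need >=3 temperature points per treatment for regression")
  fits <- lapply(split(d, d$treatment), function(g) lm(epoc ~ effort, g))
  per <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    s <- summary(f)
    data.frame(treatment = nm, slope = unname(coef(f)[2]),
               intercept = unname(coef(f)[1]), r2 = s$r.squared,
               p = if (nrow(s$coefficients) > 1) s$coefficients[2, 4]
                   else NA_real_,
               n = nrow(f$model), stringsAsFactors = FALSE)
  }))
  d$treatment <- factor(d$treatment)
  pooled <- lm(epoc ~ effort * treatment, data = d)
  ct <- summary(pooled)$coefficients
  int_row <- grep("effort:", rownames(ct))
  structure(list(per_treatment = per,
                 slope_difference_p = if (length(int_row))
                   ct[int_row[1], 4] else NA_real_,
                 pooled_fit = pooled, fits = fits),
            class = "effort_epoc_reg")
}

#' @export
print.effort_epoc_reg <- function(x, digits = 4, ...) {
  cat("Effort-EPOC linear regressions\n")
  per <- x$per_treatment
  per[, c("slope", "intercept", "r2", "p")] <-
    lapply(per[, c("slope", "intercept", "r2", "p")], signif, digits)
  print(per, row.names = FALSE)
  cat(sprintf("slope difference (effort x treatment interaction): p = %s\n",
              signif(x$slope_difference_p, digits)))
  invisible(x)
}
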