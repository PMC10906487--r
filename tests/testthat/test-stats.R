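test_that("one-way ANOVA matches the brute-force sums of squares", {
  # identical groups: no between-group variance at all
  g <- data.frame(temperature = c(14, 8), treatment = "acute")
  g$values <- list(c(1, 2, 3), c(1, 2, 3))
  tab <- make_perf_table(g)
  a <- one_way_anova(tab, "m", temperatures = c(14, 8))
  expect_equal(a$anova_table$F, 0)
  expect_equal(a$anova_table$p, 1)

  # textbook three-group case against hand-computed normal equations
  vals <- list(c(6, 8, 4, 5, 3, 4), c(8, 12, 9, 11, 6, 8),
               c(13, 9, 11, 8, 7, 12))
  tab2 <- make_perf_table(data.frame(temperature = c(14, 8, 2),
                                     treatment = "acute",
                                     values = I(vals)))
  a2 <- one_way_anova(tab2, "m", temperatures = c(14, 8, 2))
  all_v <- unlist(vals)
  grand <- mean(all_v)
  ss_b <- sum(vapply(vals, function(v) length(v) * (mean(v) - grand)^2,
                     numeric(1)))
  ss_w <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1)))
  F_oracle <- (ss_b / 2) / (ss_w / (length(all_v) - 3))
  expect_equal(a2$anova_table$F, F_oracle, tolerance = 1e-9)

  # Tukey-adjusted p never undercuts the unadjusted pairwise p
  mse <- ss_w / (length(all_v) - 3)
  tk <- a2$tukey$temperature
  se <- sqrt(mse * (1 / 6 + 1 / 6))
  p_unadj <- 2 * pt(-abs(tk$diff / se), df = length(all_v) - 3)
  expect_true(all(tk$`p adj` >= p_unadj - 1e-9))
})

test_that("two-way ANOVA handles degenerate and structured designs", {
  # every cell holds the same set: all effect sums of squares are zero
  g <- expand.grid(temperature = c(14, 8, 2),
                   treatment = c("acute", "acclimated"),
                   stringsAsFactors = FALSE)
  g$values <- replicate(6, c(1, 2, 3), simplify = FALSE)
  tab <- make_perf_table(g)
  a <- two_way_anova(tab, "m", temperatures = c(14, 8, 2))
  expect_equal(a$anova_table$F, rep(0, 3))
  expect_equal(a$anova_table$p, rep(1, 3))
  expect_setequal(a$anova_table$term,
                  c("temperature", "treatment", "temperature:treatment"))

  # type-I/II coincide on balanced data: check the partition of SS exactly
  set.seed(77)
  g2 <- g
  g2$values <- replicate(6, rnorm(4, 5), simplify = FALSE)
  tab2 <- make_perf_table(g2)
  a2 <- two_way_anova(tab2, "m", temperatures = c(14, 8, 2))
  s <- summary(a2$fit)[[1]]
  expect_equal(sum(s$`Sum Sq`),
               sum((tab2$value - mean(tab2$value))^2), tolerance = 1e-9)

  # empty/thin cells are named in the error
  thin <- tab2[!(tab2$temperature == 8 & tab2$treatment == "acclimated"), ]
  expect_error(two_way_anova(thin, "m", temperatures = c(14, 8, 2)),
               "observations")
})

test_that("omnibus-sensitivity ANOVA separates interval levels", {
  labs <- c("acute 14-8", "acute 8-2", "acclimated 14-8", "acclimated 8-2")
  d_null <- data.frame(label = rep(labs, each = 4),
                       value = rep(c(1.5, 1.7, 1.6, 1.4), times = 4))
  a <- sensitivity_anova(d_null)
  expect_equal(a$anova_table$F, 0)

  set.seed(13)
  d_eff <- data.frame(label = rep(labs, each = 6),
                      value = rnorm(24, 1.6, 0.3))
  d_eff$value[d_eff$label == "acute 8-2"] <-
    d_eff$value[d_eff$label == "acute 8-2"] + 2
  a2 <- sensitivity_anova(d_eff)
  expect_lt(a2$anova_table$p, 0.01)
  tk <- a2$tukey$label
  hot <- grepl("acute 8-2", rownames(tk))
  expect_true(all(tk$`p adj`[hot] < 0.05))

  # metric ordering is irrelevant
  a3 <- sensitivity_anova(d_eff[sample(nrow(d_eff)), ])
  expect_equal(a3$anova_table$F, a2$anova_table$F, tolerance = 1e-12)

  expect_error(sensitivity_anova(d_null[d_null$label == labs[1], ]),
               "levels")
})

test_that("Levene's test matches the brute-force deviation ANOVA", {
  # identical sets shifted: absolute deviations coincide, W = 0
  v <- c(1, 2, 3, 11, 12, 13)
  gr <- rep(c("a", "b"), each = 3)
  lv <- levene(v, gr)
  expect_equal(lv$W, 0, tolerance = 1e-12)
  expect_true(lv$p >= 0 && lv$p <= 1)

  # 2 x 3 toy: one-way ANOVA on |x - group mean| computed by hand
  v2 <- c(1, 4, 7, 2, 2, 14)
  gr2 <- rep(c("a", "b"), each = 3)
  dev <- abs(v2 - ave(v2, gr2))
  grand <- mean(dev)
  means <- tapply(dev, gr2, mean)
  ss_b <- sum(3 * (means - grand)^2)
  ss_w <- sum((dev - ave(dev, gr2))^2)
  W_oracle <- (ss_b / 1) / (ss_w / 4)
  expect_equal(levene(v2, gr2)$W, W_oracle, tolerance = 1e-9)

  expect_error(levene(1:3, c("a", "a", "b")), "2 observations")
})

test_that("effort-EPOC regressions recover exact and perturbed slopes", {
  d <- data.frame(effort = rep(c(100, 200, 300, 400, 500), 2),
                  treatment = rep(c("acute", "acclimated"), each = 5))
  d$epoc <- ifelse(d$treatment == "acute", 2 * d$effort, 0.5 * d$effort)
  r <- suppressWarnings(effort_epoc_regression(d))  # exact fit warns in summary.lm
  per <- r$per_treatment
  expect_equal(per$slope[per$treatment == "acute"], 2, tolerance = 1e-9)
  expect_equal(per$slope[per$treatment == "acclimated"], 0.5,
               tolerance = 1e-9)
  expect_equal(per$r2, c(1, 1), tolerance = 1e-12)
  expect_lt(r$slope_difference_p, 1e-6)

  # collinear points with one outlier: slope equals the normal equations
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 6, 8, 15)
  d2 <- data.frame(effort = rep(x, 2), epoc = rep(y, 2),
                   treatment = rep(c("acute", "acclimated"), each = 5))
  r2 <- suppressWarnings(effort_epoc_regression(d2))
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(r2$per_treatment$slope, rep(slope_oracle, 2),
               tolerance = 1e-9)

  expect_error(effort_epoc_regression(d[c(1, 2, 6, 7, 8), ]), "3 temperature")
})
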