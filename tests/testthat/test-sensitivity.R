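test_that("Q10 matches direct evaluation and its algebraic identities", {
  expect_equal(q10(3, 3, 2, 8), 1)
  expect_equal(q10(1, 2, 4, 14), 2)
  expect_equal(q10(40, 100, 2, 8), 2.5^(10 / 6), tolerance = 1e-12)  # 4.605

  set.seed(31)
  for (i in 1:20) {
    r <- runif(3, 0.1, 10)   # rates at 14, 8, 2 degC
    # composition over equal 6-degC spans
    expect_equal(q10(r[3], r[1], 2, 14),
                 sqrt(q10(r[3], r[2], 2, 8) * q10(r[2], r[1], 8, 14)),
                 tolerance = 1e-12)
    # scale invariance
    c0 <- runif(1, 0.5, 20)
    expect_equal(q10(c0 * r[2], c0 * r[1], 8, 14), q10(r[2], r[1], 8, 14),
                 tolerance = 1e-12)
    # direction symmetry
    expect_equal(q10(r[2], r[1], 8, 14), q10(r[1], r[2], 14, 8),
                 tolerance = 1e-12)
  }

  expect_warning(na <- q10(0, 5, 2, 8), "non-positive")
  expect_true(is.na(na))
  expect_error(q10(1, 2, 8, 8), "differ")
})

test_that("percent change is signed in the cooling direction", {
  expect_equal(percent_change(40, 100), -60)
  expect_equal(percent_change(7, 7), 0)
  expect_equal(percent_change(20, 80), -75)   # responsiveness-style collapse
  expect_warning(na <- percent_change(5, 0), "zero reference")
  expect_true(is.na(na))
})

test_that("omnibus mean and dispersion summarise per-metric values", {
  s <- omnibus(c(2.5, 3.0, 1.5, 3.8, 4.0, 4.9))
  expect_equal(s$mean, 3.283333, tolerance = 1e-6)
  expect_equal(s$n, 6)
  expect_equal(omnibus(4.2)$mean, 4.2)
  allsame <- omnibus(rep(2, 5))
  expect_equal(allsame$mean, 2)
  expect_equal(allsame$sd, 0)
  expect_error(omnibus(NA_real_), "no values")
})

test_that("interval engine inverts the generator exactly at cv = 0", {
  p <- simulate_performance_dataset(cv = 0, q10_above = 2, q10_below = 5,
                                    compensation_factor = 1, n_per_group = 3)
  sens <- thermal_sensitivity(p$table)
  q <- sens$q10
  get <- function(lab) q$q10[q$label == lab]
  expect_equal(get("acute 20-14"), 2, tolerance = 1e-9)
  expect_equal(get("acute 14-8"), 2, tolerance = 1e-9)
  expect_equal(get("acute 8-2"), 5, tolerance = 1e-9)
  expect_equal(get("acclimated 14-8"), 2, tolerance = 1e-9)
  expect_equal(get("acclimated 8-2"), 5, tolerance = 1e-9)

  # no acclimated 14-20 interval exists by design
  expect_false(any(grepl("acclimated 20", q$label)))

  # compensation lowers only the acclimated below-threshold Q10
  p2 <- simulate_performance_dataset(cv = 0, compensation_factor = 1.733,
                                     n_per_group = 3)
  q2 <- thermal_sensitivity(p2$table)$q10
  expect_equal(q2$q10[q2$label == "acclimated 8-2"],
               5 / 1.733^(10 / 6), tolerance = 1e-9)
  expect_equal(q2$q10[q2$label == "acute 8-2"], 5, tolerance = 1e-9)

  # row order of the table is irrelevant
  shuffled <- p$table[sample(nrow(p$table)), ]
  expect_equal(thermal_sensitivity(shuffled)$q10$q10, q$q10,
               tolerance = 1e-12)
})

test_that("rate/non-rate classification and SMR exclusion drive the omnibus", {
  p_rate <- simulate_performance_dataset(cv = 0, n_per_group = 2,
                                         metric = "mmr")$table
  p_non <- simulate_performance_dataset(cv = 0, n_per_group = 2,
                                        metric = "responsiveness",
                                        is_rate = FALSE)$table
  p_smr <- simulate_performance_dataset(cv = 0, n_per_group = 2,
                                        metric = "smr")$table
  sens <- thermal_sensitivity(rbind(p_rate, p_non, p_smr))

  # Q10 exists for rate metrics only; percent change for all
  expect_setequal(unique(sens$q10$metric), c("mmr", "smr"))
  expect_setequal(unique(sens$percent_change$metric),
                  c("mmr", "responsiveness", "smr"))

  # SMR never enters the omnibus, in either mode
  o <- sens$omnibus
  expect_true(all(o$n_metrics[o$mode == "q10_rates_only"] == 1))   # mmr only
  expect_true(all(o$n_metrics[o$mode == "percent_change_all"] == 2))

  # missing endpoint: a metric absent at one endpoint is skipped with warning
  partial <- p_rate[p_rate$temperature != 8, ]
  w <- capture_warnings(thermal_sensitivity(partial))
  expect_true(all(grepl("skipped", w)) && length(w) >= 1)
})

test_that("print and plot methods run", {
  p <- simulate_performance_dataset(cv = 0, n_per_group = 2)
  sens <- thermal_sensitivity(p$table)
  expect_output(print(sens), "Omnibus")
  expect_output(summary(sens), "Percent change")
  pdf(NULL)
  expect_silent(plot(sens))
  dev.off()
})
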