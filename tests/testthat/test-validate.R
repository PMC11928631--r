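# LOB / LOD / LOQ, repeatability and probit hit rate

test_that("CV uses sample SD and reproduces the reference replicate panel", {
  res <- cv_percent(c(20.6694, 18.8806, 8.8278))
  expect_equal(res$mean, 16.1259, tolerance = 1e-4)
  expect_equal(res$cv_pct, 39.58, tolerance = 1e-2)
  res2 <- cv_percent(c(14.9900, 11.7225, 13.7664))
  expect_equal(res2$mean, 13.4930, tolerance = 1e-4)
  expect_equal(res2$cv_pct, 12.23, tolerance = 1e-2)
  expect_equal(cv_percent(c(5, 5, 5))$cv_pct, 0)
  expect_error(cv_percent(5), "replicates")
  expect_error(cv_percent(c(-1, 1)), "zero")
})

test_that("repeatability summary averages per-sample CVs unweighted", {
  panel <- intra_assay_replicates()
  res <- repeatability_summary(panel)
  expect_equal(nrow(res$cv_table), 8)
  expect_equal(res$mean_cv_pct, 25.38, tolerance = 1e-2)
  one <- repeatability_summary(panel["LD8"])
  expect_equal(one$mean_cv_pct, one$cv_table$cv_pct[1])
  two <- repeatability_summary(list(a = c(10, 9, 11) * 1,
                                    b = c(10, 7, 13)))
  expect_equal(two$mean_cv_pct, mean(two$cv_table$cv_pct))
  expect_error(repeatability_summary(list(bad = 1)), "bad")
})

test_that("limit of blank is mean + 1.645 SD of the blank panel", {
  expect_equal(limit_of_blank(rep(0, 22)), 0)
  expect_equal(limit_of_blank(c(0, 0, 0, 1)), 0.25 + 1.645 * 0.5)
  expect_equal(limit_of_blank(rep(3.2, 10)), 3.2)  # SD 0
  expect_error(limit_of_blank(0), "2 blank")
})

test_that("limit of detection adds 1.645 SD of the lowest level to the LOB", {
  expect_equal(limit_of_detection(0, sd = 0.00007), 1.645 * 0.00007)
  expect_equal(round(limit_of_detection(0, sd = 0.00007), 6), 0.000115)
  expect_equal(signif(limit_of_detection(0, sd = 0.00007), 1), 1e-4)
  expect_equal(limit_of_detection(0.5, sd = 0.1), 0.6645)
  expect_equal(limit_of_detection(0.3, sd = 0), 0.3)
  expect_equal(limit_of_detection(0, c(1, 1, 1)), 0)
  expect_error(limit_of_detection(0), "sd or")
})

test_that("LOQ selects the lowest level with CV at or below the ceiling", {
  mk <- function(m, cv) scale_to_mean_sd(rnorm(3), m, m * cv / 100)
  set.seed(1)
  levels <- list(L1 = mk(100, 27), L2 = mk(10, 40), L3 = mk(1, 25),
                 L4 = mk(0.1, 20))
  res <- limit_of_quantification(levels, cv_max_pct = 35)
  expect_true(res$reached)
  expect_equal(res$level, "L4")
  expect_equal(res$cv_pct, 20, tolerance = 1e-6)
  # all above ceiling -> explicit not-reached
  none <- limit_of_quantification(list(L1 = mk(10, 50), L2 = mk(1, 60)),
                                  cv_max_pct = 35)
  expect_false(none$reached)
  # boundary: CV exactly at the ceiling qualifies
  res35 <- limit_of_quantification(list(L1 = mk(10, 35)), cv_max_pct = 35)
  expect_true(res35$reached)
  expect_error(limit_of_quantification(list(a = mk(1, 10), b = mk(2, 10))),
               "decreasing")
})

test_that("all-or-nothing hit rates flag the probit fit as degenerate", {
  det <- data.frame(n_detected = c(3, 3, 3, 3), n_replicates = 3,
                    concentration = c(0.016, 0.0016, 0.0006, 0.0003))
  res <- probit_hit_rate(det)
  expect_equal(res$hit_rates$hit_rate, rep(1, 4))
  expect_identical(res$probit_fit, "degenerate")
  single <- probit_hit_rate(data.frame(n_detected = 0, n_replicates = 3,
                                       concentration = 0.001))
  expect_equal(single$hit_rates$hit_rate, 0)
  expect_identical(single$probit_fit, "degenerate")
  expect_error(probit_hit_rate(data.frame(n_detected = 1,
                                          n_replicates = 0,
                                          concentration = 1)),
               "replicates")
})

test_that("probit ML fit matches a grid-search oracle on varying rates", {
  det <- data.frame(n_detected = c(10, 5, 0), n_replicates = 10,
                    concentration = c(1, 0.1, 0.01))
  res <- probit_hit_rate(det)
  fit <- res$probit_fit
  expect_true(is.list(fit))
  expect_gt(fit$slope, 0)  # monotone increasing in concentration
  # c50 between the outer levels
  expect_gt(fit$c50, 0.01)
  expect_lt(fit$c50, 1)
  expect_gt(fit$c95, fit$c50)
  # grid-search maximum likelihood on the 3-point binomial likelihood
  lx <- log10(det$concentration)
  best <- c(ll = -Inf, b0 = NA, b1 = NA)
  for (b0 in seq(-2, 8, by = 0.05)) {
    for (b1 in seq(0.1, 8, by = 0.05)) {
      p <- pnorm(b0 + b1 * lx)
      ll <- sum(dbinom(det$n_detected, det$n_replicates, p, log = TRUE))
      if (ll > best["ll"]) best <- c(ll = ll, b0 = b0, b1 = b1)
    }
  }
  c50_grid <- 10^(-best[["b0"]] / best[["b1"]])
  expect_equal(log10(fit$c50), log10(c50_grid), tolerance = 0.05)
})
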