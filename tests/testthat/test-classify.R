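# thresholding, quadrant classification, QC and merging

test_that("threshold is pooled blank mean + k x SD per channel", {
  blank <- fixed_amplitude_well(n = 500, mean1 = 1000, sd1 = 100,
                                mean2 = 2000, sd2 = 50)
  thr <- fit_thresholds(list(blank), k_sd = 7)
  expect_equal(thr$ch1_threshold, 1700)
  expect_equal(thr$ch2_threshold, 2350)
  expect_equal(thr$n_blank_wells, 1)
})

test_that("constant blank amplitudes fall back to an absolute margin", {
  blank <- well_data("N1", "ntc",
                     data.frame(ch1 = rep(1000, 200),
                                ch2 = rep(1000, 200)))
  # one warning per constant channel
  expect_warning(expect_warning(
    thr <- fit_thresholds(list(blank), fallback_margin = 500),
    "fallback"), "fallback")
  expect_equal(thr$ch1_threshold, 1500)
})

test_that("empty blanks error and sparse blanks warn", {
  expect_error(fit_thresholds(list()), "blank")
  tiny <- well_data("N1", "ntc", data.frame(ch1 = rnorm(10, 1000, 100),
                                            ch2 = rnorm(10, 1000, 100)))
  expect_warning(fit_thresholds(list(tiny)), "100")
})

test_that("simulated thresholds separate clusters with no false positives", {
  thr <- fit_thresholds(sim_blank_wells(4, seed0 = 10), k_sd = 7)
  # threshold lies between the cluster means
  expect_gt(thr$ch1_threshold, 1000)
  expect_lt(thr$ch1_threshold, 8000)
  # P(blank droplet above mean + 7 SD) ~ pnorm(-7) ~ 1e-12: a fresh
  # 20k-droplet blank well yields zero positives
  fresh <- simulate_blank_well(sim_config(seed = 123), "NTC09")
  counts <- classify_well(fresh, thr)
  expect_equal(counts$n_ch1_only + counts$n_ch2_only + counts$n_dp, 0)
})

test_that("quadrant assignment is exhaustive, exclusive, and strict at the threshold", {
  thr <- structure(list(ch1_threshold = 1700, ch2_threshold = 1700,
                        method = "manual", k_sd = NA, n_blank_wells = 0),
                   class = "threshold_pair")
  w <- well_data("S1", "sample",
                 data.frame(ch1 = c(1000, 1700, 1700.01, 8000, 8000),
                            ch2 = c(1000, 1700, 1600.00, 1000, 8000)))
  counts <- classify_well(w, thr)
  expect_equal(counts$n_total, 5)
  # droplets exactly at threshold are negative (strict >)
  expect_equal(counts$n_dn, 2)
  expect_equal(counts$n_ch1_only, 2)
  expect_equal(counts$n_ch2_only, 0)
  expect_equal(counts$n_dp, 1)
  expect_equal(counts$n_dn + counts$n_ch1_only + counts$n_ch2_only +
                 counts$n_dp, counts$n_total)
})

test_that("all-negative wells classify as pure double negatives", {
  thr <- structure(list(ch1_threshold = 1700, ch2_threshold = 1700,
                        method = "manual", k_sd = NA, n_blank_wells = 0),
                   class = "threshold_pair")
  w <- well_data("S1", "sample",
                 data.frame(ch1 = runif(100, 500, 1500),
                            ch2 = runif(100, 500, 1500)))
  counts <- classify_well(w, thr)
  expect_equal(counts$n_dn, 100)
  expect_equal(counts$n_ch1_only + counts$n_ch2_only + counts$n_dp, 0)
})

test_that("exclusion regions remove droplets from the classified total", {
  thr <- structure(list(ch1_threshold = 1700, ch2_threshold = 1700,
                        method = "manual", k_sd = NA, n_blank_wells = 0),
                   class = "threshold_pair")
  w <- well_data("S1", "sample",
                 data.frame(ch1 = c(1000, 1900, 1901, 8000),
                            ch2 = c(1000, 1000, 1000, 1000)))
  # excludes the shifted double-negative sub-cluster around ch1 ~ 1900
  ex <- exclusion_region(c(1800, 2200), c(0, 1700), "shifted DN cluster")
  counts <- classify_well(w, thr, exclusions = list(ex))
  expect_equal(counts$n_excluded, 2)
  expect_equal(counts$n_total, 2)
  expect_equal(counts$n_ch1_only, 1)
  expect_error(exclusion_region(c(2, 1), c(0, 1)), "interval")
})

test_that("raising a threshold never increases positive counts", {
  set.seed(42)
  w <- well_data("S1", "sample",
                 data.frame(ch1 = c(rnorm(500, 1000, 100),
                                    rnorm(80, 8000, 300),
                                    runif(40, 1000, 8000)),
                            ch2 = rnorm(620, 1000, 100)))
  pos_at <- function(t) {
    thr <- structure(list(ch1_threshold = t, ch2_threshold = 1700,
                          method = "manual", k_sd = NA,
                          n_blank_wells = 0),
                     class = "threshold_pair")
    cc <- classify_well(w, thr)
    cc$n_ch1_only + cc$n_dp
  }
  ts <- seq(1200, 8500, by = 250)
  pos <- vapply(ts, pos_at, numeric(1))
  expect_true(all(diff(pos) <= 0))
})

test_that("QC keeps wells strictly above the droplet cutoff", {
  at <- qc_counts(10000, well_id = "A")
  above <- qc_counts(10001, well_id = "B")
  res <- qc_filter_wells(list(at, above))
  expect_length(res$kept, 1)
  expect_equal(res$kept[[1]]$well_id, "B")
  expect_equal(res$dropped$well_id, "A")
  expect_match(res$dropped$reason, "10000")
  empty <- qc_filter_wells(list())
  expect_length(empty$kept, 0)
  expect_equal(nrow(empty$dropped), 0)
})

test_that("merging sums counts field-wise and preserves the partition", {
  a <- qc_counts(15000, ch1_only = 190, ch2_only = 40, dp = 10,
                 well_id = "A", group_id = "G")
  b <- qc_counts(20000, ch1_only = 290, ch2_only = 40, dp = 10,
                 well_id = "B", group_id = "G")
  m <- merge_counts(list(a, b))
  expect_equal(m$n_total, 35000)
  expect_equal(m$n_total - m$n_ch1_only - m$n_dp, 34500)  # ch1-negatives
  expect_equal(m$n_dn + m$n_ch1_only + m$n_ch2_only + m$n_dp, m$n_total)
  expect_equal(m$group_id, "G")
})

test_that("merging a well with itself doubles counts but leaves lambda unchanged", {
  a <- qc_counts(12000, ch1_only = 300, dp = 50, group_id = "G")
  m <- merge_counts(list(a, a))
  expect_equal(m$n_total, 24000)
  lam1 <- estimate_lambda(a$n_total - a$n_ch1_only - a$n_dp,
                          a$n_total)$lambda
  lam2 <- estimate_lambda(m$n_total - m$n_ch1_only - m$n_dp,
                          m$n_total)$lambda
  expect_equal(lam1, lam2)
})

test_that("merging is commutative and associative; mixed groups error", {
  set.seed(9)
  counts <- lapply(1:4, function(i)
    qc_counts(10000 + i * 100, ch1_only = sample(0:50, 1),
              ch2_only = sample(0:500, 1), dp = sample(0:20, 1),
              well_id = paste0("W", i), group_id = "G"))
  m1 <- merge_counts(counts)
  m2 <- merge_counts(rev(counts))
  m3 <- merge_counts(list(merge_counts(counts[1:2]),
                          merge_counts(counts[3:4])))
  for (f in c("n_total", "n_dn", "n_ch1_only", "n_ch2_only", "n_dp")) {
    expect_equal(m1[[f]], m2[[f]])
    expect_equal(m1[[f]], m3[[f]])
  }
  other <- qc_counts(10000, group_id = "H")
  expect_error(merge_counts(c(counts, list(other))), "group")
})
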