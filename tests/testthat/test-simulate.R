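# synthetic droplet-plate generator

test_that("zero target concentration yields no true-positive droplets", {
  cfg <- sim_config(conc_target_per_ul = 0, conc_ref_per_ul = 500,
                    seed = 11)
  sim <- simulate_well(cfg)
  expect_true(all(sim$truth$droplets$k1 == 0))
  expect_gt(sum(sim$truth$droplets$k2 > 0), 0)
})

test_that("negative-droplet fraction follows the Poisson occupancy law", {
  # lambda = conc * E[V in uL]; expected negative fraction exp(-lambda)
  for (lambda in c(0.05, 0.105, 1.0)) {
    n <- 1e5
    cfg <- sim_config(conc_target_per_ul = lambda / 7e-4,
                      n_droplets_mean = n, n_droplets_sd = 0,
                      seed = round(1000 * lambda))
    sim <- simulate_well(cfg)
    p <- exp(-lambda)
    obs <- mean(sim$truth$droplets$k1 == 0)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs - p), 3 * se)
  }
})

test_that("the same seed and config regenerate an identical well", {
  cfg <- sim_config(conc_target_per_ul = 100, conc_ref_per_ul = 1000,
                    seed = 77)
  a <- simulate_well(cfg)
  b <- simulate_well(cfg)
  expect_identical(a$well$droplets, b$well$droplets)
  expect_identical(a$truth$droplets, b$truth$droplets)
})

test_that("droplet volumes are strictly positive even at large volume SD", {
  cfg <- sim_config(droplet_volume_nl_mean = 0.1,
                    droplet_volume_nl_sd = 0.3, seed = 5,
                    n_droplets_mean = 5000)
  sim <- simulate_well(cfg)
  expect_true(all(sim$truth$droplets$volume_nl > 0))
})

test_that("a non-positive drawn droplet count is a degenerate-config error", {
  cfg <- sim_config(n_droplets_mean = 1, n_droplets_sd = 50, seed = 1)
  expect_error(simulate_well(cfg), "degenerate")
})

test_that("the no-VB diagonal artifact shrinks the droplet count and smears both channels", {
  n <- 20000
  cfg <- sim_config(conc_target_per_ul = 100, conc_ref_per_ul = 100,
                    n_droplets_mean = n, n_droplets_sd = 0,
                    artifact = "no_vb_diagonal",
                    artifact_params = list(reduction = 0.6, fraction = 0.5,
                                           scale = 3000),
                    seed = 21)
  sim <- simulate_well(cfg)
  expect_equal(nrow(sim$well$droplets), round(0.6 * n))
  # smeared double negatives sit above the negative cluster on BOTH channels
  dn_idx <- which(sim$truth$droplets$k1 == 0 & sim$truth$droplets$k2 == 0)
  up <- sim$well$droplets$ch1[dn_idx] > 1000 + 5 * 100 &
    sim$well$droplets$ch2[dn_idx] > 1000 + 5 * 100
  expect_gt(sum(up), 0.3 * length(dn_idx))   # ~half smeared
  expect_gt(cor(sim$well$droplets$ch1[dn_idx[up]],
                sim$well$droplets$ch2[dn_idx[up]]), 0.9)  # shared offset
})

test_that("the shifted double-negative artifact relocates a Ch1 sub-cluster", {
  cfg <- sim_config(artifact = "shifted_dn_cluster",
                    artifact_params = list(fraction = 0.25, offset = 800),
                    n_droplets_mean = 20000, n_droplets_sd = 0, seed = 31)
  sim <- simulate_well(cfg)
  shifted <- sim$well$droplets$ch1 > 1400 & sim$well$droplets$ch1 < 2200
  frac <- mean(shifted)
  expect_gt(frac, 0.20)
  expect_lt(frac, 0.30)
})

test_that("blank wells carry zero true copies and no droplet above threshold", {
  blanks <- sim_blank_wells(4, seed0 = 400)
  thr <- fit_thresholds(blanks, k_sd = 7)
  fresh <- simulate_blank_well(sim_config(seed = 999), "NTC99")
  counts <- classify_well(fresh, thr)
  expect_equal(counts$n_ch1_only + counts$n_dp, 0)
  expect_equal(counts$n_ch2_only, 0)
})

test_that("dilution series emits levels x replicates wells with decreasing ratios", {
  plate <- simulate_dilution_series(
    sim_config(seed = 1, n_droplets_mean = 2000, n_droplets_sd = 200),
    targets_per_cell = c(0.016, 0.0016, 0.0006, 0.0003),
    cells_per_well = 2500, replicates = 3)
  expect_length(plate$wells, 12)
  expect_equal(nrow(plate$manifest), 12)
  expect_setequal(unique(plate$manifest$dilution),
                  c(0.016, 0.0016, 0.0006, 0.0003))
  expect_error(simulate_dilution_series(sim_config(), numeric(0), 1000),
               "empty")
  expect_error(simulate_dilution_series(sim_config(), c(0.01, 0), 1000),
               "positive")
  expect_error(simulate_dilution_series(sim_config(), c(0.001, 0.01), 1000),
               "decreasing")
})

test_that("rare dilution level loads the expected copies per well", {
  # 0.0003 targets/cell x 2500 cells -> 0.75 expected copies in a well's
  # droplets; fraction of wells with zero true positives ~ exp(-0.75)
  n_wells <- 100
  totals <- vapply(seq_len(n_wells), function(i) {
    base <- sim_config(seed = 5000 + i)
    plate <- simulate_dilution_series(base, 0.0003,
                                      cells_per_well = 2500,
                                      replicates = 1)
    sum(plate$truth[[1]]$droplets$k1)
  }, numeric(1))
  expect_lt(abs(mean(totals) - 0.75), 3 * sqrt(0.75 / n_wells))
  p0 <- exp(-0.75)
  expect_lt(abs(mean(totals == 0) - p0),
            3 * sqrt(p0 * (1 - p0) / n_wells))
})

test_that("blank panel has the requested arity and roles", {
  plate <- simulate_blank_panel(sim_config(seed = 3, n_droplets_mean = 500,
                                           n_droplets_sd = 50),
                                n_ntc = 11, n_clc = 11)
  expect_length(plate$wells, 22)
  expect_equal(sum(plate$manifest$role == "ntc"), 11)
  expect_equal(sum(plate$manifest$role == "clc"), 11)
})

test_that("classified positives never exceed ground-truth positives without rain", {
  blanks <- sim_blank_wells(3, seed0 = 50)
  thr <- fit_thresholds(blanks)
  for (seed in 1:5) {
    cfg <- sim_config(conc_target_per_ul = 200, conc_ref_per_ul = 2000,
                      rain_fraction = 0, seed = seed)
    sim <- simulate_well(cfg)
    counts <- classify_well(sim$well, thr)
    expect_lte(counts$n_ch1_only + counts$n_dp,
               sum(sim$truth$droplets$k1 > 0))
    expect_lte(counts$n_ch2_only + counts$n_dp,
               sum(sim$truth$droplets$k2 > 0))
  }
})
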