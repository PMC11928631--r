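# shared fixtures: all synthetic, built in code at test time

# rescale a vector to an exact mean and sample SD
scale_to_mean_sd <- function(x, m, s) {
  m + s * (x - mean(x)) / stats::sd(x)
}

# a well with given exact amplitude means/SDs on both channels
fixed_amplitude_well <- function(n = 500, mean1 = 1000, sd1 = 100,
                                 mean2 = 1000, sd2 = 100,
                                 well_id = "B01", role = "ntc",
                                 seed = 1) {
  set.seed(seed)
  well_data(well_id, role,
            data.frame(ch1 = scale_to_mean_sd(rnorm(n), mean1, sd1),
                       ch2 = scale_to_mean_sd(rnorm(n), mean2, sd2)))
}

# blank wells from the simulator
sim_blank_wells <- function(n_wells = 4, seed0 = 100, ...) {
  lapply(seq_len(n_wells), function(i)
    simulate_blank_well(sim_config(seed = seed0 + i, ...),
                        well_id = sprintf("NTC%02d", i)))
}

# a quadrant_counts object from raw numbers, defaulting the rest to dn
qc_counts <- function(n_total, ch1_only = 0, ch2_only = 0, dp = 0,
                      excluded = 0, well_id = "W", group_id = "G") {
  quadrant_counts(n_total = n_total,
                  n_dn = n_total - ch1_only - ch2_only - dp,
                  n_ch1_only = ch1_only, n_ch2_only = ch2_only,
                  n_dp = dp, n_excluded = excluded,
                  well_id = well_id, group_id = group_id)
}
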