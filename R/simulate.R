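# Synthetic droplet plates with known ground truth.
#
# The generator emulates a two-channel droplet digital PCR experiment run on
# crude cell lysate: Poisson loading of target (Ch1, FAM) and reference
# (Ch2, HEX) copies into ~10^4 droplets of ~0.70 nL each, four amplitude
# clusters (double-negative, single-positives, double-positive) with
# Gaussian spread, an optional "rain" fraction of intermediate amplitudes,
# and the two artifacts observed in lysate runs without a
# viscosity-breakdown pre-treatment (a diagonal smear with reduced droplet
# count, and an upward-shifted double-negative cluster).

VALID_ROLES <- c("sample", "ntc", "clc", "dna_control")

#' Simulation configuration for synthetic ddPCR wells
#'
#' Collects every generative parameter of a simulated well. Defaults
#' describe a typical crude-lysate reaction: ~20,000 droplets of mean volume
#' 0.70 nL (SD 0.022 nL, the measured lysate droplet-volume spread),
#' negative amplitude clusters at 1000 (SD 100) and positive clusters at
#' 8000/7000 (SD 300) so clusters are far (> 8 SD) apart, and a small rain
#' fraction.
#'
#' @param n_droplets_mean,n_droplets_sd Mean and SD of the per-well droplet
#'   count; the count is drawn once per well from a rounded normal.
#' @param droplet_volume_nl_mean,droplet_volume_nl_sd Mean and SD of the
#'   per-droplet volume in nL; volumes are truncated-normal (strictly
#'   positive).
#' @param conc_target_per_ul,conc_ref_per_ul True concentrations, copies/µL,
#'   of the target (Ch1) and reference (Ch2) species.
#' @param neg_mean_ch1,neg_sd_ch1,pos_mean_ch1,pos_sd_ch1 Gaussian amplitude
#'   cluster parameters for channel 1 (likewise `*_ch2` for channel 2).
#' @param neg_mean_ch2,neg_sd_ch2,pos_mean_ch2,pos_sd_ch2 See above.
#' @param rain_fraction Probability in `[0, 1)` that a truly positive
#'   droplet's amplitude is drawn uniformly between the negative and
#'   positive cluster means instead of from the positive cluster
#'   ("rain": partial amplification / delayed onset).
#' @param artifact One of `"none"`, `"no_vb_diagonal"` (diagonal smear plus
#'   droplet-count reduction seen without viscosity breakdown) or
#'   `"shifted_dn_cluster"` (a sub-cluster of double negatives shifted
#'   upward in Ch1).
#' @param artifact_params Named list of artifact knobs. For
#'   `no_vb_diagonal`: `reduction` (droplet-count multiplier < 1, default
#'   0.6), `fraction` (fraction of droplets smeared, default 0.3), `scale`
#'   (max shared amplitude offset, default 3000). For `shifted_dn_cluster`:
#'   `fraction` (default 0.25) and `offset` (Ch1 shift, default 800).
#' @param seed Integer seed; every stochastic draw for the well derives
#'   from it, so the same config regenerates the identical well.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_droplets_mean = 20000, n_droplets_sd = 1000,
                       droplet_volume_nl_mean = 0.70,
                       droplet_volume_nl_sd = 0.022,
                       conc_target_per_ul = 0, conc_ref_per_ul = 0,
                       neg_mean_ch1 = 1000, neg_sd_ch1 = 100,
                       pos_mean_ch1 = 8000, pos_sd_ch1 = 300,
                       neg_mean_ch2 = 1000, neg_sd_ch2 = 100,
                       pos_mean_ch2 = 7000, pos_sd_ch2 = 300,
                       rain_fraction = 0.01,
                       artifact = c("none", "no_vb_diagonal",
                                    "shifted_dn_cluster"),
                       artifact_params = list(), seed = 1L) {
  artifact <- match.arg(artifact)
  if (conc_target_per_ul < 0 || conc_ref_per_ul < 0)
    stop("concentrations must be >= 0")
  if (rain_fraction < 0 || rain_fraction >= 1)
    stop("rain_fraction must be in [0, 1)")
  if (pos_mean_ch1 <= neg_mean_ch1 || pos_mean_ch2 <= neg_mean_ch2)
    stop("positive cluster mean must exceed negative cluster mean")
  if (droplet_volume_nl_mean <= 0)
    stop("droplet_volume_nl_mean must be > 0")
  if (n_droplets_mean <= 0) stop("n_droplets_mean must be > 0")
  structure(list(
    n_droplets_mean = n_droplets_mean, n_droplets_sd = n_droplets_sd,
    droplet_volume_nl_mean = droplet_volume_nl_mean,
    droplet_volume_nl_sd = droplet_volume_nl_sd,
    conc_target_per_ul = conc_target_per_ul,
    conc_ref_per_ul = conc_ref_per_ul,
    neg_mean_ch1 = neg_mean_ch1, neg_sd_ch1 = neg_sd_ch1,
    pos_mean_ch1 = pos_mean_ch1, pos_sd_ch1 = pos_sd_ch1,
    neg_mean_ch2 = neg_mean_ch2, neg_sd_ch2 = neg_sd_ch2,
    pos_mean_ch2 = pos_mean_ch2, pos_sd_ch2 = pos_sd_ch2,
    rain_fraction = rain_fraction, artifact = artifact,
    artifact_params = artifact_params, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Per-well droplet data
#'
#' The unit of raw input: one reaction well's droplet amplitudes plus
#' metadata. `droplets` must contain finite numeric columns `ch1` and `ch2`;
#' an optional `cluster` column carries the ground-truth quadrant (1 =
#' double-negative, 2 = Ch1-only, 3 = Ch2-only, 4 = double-positive).
#'
#' @param well_id Well identifier, e.g. `"A01"`.
#' @param role One of `"sample"`, `"ntc"`, `"clc"`, `"dna_control"`.
#' @param droplets Data frame of per-droplet amplitudes.
#' @param group_id Replicate-merge key; wells sharing a `group_id` are
#'   summed before Poisson estimation.
#' @param metadata Optional named list.
#' @return An object of class `well_data`.
#' @export
well_data <- function(well_id, role, droplets, group_id = well_id,
                      metadata = list()) {
  role <- match.arg(role, VALID_ROLES)
  if (!is.data.frame(droplets) ||
      !all(c("ch1", "ch2") %in% names(droplets)))
    stop("droplets must be a data frame with columns ch1 and ch2")
  if (nrow(droplets) > 0 &&
      (!all(is.finite(droplets$ch1)) || !all(is.finite(droplets$ch2))))
    stop("droplet amplitudes must be finite")
  structure(list(well_id = as.character(well_id), role = role,
                 droplets = droplets, group_id = as.character(group_id),
                 metadata = metadata),
            class = "well_data")
}

#' @export
print.well_data <- function(x, ...) {
  cat(sprintf("<well_data> %s (role %s, group %s): %d droplets\n",
              x$well_id, x$role, x$group_id, nrow(x$droplets)))
  invisible(x)
}

# positive truncated-normal draws (resample any non-positive value)
rtruncnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

# amplitude draw for one channel given per-droplet copy counts
draw_amplitudes <- function(k, neg_mean, neg_sd, pos_mean, pos_sd,
                            rain_fraction) {
  amp <- stats::rnorm(length(k), neg_mean, neg_sd)
  pos <- which(k > 0)
  if (length(pos) > 0) {
    amp[pos] <- stats::rnorm(length(pos), pos_mean, pos_sd)
    if (rain_fraction > 0) {
      rain <- pos[stats::runif(length(pos)) < rain_fraction]
      if (length(rain) > 0)
        amp[rain] <- stats::runif(length(rain), neg_mean, pos_mean)
    }
  }
  amp
}

#' Simulate one ddPCR well with ground truth
#'
#' Draws a droplet count `N ~ round(Normal(mean, sd))`, per-droplet volumes
#' `V_i` (truncated normal, nL), per-droplet copy counts
#' `k ~ Poisson(conc × V_i × 1e-3)` independently per channel (the standard
#' dPCR partition model: copies distribute independently across droplets),
#' then amplitudes from the negative cluster if `k = 0` and from the
#' positive cluster (or uniform "rain") otherwise. Artifact transforms are
#' applied last.
#'
#' @param config A [sim_config()].
#' @param well_id,role,group_id Well metadata (see [well_data()]).
#' @return A list with elements `well` (a `well_data`) and `truth`: the
#'   per-droplet copy counts and volumes plus the true concentrations and
#'   the true target-per-cell ratio (assuming a diploid reference, 2
#'   copies/cell).
#' @export
simulate_well <- function(config, well_id = "A01", role = "sample",
                          group_id = well_id) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- as.integer(round(stats::rnorm(1, config$n_droplets_mean,
                                     config$n_droplets_sd)))
  if (n <= 0)
    stop("degenerate config: drawn droplet count is not positive")
  vol <- rtruncnorm_pos(n, config$droplet_volume_nl_mean,
                        config$droplet_volume_nl_sd)
  # nL -> µL conversion: copies per droplet = conc [copies/µL] × V [µL]
  k1 <- stats::rpois(n, config$conc_target_per_ul * vol * 1e-3)
  k2 <- stats::rpois(n, config$conc_ref_per_ul * vol * 1e-3)
  ch1 <- draw_amplitudes(k1, config$neg_mean_ch1, config$neg_sd_ch1,
                         config$pos_mean_ch1, config$pos_sd_ch1,
                         config$rain_fraction)
  ch2 <- draw_amplitudes(k2, config$neg_mean_ch2, config$neg_sd_ch2,
                         config$pos_mean_ch2, config$pos_sd_ch2,
                         config$rain_fraction)

  if (config$artifact == "no_vb_diagonal") {
    p <- config$artifact_params
    reduction <- if (is.null(p$reduction)) 0.6 else p$reduction
    fraction <- if (is.null(p$fraction)) 0.3 else p$fraction
    scale <- if (is.null(p$scale)) 3000 else p$scale
    if (reduction <= 0 || reduction > 1)
      stop("no_vb_diagonal reduction must be in (0, 1]")
    keep <- seq_len(max(1L, as.integer(round(n * reduction))))
    vol <- vol[keep]; k1 <- k1[keep]; k2 <- k2[keep]
    ch1 <- ch1[keep]; ch2 <- ch2[keep]
    m <- length(keep)
    smear <- which(stats::runif(m) < fraction)
    off <- scale * stats::runif(length(smear))  # shared offset -> diagonal
    ch1[smear] <- ch1[smear] + off
    ch2[smear] <- ch2[smear] + off
  } else if (config$artifact == "shifted_dn_cluster") {
    p <- config$artifact_params
    fraction <- if (is.null(p$fraction)) 0.25 else p$fraction
    offset <- if (is.null(p$offset)) 800 else p$offset
    dn <- which(k1 == 0 & k2 == 0)
    shift <- dn[stats::runif(length(dn)) < fraction]
    ch1[shift] <- ch1[shift] + offset
  }

  cluster <- ifelse(k1 > 0 & k2 > 0, 4L,
                    ifelse(k1 > 0, 2L, ifelse(k2 > 0, 3L, 1L)))
  well <- well_data(well_id, role,
                    data.frame(ch1 = ch1, ch2 = ch2, cluster = cluster),
                    group_id = group_id,
                    metadata = list(seed = config$seed))
  truth <- list(
    droplets = data.frame(k1 = k1, k2 = k2, volume_nl = vol),
    conc_target_per_ul = config$conc_target_per_ul,
    conc_ref_per_ul = config$conc_ref_per_ul,
    targets_per_cell = if (config$conc_ref_per_ul > 0)
      config$conc_target_per_ul / (config$conc_ref_per_ul / 2) else NA_real_
  )
  list(well = well, truth = truth)
}

#' Simulate a blank (NTC or CLC) well
#'
#' As [simulate_well()] with both concentrations forced to zero and rain
#' disabled: every amplitude comes from the negative clusters and no droplet
#' carries a true copy.
#'
#' @param config A [sim_config()]; its concentrations and rain are ignored.
#' @param well_id Well identifier.
#' @param role `"ntc"` (no-template control) or `"clc"` (cell-lysate
#'   control).
#' @param group_id Merge key, defaults to the well id.
#' @return A `well_data`.
#' @export
simulate_blank_well <- function(config, well_id = "NTC01", role = "ntc",
                                group_id = well_id) {
  role <- match.arg(role, c("ntc", "clc"))
  cfg <- config
  cfg$conc_target_per_ul <- 0
  cfg$conc_ref_per_ul <- 0
  cfg$rain_fraction <- 0
  simulate_well(cfg, well_id = well_id, role = role,
                group_id = group_id)$well
}

#' A plate: wells plus manifest
#'
#' @param wells Named list of `well_data` (names = well ids).
#' @param manifest Data frame with columns `well`, `sample_id`, `role`,
#'   `group`, `dilution`, `replicate`, `cells_per_well`.
#' @param truth Optional named list of per-well ground truth.
#' @param seed Optional integer recorded for provenance.
#' @return An object of class `plate_data`.
#' @export
plate_data <- function(wells, manifest, truth = NULL, seed = NULL) {
  required <- c("well", "sample_id", "role", "group", "dilution",
                "replicate", "cells_per_well")
  if (!all(required %in% names(manifest)))
    stop("manifest missing columns: ",
         paste(setdiff(required, names(manifest)), collapse = ", "))
  if (anyDuplicated(manifest$well))
    stop("duplicate well ids in manifest")
  ids <- vapply(wells, function(w) w$well_id, character(1))
  names(wells) <- ids
  if (!setequal(ids, manifest$well))
    stop("manifest wells and amplitude wells do not match")
  bad <- setdiff(manifest$role, VALID_ROLES)
  if (length(bad) > 0)
    stop("unknown role(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(VALID_ROLES, collapse = ", "))
  structure(list(wells = wells, manifest = manifest, truth = truth,
                 seed = seed),
            class = "plate_data")
}

#' @export
print.plate_data <- function(x, ...) {
  cat(sprintf("<plate_data> %d wells (%s)\n", length(x$wells),
              paste(sprintf("%d %s", table(x$manifest$role),
                            names(table(x$manifest$role))),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate a dilution series plate
#'
#' Builds a standard-curve plate: for each target-per-cell ratio, replicate
#' samples of `wells_per_group` reaction wells each (replicate wells of one
#' sample share a merge group, mirroring the practice of splitting one
#' lysate across several reactions and summing the droplet counts). The
#' reference (Ch2) concentration is set from the cell input at
#' `ref_copies_per_cell` copies per cell; the target concentration is the
#' ratio times the per-cell reference. `cells_per_well` counts the cells
#' captured in a well's droplets, so the expected number of target copies
#' among a well's droplets is `ratio × cells_per_well`.
#'
#' @param base A [sim_config()] supplying droplet counts, volumes, amplitude
#'   clusters, rain, and the base seed (each well gets a distinct seed
#'   derived from it).
#' @param targets_per_cell Positive, strictly decreasing ratios, one per
#'   dilution level.
#' @param cells_per_well Cells captured in the screened droplets of one
#'   well.
#' @param replicates Replicate samples per level.
#' @param wells_per_group Reaction wells per replicate sample (merged
#'   downstream).
#' @param ref_copies_per_cell Reference copies per cell (2 for a diploid
#'   autosomal single-copy gene such as RPP30).
#' @return A [plate_data()] with per-well ground truth attached.
#' @export
simulate_dilution_series <- function(base, targets_per_cell, cells_per_well,
                                     replicates = 3, wells_per_group = 1,
                                     ref_copies_per_cell = 2) {
  if (length(targets_per_cell) == 0) stop("empty ratio list")
  if (any(targets_per_cell <= 0)) stop("ratios must be positive")
  if (length(targets_per_cell) > 1 && any(diff(targets_per_cell) >= 0))
    stop("ratios must be strictly decreasing")
  if (replicates < 1) stop("replicates must be >= 1")
  screened_ul <- base$n_droplets_mean * base$droplet_volume_nl_mean * 1e-3
  wells <- list()
  truth <- list()
  rows <- list()
  for (l in seq_along(targets_per_cell)) {
    ratio <- targets_per_cell[l]
    conc_ref <- ref_copies_per_cell * cells_per_well / screened_ul
    conc_target <- ratio * cells_per_well / screened_ul
    for (r in seq_len(replicates)) {
      group <- sprintf("Dil%d_R%d", l, r)
      for (w in seq_len(wells_per_group)) {
        cfg <- base
        cfg$conc_target_per_ul <- conc_target
        cfg$conc_ref_per_ul <- conc_ref
        cfg$seed <- as.integer(base$seed + 10000L * l + 100L * r + w)
        wid <- sprintf("D%dR%dW%d", l, r, w)
        sim <- simulate_well(cfg, well_id = wid, role = "sample",
                             group_id = group)
        wells[[wid]] <- sim$well
        truth[[wid]] <- sim$truth
        rows[[length(rows) + 1L]] <- data.frame(
          well = wid, sample_id = group, role = "sample", group = group,
          dilution = ratio, replicate = r, cells_per_well = cells_per_well,
          stringsAsFactors = FALSE)
      }
    }
  }
  plate_data(wells, do.call(rbind, rows), truth = truth, seed = base$seed)
}

#' Add blank wells to a plate (or build a blank-only plate)
#'
#' Convenience wrapper creating `n_ntc` no-template and `n_clc` cell-lysate
#' control wells from a base configuration.
#'
#' @param base A [sim_config()].
#' @param n_ntc,n_clc Numbers of blank wells of each role.
#' @param plate Optional existing [plate_data()] to extend.
#' @return A [plate_data()].
#' @export
simulate_blank_panel <- function(base, n_ntc = 11, n_clc = 11,
                                 plate = NULL) {
  wells <- list()
  rows <- list()
  add <- function(role, i, idx) {
    cfg <- base
    cfg$seed <- as.integer(base$seed + 900000L + idx)
    wid <- sprintf("%s%02d", toupper(role), i)
    wells[[wid]] <<- simulate_blank_well(cfg, well_id = wid, role = role)
    rows[[length(rows) + 1L]] <<- data.frame(
      well = wid, sample_id = wid, role = role, group = wid,
      dilution = NA_real_, replicate = 1L, cells_per_well = NA_real_,
      stringsAsFactors = FALSE)
  }
  idx <- 0L
  for (i in seq_len(n_ntc)) { idx <- idx + 1L; add("ntc", i, idx) }
  for (i in seq_len(n_clc)) { idx <- idx + 1L; add("clc", i, idx) }
  manifest <- do.call(rbind, rows)
  if (is.null(plate))
    return(plate_data(wells, manifest, seed = base$seed))
  plate_data(c(plate$wells, wells), rbind(plate$manifest, manifest),
             truth = plate$truth, seed = plate$seed)
}
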