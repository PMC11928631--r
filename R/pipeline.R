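# End-to-end pipeline: thresholds -> classification -> QC -> replicate
# merging -> Poisson quantification -> validation report.

#' Pipeline configuration
#'
#' Fixed analysis constants with their assay defaults: droplet volume
#' 0.70 nL (microscopy-corrected), thresholds at blank mean + 7 SD, a
#' diploid reference gene (2 copies/cell), 20 µL loaded reaction volume,
#' LOQ CV ceiling 35%, and the > 10,000 accepted-droplets QC rule.
#'
#' @param droplet_volume_nl Droplet volume used for all concentrations,
#'   nL.
#' @param threshold_k_sd Blank-SD multiplier for [fit_thresholds()].
#' @param ref_copies_per_cell Reference-gene copies per cell.
#' @param reaction_volume_ul Loaded reaction volume, µL.
#' @param cv_max_pct LOQ CV ceiling, percent.
#' @param qc_min_droplets QC cutoff (strict `>`).
#' @param exclusions List of [exclusion_region()]s applied to every well.
#' @param loq_scale Scale on which LOD/LOQ replicate statistics are
#'   computed: target copies per reaction, or targets per cell.
#' @return An object of class `run_config`.
#' @export
run_config <- function(droplet_volume_nl = 0.70, threshold_k_sd = 7,
                       ref_copies_per_cell = 2, reaction_volume_ul = 20,
                       cv_max_pct = 35, qc_min_droplets = 10000,
                       exclusions = list(),
                       loq_scale = c("copies_per_reaction",
                                     "targets_per_cell")) {
  loq_scale <- match.arg(loq_scale)
  stopifnot(droplet_volume_nl > 0, threshold_k_sd > 0,
            ref_copies_per_cell > 0, reaction_volume_ul > 0,
            cv_max_pct > 0, qc_min_droplets > 0)
  structure(list(droplet_volume_nl = droplet_volume_nl,
                 threshold_k_sd = threshold_k_sd,
                 ref_copies_per_cell = ref_copies_per_cell,
                 reaction_volume_ul = reaction_volume_ul,
                 cv_max_pct = cv_max_pct,
                 qc_min_droplets = qc_min_droplets,
                 exclusions = exclusions, loq_scale = loq_scale),
            class = "run_config")
}

#' Run the full analysis pipeline on a plate
#'
#' Fits thresholds from the plate's blank (NTC/CLC) wells, classifies every
#' well (applying any exclusion regions), applies the accepted-droplet QC
#' rule, merges replicate wells by group, quantifies each sample group on
#' both channels (Poisson, with target-per-cell via the reference), and
#' characterizes assay performance: LOB from the blank wells'
#' target-channel concentrations, LOD/LOQ and per-level hit rates from any
#' dilution-series metadata in the manifest. Deterministic given its
#' inputs.
#'
#' @param plate A [plate_data()].
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, per-stage CSVs and a
#'   plain-text report are written there.
#' @return A list with `thresholds`, `classification` (per-well data
#'   frame), `qc_dropped`, `quantification` (per-group data frame),
#'   `validation` (a `validation_report`), and `config`.
#' @export
run_pipeline <- function(plate, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(plate, "plate_data"), inherits(config, "run_config"))
  manifest <- plate$manifest
  blank_ids <- manifest$well[manifest$role %in% c("ntc", "clc")]
  if (length(blank_ids) == 0)
    stop("no blank (ntc/clc) wells present; cannot fit thresholds")
  thresholds <- fit_thresholds(plate$wells[blank_ids],
                               k_sd = config$threshold_k_sd)

  counts <- lapply(plate$wells, classify_well, thresholds = thresholds,
                   exclusions = config$exclusions)
  qc <- qc_filter_wells(counts, min_droplets = config$qc_min_droplets)
  if (length(qc$kept) == 0)
    stop("all wells failed QC:\n",
         paste(sprintf("  %s: %s", qc$dropped$well_id, qc$dropped$reason),
               collapse = "\n"))
  kept_ids <- vapply(qc$kept, function(x) x$well_id, character(1))

  classification <- do.call(rbind, lapply(counts, function(x)
    data.frame(well = x$well_id, n_total = x$n_total, n_dn = x$n_dn,
               n_ch1_only = x$n_ch1_only, n_ch2_only = x$n_ch2_only,
               n_dp = x$n_dp, n_excluded = x$n_excluded,
               ch1_threshold = thresholds$ch1_threshold,
               ch2_threshold = thresholds$ch2_threshold,
               qc_pass = x$well_id %in% kept_ids,
               stringsAsFactors = FALSE)))
  rownames(classification) <- NULL

  # merge kept sample wells by group and quantify
  kept_samples <- qc$kept[vapply(qc$kept, function(x) {
    manifest$role[manifest$well == x$well_id] == "sample"
  }, logical(1))]
  groups <- split(kept_samples,
                  vapply(kept_samples, function(x) x$group_id,
                         character(1)))
  merged <- lapply(groups, merge_counts)
  quant_rows <- list()
  group_stats <- list()
  for (g in names(merged)) {
    mc <- merged[[g]]
    est <- quantify_counts(mc, config$droplet_volume_nl)
    tpc <- if (est$reference$concentration_per_ul > 0)
      targets_per_cell(est$target, est$reference,
                       ref_copies_per_cell = config$ref_copies_per_cell,
                       reaction_volume_ul = config$reaction_volume_ul)
      else NULL
    group_stats[[g]] <- list(counts = mc, est = est, tpc = tpc)
    for (channel in c("target", "reference")) {
      e <- est[[channel]]
      quant_rows[[length(quant_rows) + 1L]] <- data.frame(
        group = g, channel = channel, n_total = e$n_total,
        n_neg = e$n_neg, lambda = e$lambda,
        conc_per_ul = e$concentration_per_ul, ci_low = e$ci95[1],
        ci_high = e$ci95[2],
        droplet_volume_nl = config$droplet_volume_nl,
        cells_per_reaction = if (is.null(tpc)) NA_real_
          else tpc$cells_per_reaction,
        copies_per_reaction = if (is.null(tpc)) NA_real_
          else tpc$copies_per_reaction,
        targets_per_cell = if (is.null(tpc)) NA_real_
          else tpc$targets_per_cell,
        stringsAsFactors = FALSE)
    }
  }
  quantification <- if (length(quant_rows) > 0) do.call(rbind, quant_rows)
    else data.frame()

  validation <- validate_plate(plate, qc, group_stats, config)
  result <- list(thresholds = thresholds, classification = classification,
                 qc_dropped = qc$dropped, quantification = quantification,
                 validation = validation, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# assay-performance section of the pipeline
validate_plate <- function(plate, qc, group_stats, config) {
  manifest <- plate$manifest
  kept_ids <- vapply(qc$kept, function(x) x$well_id, character(1))

  # LOB: target-channel concentration of each kept blank well
  blank_kept <- qc$kept[vapply(qc$kept, function(x) {
    manifest$role[manifest$well == x$well_id] %in% c("ntc", "clc")
  }, logical(1))]
  blank_conc <- vapply(blank_kept, function(x) {
    quantify_counts(x, config$droplet_volume_nl)$target$concentration_per_ul
  }, numeric(1))
  lob <- if (length(blank_conc) >= 2) limit_of_blank(blank_conc)
         else NA_real_

  # dilution-series statistics on merged sample groups
  sm <- manifest[manifest$role == "sample" & !is.na(manifest$dilution), ]
  lod <- NA_real_; loq <- NULL; hits <- NULL; level_values <- NULL
  if (nrow(sm) > 0 && length(group_stats) > 0) {
    glev <- unique(sm[, c("group", "dilution", "cells_per_well")])
    glev <- glev[glev$group %in% names(group_stats), ]
    ratios <- sort(unique(glev$dilution), decreasing = TRUE)
    value_of <- function(g) {
      gs <- group_stats[[g]]
      if (config$loq_scale == "targets_per_cell") {
        if (is.null(gs$tpc)) NA_real_ else gs$tpc$targets_per_cell
      } else {
        if (is.null(gs$tpc))
          gs$est$target$concentration_per_ul * config$reaction_volume_ul
        else gs$tpc$copies_per_reaction
      }
    }
    level_values <- lapply(ratios, function(r) {
      gs <- glev$group[glev$dilution == r]
      vals <- vapply(gs, value_of, numeric(1))
      detected <- vapply(gs, function(g) {
        cc <- group_stats[[g]]$counts
        (cc$n_ch1_only + cc$n_dp) >= 1
      }, logical(1))
      list(ratio = r, groups = gs, values = vals,
           n_detected = sum(detected), n_replicates = length(gs))
    })
    names(level_values) <- sprintf("Dil%d", seq_along(ratios))

    lowest <- level_values[[length(level_values)]]
    if (length(lowest$values) >= 2) {
      cells_per_ul <- mean(vapply(lowest$groups, function(g) {
        gs <- group_stats[[g]]
        if (is.null(gs$tpc)) NA_real_
        else gs$tpc$cells_per_reaction / config$reaction_volume_ul
      }, numeric(1)), na.rm = TRUE)
      lob_scaled <- scale_lob(lob, cells_per_ul, config)
      lod <- limit_of_detection(lob_scaled, lowest$values)
    }
    reps <- lapply(level_values, `[[`, "values")
    nominal <- vapply(level_values, function(l) {
      if (config$loq_scale == "targets_per_cell") l$ratio
      else l$ratio * mean(glev$cells_per_well[glev$dilution == l$ratio])
    }, numeric(1))
    enough <- vapply(reps, length, integer(1)) >= 2
    if (all(enough))
      loq <- limit_of_quantification(reps, cv_max_pct = config$cv_max_pct,
                                     mean_conc = nominal)
    det <- data.frame(
      n_detected = vapply(level_values, `[[`, numeric(1), "n_detected"),
      n_replicates = vapply(level_values, `[[`, numeric(1),
                            "n_replicates"),
      concentration = vapply(level_values, `[[`, numeric(1), "ratio"))
    hits <- probit_hit_rate(det)
  }
  cv_tab <- NULL
  if (!is.null(level_values)) {
    cv_tab <- do.call(rbind, lapply(names(level_values), function(nm) {
      l <- level_values[[nm]]
      cv <- if (length(l$values) >= 2 && mean(l$values) != 0)
        cv_percent(l$values) else list(mean = mean(l$values), sd = NA_real_,
                                       cv_pct = NA_real_)
      data.frame(level = nm, dilution = l$ratio, n = length(l$values),
                 mean = cv$mean, sd = cv$sd, cv_pct = cv$cv_pct,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(lob = lob, lob_units = "copies_per_ul",
                 n_blanks = length(blank_conc), lod = lod,
                 lod_units = config$loq_scale, loq = loq,
                 cv_table = cv_tab, hit_rates = hits,
                 loq_scale = config$loq_scale),
            class = "validation_report")
}

# convert the copies/µL LOB onto the scale used for LOD/LOQ statistics;
# a zero LOB is zero on every scale
scale_lob <- function(lob, cells_per_ul, config) {
  if (is.na(lob) || lob == 0) return(ifelse(is.na(lob), 0, lob))
  if (config$loq_scale == "copies_per_reaction")
    return(lob * config$reaction_volume_ul)
  # targets_per_cell: divide by the measured cell density of the level
  if (!is.finite(cells_per_ul) || cells_per_ul <= 0) return(NA_real_)
  lob / cells_per_ul
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  LOB: %s %s (over %d blank reactions)\n",
              format(x$lob), x$lob_units, x$n_blanks))
  cat(sprintf("  LOD: %s %s\n", format(x$lod), x$lod_units))
  if (!is.null(x$loq)) {
    if (x$loq$reached)
      cat(sprintf("  LOQ: level %s, mean %.4g %s, CV %.2f%%\n",
                  x$loq$level, x$loq$mean, x$loq_scale, x$loq$cv_pct))
    else cat("  LOQ: not reached\n")
  } else cat("  LOQ: unavailable\n")
  if (!is.null(x$cv_table)) {
    cat("  per-level CV:\n")
    print(x$cv_table, row.names = FALSE)
  }
  if (!is.null(x$hit_rates)) {
    cat("  hit rates:\n")
    print(x$hit_rates$hit_rates, row.names = FALSE)
    if (identical(x$hit_rates$probit_fit, "degenerate"))
      cat("  probit fit: degenerate (all rates 0 or 1)\n")
    else
      cat(sprintf("  probit fit: intercept %.3f slope %.3f c50 %.3g c95 %.3g\n",
                  x$hit_rates$probit_fit$intercept,
                  x$hit_rates$probit_fit$slope,
                  x$hit_rates$probit_fit$c50, x$hit_rates$probit_fit$c95))
  }
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$classification,
                   file.path(out_dir, "classification.csv"),
                   row.names = FALSE)
  if (nrow(result$quantification) > 0)
    utils::write.csv(result$quantification,
                     file.path(out_dir, "quantification.csv"),
                     row.names = FALSE)
  v <- result$validation
  if (!is.null(v$cv_table))
    utils::write.csv(v$cv_table, file.path(out_dir, "validation_levels.csv"),
                     row.names = FALSE)
  if (!is.null(v$hit_rates))
    utils::write.csv(v$hit_rates$hit_rates,
                     file.path(out_dir, "hit_rates.csv"), row.names = FALSE)
  con <- file(file.path(out_dir, "report.txt"), open = "wt")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  cat("Crude-lysate ddPCR pipeline report\n")
  cat("----------------------------------\n")
  cat("config:\n")
  cfg <- result$config
  for (nm in setdiff(names(cfg), "exclusions"))
    cat(sprintf("  %s = %s\n", nm, format(cfg[[nm]])))
  cat(sprintf("  exclusion regions: %d\n", length(cfg$exclusions)))
  print(result$thresholds)
  if (nrow(result$qc_dropped) > 0) {
    cat("QC-dropped wells:\n")
    print(result$qc_dropped, row.names = FALSE)
  } else cat("QC-dropped wells: none\n")
  print(v)
  invisible(result)
}
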