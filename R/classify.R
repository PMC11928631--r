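# Droplet classification: thresholds from blanks, exclusion regions,
# quadrant counts, well QC and replicate merging.

#' Fit amplitude thresholds from blank wells
#'
#' Pools the droplets of the supplied blank (NTC/CLC) wells and sets, per
#' channel, `threshold = mean + k_sd × SD` of the pooled blank amplitudes.
#' With the default `k_sd = 7` the false-positive probability per blank
#' droplet is below 1e-11 under the Gaussian cluster model, which keeps the
#' limit of blank at zero over dozens of blank wells while staying far
#' below the positive cluster.
#'
#' @param blank_wells List of `well_data` with roles `ntc`/`clc`.
#' @param k_sd Multiplier of the pooled blank SD.
#' @param fallback_margin Absolute margin used (with a warning) when the
#'   pooled blank SD is zero.
#' @return An object of class `threshold_pair` with fields
#'   `ch1_threshold`, `ch2_threshold`, `method`, `k_sd`, `n_blank_wells`.
#' @export
fit_thresholds <- function(blank_wells, k_sd = 7, fallback_margin = 500) {
  if (length(blank_wells) == 0) stop("at least one blank well required")
  ch1 <- unlist(lapply(blank_wells, function(w) w$droplets$ch1))
  ch2 <- unlist(lapply(blank_wells, function(w) w$droplets$ch2))
  if (length(ch1) == 0) stop("blank wells contain no droplets")
  if (length(ch1) < 100)
    warning("fewer than 100 pooled blank droplets; thresholds unstable")
  thr <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
      warning("blank SD is zero; using absolute fallback margin")
      mean(x) + fallback_margin
    } else mean(x) + k_sd * s
  }
  structure(list(ch1_threshold = thr(ch1), ch2_threshold = thr(ch2),
                 method = "pooled_blank_mean_plus_k_sd", k_sd = k_sd,
                 n_blank_wells = length(blank_wells)),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf(
    "<threshold_pair> ch1 %.1f, ch2 %.1f (%s, k = %g, %d blank wells)\n",
    x$ch1_threshold, x$ch2_threshold, x$method, x$k_sd, x$n_blank_wells))
  invisible(x)
}

#' Rectangular exclusion region
#'
#' Axis-aligned rectangle in amplitude space; droplets falling inside are
#' excluded from classification (an auditable replay of manual gating of
#' artifact clusters, e.g. a shifted double-negative cluster).
#'
#' @param ch1_range,ch2_range Closed intervals `c(lo, hi)`.
#' @param reason Free-text audit note.
#' @return An object of class `exclusion_region`.
#' @export
exclusion_region <- function(ch1_range, ch2_range, reason = "") {
  if (length(ch1_range) != 2 || length(ch2_range) != 2 ||
      diff(ch1_range) < 0 || diff(ch2_range) < 0)
    stop("ranges must be non-empty closed intervals c(lo, hi)")
  structure(list(ch1_range = ch1_range, ch2_range = ch2_range,
                 reason = reason),
            class = "exclusion_region")
}

#' Quadrant counts
#'
#' Classified droplet tallies for a well or merged group. The four
#' quadrants partition the non-excluded droplets:
#' `n_dn + n_ch1_only + n_ch2_only + n_dp = n_total`; excluded droplets are
#' tallied separately and are not part of `n_total`.
#'
#' @param n_total,n_dn,n_ch1_only,n_ch2_only,n_dp,n_excluded Non-negative
#'   counts.
#' @param well_id,group_id Provenance, carried for merging and reporting.
#' @return An object of class `quadrant_counts`.
#' @export
quadrant_counts <- function(n_total, n_dn, n_ch1_only, n_ch2_only, n_dp,
                            n_excluded = 0, well_id = NA_character_,
                            group_id = NA_character_) {
  counts <- c(n_total, n_dn, n_ch1_only, n_ch2_only, n_dp, n_excluded)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (n_dn + n_ch1_only + n_ch2_only + n_dp != n_total)
    stop("quadrant counts must sum to n_total")
  structure(list(n_total = n_total, n_dn = n_dn, n_ch1_only = n_ch1_only,
                 n_ch2_only = n_ch2_only, n_dp = n_dp,
                 n_excluded = n_excluded, well_id = well_id,
                 group_id = group_id),
            class = "quadrant_counts")
}

#' @export
print.quadrant_counts <- function(x, ...) {
  cat(sprintf(
    "<quadrant_counts> %s: N %d (dn %d, ch1+ %d, ch2+ %d, dp %d; excluded %d)\n",
    ifelse(is.na(x$well_id), x$group_id, x$well_id), x$n_total, x$n_dn,
    x$n_ch1_only, x$n_ch2_only, x$n_dp, x$n_excluded))
  invisible(x)
}

#' Classify a well's droplets into quadrants
#'
#' Droplets inside any exclusion region are removed first; the remainder
#' are assigned per channel by strict inequality (`amplitude > threshold`
#' is positive, so a droplet exactly at the threshold is negative —
#' conservative for rare targets).
#'
#' @param well A `well_data`.
#' @param thresholds A [fit_thresholds()] result.
#' @param exclusions List of [exclusion_region()]s.
#' @return A [quadrant_counts()].
#' @export
classify_well <- function(well, thresholds, exclusions = list()) {
  stopifnot(inherits(well, "well_data"),
            inherits(thresholds, "threshold_pair"))
  ch1 <- well$droplets$ch1
  ch2 <- well$droplets$ch2
  excl <- rep(FALSE, length(ch1))
  for (e in exclusions) {
    stopifnot(inherits(e, "exclusion_region"))
    excl <- excl | (ch1 >= e$ch1_range[1] & ch1 <= e$ch1_range[2] &
                    ch2 >= e$ch2_range[1] & ch2 <= e$ch2_range[2])
  }
  p1 <- ch1[!excl] > thresholds$ch1_threshold
  p2 <- ch2[!excl] > thresholds$ch2_threshold
  quadrant_counts(
    n_total = sum(!excl),
    n_dn = sum(!p1 & !p2),
    n_ch1_only = sum(p1 & !p2),
    n_ch2_only = sum(!p1 & p2),
    n_dp = sum(p1 & p2),
    n_excluded = sum(excl),
    well_id = well$well_id, group_id = well$group_id)
}

#' Filter wells on accepted-droplet count
#'
#' Keeps wells whose post-exclusion droplet count is strictly greater than
#' `min_droplets` (default 10,000, the usual acceptance rule for ddPCR
#' reactions); dropped wells are reported with the reason.
#'
#' @param counts_list List of [quadrant_counts()].
#' @param min_droplets QC cutoff (strict `>`).
#' @return A list with `kept` (list of `quadrant_counts`) and `dropped`
#'   (data frame `well_id`, `n_total`, `reason`).
#' @export
qc_filter_wells <- function(counts_list, min_droplets = 10000) {
  keep <- vapply(counts_list, function(x) x$n_total > min_droplets,
                 logical(1))
  dropped <- counts_list[!keep]
  list(
    kept = counts_list[keep],
    dropped = data.frame(
      well_id = vapply(dropped, function(x) x$well_id, character(1)),
      n_total = vapply(dropped, function(x) x$n_total, numeric(1)),
      reason = if (length(dropped) > 0)
        sprintf("n_total <= %d", min_droplets) else character(0),
      stringsAsFactors = FALSE))
}

#' Merge replicate quadrant counts
#'
#' Field-wise sum over the replicate reactions of one sample (same merge
#' group), increasing the number of screened partitions before the Poisson
#' estimate — the key step for rare targets (e.g. four ~20,000-droplet
#' wells merged to ~80,000 screened droplets per sample).
#'
#' @param counts_list Non-empty list of [quadrant_counts()] sharing a
#'   `group_id` (all-`NA` group ids are also accepted).
#' @return A merged [quadrant_counts()] carrying the shared group id.
#' @export
merge_counts <- function(counts_list) {
  if (length(counts_list) == 0) stop("non-empty list required")
  groups <- vapply(counts_list, function(x) x$group_id, character(1))
  gu <- unique(groups[!is.na(groups)])
  if (length(gu) > 1)
    stop("cannot merge counts from different groups: ",
         paste(gu, collapse = ", "))
  s <- function(f) sum(vapply(counts_list, function(x) x[[f]], numeric(1)))
  quadrant_counts(n_total = s("n_total"), n_dn = s("n_dn"),
                  n_ch1_only = s("n_ch1_only"),
                  n_ch2_only = s("n_ch2_only"), n_dp = s("n_dp"),
                  n_excluded = s("n_excluded"),
                  well_id = NA_character_,
                  group_id = if (length(gu) == 1) gu else NA_character_)
}
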