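# Assay performance characterization: repeatability (CV), limit of blank,
# limit of detection, limit of quantification, and probit hit-rate
# analysis of a dilution series.

#' Coefficient of variation of replicate measurements
#'
#' Sample SD (n − 1 denominator) and `CV% = 100 × SD / mean`.
#'
#' @param replicates Numeric vector, length >= 2, with non-zero mean.
#' @return A list with `mean`, `sd`, `cv_pct`.
#' @export
cv_percent <- function(replicates) {
  if (length(replicates) < 2) stop("at least 2 replicates required")
  m <- mean(replicates)
  if (m == 0) stop("mean of replicates is zero; CV undefined")
  s <- stats::sd(replicates)
  list(mean = m, sd = s, cv_pct = 100 * s / m)
}

#' Intra-assay repeatability summary
#'
#' Per-sample [cv_percent()] plus the unweighted mean of the CVs.
#'
#' @param samples Named list, one numeric replicate vector per sample.
#' @return A list with `cv_table` (data frame `sample`, `n`, `mean`, `sd`,
#'   `cv_pct`) and `mean_cv_pct`.
#' @export
repeatability_summary <- function(samples) {
  if (length(samples) == 0) stop("no samples supplied")
  if (is.null(names(samples)))
    names(samples) <- sprintf("sample%d", seq_along(samples))
  rows <- lapply(names(samples), function(id) {
    res <- tryCatch(cv_percent(samples[[id]]),
                    error = function(e) stop("sample '", id, "': ",
                                             conditionMessage(e),
                                             call. = FALSE))
    data.frame(sample = id, n = length(samples[[id]]), mean = res$mean,
               sd = res$sd, cv_pct = res$cv_pct, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(cv_table = tab, mean_cv_pct = mean(tab$cv_pct))
}

#' Limit of blank
#'
#' `LOB = mean + 1.645 × SD` over the blank-reaction measurements (sample
#' SD); the one-sided 95th percentile of the blank distribution under a
#' normal model.
#'
#' @param blank_measurements Per-blank copy-number concentrations
#'   (length >= 2, values >= 0).
#' @return The LOB, same units as the input.
#' @export
limit_of_blank <- function(blank_measurements) {
  if (length(blank_measurements) < 2)
    stop("at least 2 blank measurements required")
  if (any(blank_measurements < 0))
    stop("blank measurements must be >= 0")
  mean(blank_measurements) + 1.645 * stats::sd(blank_measurements)
}

#' Limit of detection
#'
#' `LOD = LOB + 1.645 × SD(lowest-level replicates)`: the lowest
#' concentration distinguishable from blank with 95% confidence.
#'
#' @param lob Limit of blank.
#' @param lowest_level_replicates Replicate measurements at the lowest
#'   tested level (ignored when `sd` is given directly).
#' @param sd Optional precomputed SD of the lowest level.
#' @return The LOD, same units as `lob`.
#' @export
limit_of_detection <- function(lob, lowest_level_replicates = NULL,
                               sd = NULL) {
  if (is.null(sd)) {
    if (is.null(lowest_level_replicates) ||
        length(lowest_level_replicates) < 2)
      stop("supply sd or at least 2 replicates of the lowest level")
    sd <- stats::sd(lowest_level_replicates)
  }
  lob + 1.645 * sd
}

#' Limit of quantification
#'
#' The lowest-concentration level whose replicate CV is at or below
#' `cv_max_pct` (inclusive). Levels must be supplied in decreasing
#' concentration order.
#'
#' @param levels Named list of replicate vectors, ordered by decreasing
#'   concentration.
#' @param cv_max_pct CV ceiling in percent (default 35).
#' @param mean_conc Optional vector of level concentrations; defaults to
#'   the replicate means.
#' @return A list with `reached` (logical), `level` (name or `NA`),
#'   `mean`, `cv_pct`, and `table` (per-level mean and CV).
#' @export
limit_of_quantification <- function(levels, cv_max_pct = 35,
                                    mean_conc = NULL) {
  if (length(levels) == 0) stop("no levels supplied")
  if (is.null(names(levels)))
    names(levels) <- sprintf("level%d", seq_along(levels))
  stats_by_level <- lapply(levels, cv_percent)
  means <- if (is.null(mean_conc))
    vapply(stats_by_level, `[[`, numeric(1), "mean") else mean_conc
  if (length(means) > 1 && any(diff(means) >= 0))
    stop("levels must be sorted by decreasing concentration")
  cvs <- vapply(stats_by_level, `[[`, numeric(1), "cv_pct")
  tab <- data.frame(level = names(levels), mean_conc = means,
                    cv_pct = cvs, stringsAsFactors = FALSE,
                    row.names = NULL)
  ok <- which(cvs <= cv_max_pct)
  if (length(ok) == 0)
    return(list(reached = FALSE, level = NA_character_, mean = NA_real_,
                cv_pct = NA_real_, table = tab))
  sel <- max(ok)  # lowest concentration among qualifying levels
  list(reached = TRUE, level = names(levels)[sel], mean = means[[sel]],
       cv_pct = cvs[[sel]], table = tab)
}

#' Per-level hit rates with probit regression
#'
#' A "detection" is a merged sample group with at least one positive
#' target droplet after exclusions. Reports the per-level hit rate; when
#' the rates vary (not all 0 or 1), fits a probit regression of detection
#' on `log10(concentration)` by maximum likelihood
#' (`glm(..., binomial(link = "probit"))`) and reports the fitted
#' intercept/slope plus the concentrations with 50% and 95% predicted hit
#' rate. With all rates 0 or 1 the slope is unidentifiable and the fit is
#' flagged `"degenerate"` (rates still reported).
#'
#' @param detections Data frame with columns `n_detected`,
#'   `n_replicates`, `concentration` (one row per level).
#' @return A list with `hit_rates` (the input plus `hit_rate`) and
#'   `probit_fit`: either the string `"degenerate"` or a list
#'   `(intercept, slope, c50, c95)` with `c50`/`c95` on the concentration
#'   scale.
#' @export
probit_hit_rate <- function(detections) {
  req <- c("n_detected", "n_replicates", "concentration")
  if (!is.data.frame(detections) || !all(req %in% names(detections)))
    stop("detections must be a data frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(detections) == 0) stop("at least one level required")
  if (any(detections$n_replicates <= 0))
    stop("zero replicates at a level")
  if (any(detections$n_detected < 0 |
          detections$n_detected > detections$n_replicates))
    stop("n_detected must be in [0, n_replicates]")
  rate <- detections$n_detected / detections$n_replicates
  out <- cbind(detections, hit_rate = rate)
  degenerate <- all(rate %in% c(0, 1))
  if (degenerate)
    return(list(hit_rates = out, probit_fit = "degenerate"))
  lx <- log10(detections$concentration)
  # quasi-separated dilution series (some levels all-hit) legitimately
  # drive fitted probabilities to 0/1; the glm.fit notice is expected
  fit <- withCallingHandlers(
    stats::glm(
      cbind(detections$n_detected,
            detections$n_replicates - detections$n_detected) ~ lx,
      family = stats::binomial(link = "probit")),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  b <- unname(stats::coef(fit))
  c50 <- if (b[2] != 0) 10^(-b[1] / b[2]) else NA_real_
  c95 <- if (b[2] != 0) 10^((stats::qnorm(0.95) - b[1]) / b[2])
         else NA_real_
  list(hit_rates = out,
       probit_fit = list(intercept = b[1], slope = b[2], c50 = c50,
                         c95 = c95))
}
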