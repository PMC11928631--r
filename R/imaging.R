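# Droplet-volume estimation from monolayer micrographs.
#
# Droplets imaged in a monolayer present their equatorial cross-section, so
# a segmented 2-D area A converts to an equivalent diameter d = 2*sqrt(A/pi)
# and a sphere volume V = (pi/6) d^3 (1 nL = 1e6 µm^3). Segmentation follows
# the standard particle-analysis recipe: global threshold, hole filling,
# connected components, then area and circularity filters to reject debris
# and touching droplets.

#' Imaging configuration
#'
#' @param pixel_scale_um_per_px Physical pixel size, µm.
#' @param area_filter Optional absolute `(min, max)` area filter in µm².
#'   When `NULL`, a relative filter is applied instead: components outside
#'   `relative_area_filter × median(area)` are dropped (debris below,
#'   merged doublets above).
#' @param relative_area_filter Multipliers of the median component area
#'   used when `area_filter` is `NULL`.
#' @param circularity_min Minimum circularity `4*pi*A/P^2` (1 = perfect
#'   circle; digitized perimeters are noisy, so the default is permissive).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Grey level used when `threshold_method = "fixed"`.
#' @return An object of class `image_config`.
#' @export
image_config <- function(pixel_scale_um_per_px, area_filter = NULL,
                         relative_area_filter = c(0.25, 2),
                         circularity_min = 0.6,
                         threshold_method = c("otsu", "fixed"),
                         fixed_threshold = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (pixel_scale_um_per_px <= 0) stop("pixel scale must be > 0")
  if (circularity_min < 0 || circularity_min > 1)
    stop("circularity_min must be in [0, 1]")
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    stop("fixed_threshold required for threshold_method = 'fixed'")
  structure(list(pixel_scale_um_per_px = pixel_scale_um_per_px,
                 area_filter = area_filter,
                 relative_area_filter = relative_area_filter,
                 circularity_min = circularity_min,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold),
            class = "image_config")
}

#' Segment droplets in a monolayer micrograph
#'
#' Global threshold (Otsu by default) -> fill holes -> connected components
#' -> area and circularity filters -> per-droplet measurements in physical
#' units.
#'
#' @param image A numeric matrix in `[0, 1]`, or a path to a grayscale
#'   PNG/TIFF (read with EBImage; the first channel is used for
#'   multi-channel files).
#' @param config An [image_config()].
#' @return A data frame with one row per retained droplet: `id`,
#'   `area_um2`, `diameter_um`, `volume_nl`, `circularity`. Empty (with a
#'   warning) when nothing survives filtering.
#' @export
segment_droplets <- function(image, config) {
  stopifnot(inherits(config, "image_config"))
  if (is.character(image)) {
    im <- EBImage::readImage(image)
    dat <- EBImage::imageData(im)
    if (length(dim(dat)) == 3) dat <- dat[, , 1]
    image <- t(dat)  # EBImage stores x,y; internal convention is row,col
  }
  if (!is.matrix(image)) stop("image must be a matrix or a file path")
  empty <- data.frame(id = integer(0), area_um2 = numeric(0),
                      diameter_um = numeric(0), volume_nl = numeric(0),
                      circularity = numeric(0))
  eb <- EBImage::Image(t(image))
  thr <- switch(config$threshold_method,
                otsu = EBImage::otsu(eb),
                fixed = config$fixed_threshold)
  mask <- eb > thr
  if (sum(mask) == 0 || all(mask)) {
    warning("no foreground after thresholding (blank image?)")
    return(empty)
  }
  # droplets are sparse bright objects on a dark background; a threshold
  # splitting a featureless image produces near-zero contrast
  contrast <- mean(eb[mask]) - mean(eb[!mask])
  if (contrast < 0.2) {
    warning("insufficient foreground contrast; treating image as blank")
    return(empty)
  }
  mask <- EBImage::fillHull(mask)
  labels <- EBImage::bwlabel(mask)
  feats <- EBImage::computeFeatures.shape(labels)
  if (is.null(feats) || nrow(feats) == 0) {
    warning("no components found")
    return(empty)
  }
  area_px <- feats[, "s.area"]
  perim_px <- feats[, "s.perimeter"]
  scale <- config$pixel_scale_um_per_px
  area_um2 <- area_px * scale^2
  circularity <- pmin(1, 4 * pi * area_px / pmax(perim_px, 1)^2)
  keep <- circularity >= config$circularity_min
  if (is.null(config$area_filter)) {
    med <- stats::median(area_um2)
    lo <- config$relative_area_filter[1] * med
    hi <- config$relative_area_filter[2] * med
  } else {
    lo <- config$area_filter[1]
    hi <- config$area_filter[2]
  }
  keep <- keep & area_um2 >= lo & area_um2 <= hi
  if (!any(keep)) {
    warning("no components survived area/circularity filtering")
    return(empty)
  }
  area_um2 <- area_um2[keep]
  diameter_um <- 2 * sqrt(area_um2 / pi)
  data.frame(id = seq_along(area_um2),
             area_um2 = area_um2,
             diameter_um = diameter_um,
             volume_nl = pi / 6 * diameter_um^3 / 1e6,
             circularity = circularity[keep],
             row.names = NULL)
}

#' Summarize droplet volumes
#'
#' Mean, sample SD and a normal-approximation 95% confidence interval of
#' the mean (`mean ± 1.96·SD/sqrt(n)`).
#'
#' @param measurements A numeric vector of volumes (nL) or the data frame
#'   returned by [segment_droplets()] (its `volume_nl` column is used).
#' @return A list with `mean_nl`, `sd_nl`, `ci95` (length-2 vector), `n`.
#' @export
volume_summary <- function(measurements) {
  v <- if (is.data.frame(measurements)) measurements$volume_nl
       else measurements
  if (!is.numeric(v)) stop("measurements must be numeric volumes")
  n <- length(v)
  if (n < 2) stop("at least 2 measurements required")
  m <- mean(v)
  s <- stats::sd(v)
  half <- 1.96 * s / sqrt(n)
  list(mean_nl = m, sd_nl = s, ci95 = c(m - half, m + half), n = n)
}
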