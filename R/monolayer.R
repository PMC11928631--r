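# Synthetic monolayer micrographs for droplet-volume estimation.

#' Render a synthetic droplet-monolayer micrograph
#'
#' Renders non-overlapping bright discs with a darker rim on a dark
#' background, mimicking a bright-field image of a droplet monolayer, and
#' returns the image together with a per-disc ground-truth table. Disc
#' placement is uniform-random with rejection of overlaps; rendering a disc
#' paints every pixel whose centre lies within the disc radius.
#'
#' @param diameters_um Disc diameters in µm (possibly empty).
#' @param pixel_scale_um_per_px Physical size of one pixel, µm.
#' @param image_size_px `c(rows, cols)` of the canvas.
#' @param seed Integer seed for placement and noise.
#' @param rim_width_um Width of the darker rim ring, µm.
#' @param background,rim_intensity,disc_intensity Grey levels in `[0, 1]`;
#'   the rim stays brighter than the midpoint between background and disc so
#'   global thresholding keeps the full disc (rim included) in the
#'   foreground and the measured diameter is the true outer diameter.
#' @param noise_sd SD of additive Gaussian pixel noise (clamped to
#'   `[0, 1]`).
#' @param min_gap_px Minimum edge-to-edge gap between discs, px.
#' @param max_retries Placement attempts per disc before giving up.
#' @return A list with `image` (numeric matrix in `[0, 1]`) and `truth`, a
#'   data frame with per-disc centre (px), diameter (µm), area in px² and
#'   µm², and sphere volume in nL.
#' @export
render_monolayer_image <- function(diameters_um, pixel_scale_um_per_px,
                                   image_size_px = c(1024, 1024),
                                   seed = 1L, rim_width_um = 2,
                                   background = 0.10, rim_intensity = 0.60,
                                   disc_intensity = 0.90, noise_sd = 0.02,
                                   min_gap_px = 3, max_retries = 5000) {
  if (pixel_scale_um_per_px <= 0) stop("pixel scale must be > 0")
  nr <- image_size_px[1]; nc <- image_size_px[2]
  img <- matrix(background, nrow = nr, ncol = nc)
  truth <- data.frame(id = integer(0), cy_px = numeric(0),
                      cx_px = numeric(0), diameter_um = numeric(0),
                      area_px2 = numeric(0), area_um2 = numeric(0),
                      volume_nl = numeric(0))
  set.seed(as.integer(seed))
  if (length(diameters_um) > 0) {
    if (any(diameters_um <= 0)) stop("all diameters must be > 0")
    r_px <- diameters_um / 2 / pixel_scale_um_per_px
    if (any(2 * r_px + 2 > min(nr, nc)))
      stop("disc does not fit the canvas")
    # place largest first: improves packing success
    ord <- order(r_px, decreasing = TRUE)
    centers <- matrix(numeric(0), ncol = 2)
    rad <- numeric(0)
    ids <- integer(0)
    for (i in ord) {
      r <- r_px[i]
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        cy <- stats::runif(1, r + 1, nr - r)
        cx <- stats::runif(1, r + 1, nc - r)
        if (nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >
                rad + r + min_gap_px)) {
          centers <- rbind(centers, c(cy, cx))
          rad <- c(rad, r)
          ids <- c(ids, i)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place all discs without overlap; ",
             "use a larger canvas or fewer discs")
    }
    rim_px <- rim_width_um / pixel_scale_um_per_px
    for (j in seq_along(ids)) {
      cy <- centers[j, 1]; cx <- centers[j, 2]; r <- rad[j]
      rows <- max(1, floor(cy - r - 1)):min(nr, ceiling(cy + r + 1))
      cols <- max(1, floor(cx - r - 1)):min(nc, ceiling(cx + r + 1))
      d <- sqrt(outer((rows - cy)^2, (cols - cx)^2, `+`))
      patch <- img[rows, cols]
      patch[d <= r] <- disc_intensity
      patch[d <= r & d > r - rim_px] <- rim_intensity
      img[rows, cols] <- patch
    }
    i <- ids
    truth <- data.frame(
      id = i, cy_px = centers[, 1], cx_px = centers[, 2],
      diameter_um = diameters_um[i],
      area_px2 = pi * r_px[i]^2,
      area_um2 = pi * (diameters_um[i] / 2)^2,
      volume_nl = pi / 6 * diameters_um[i]^3 / 1e6)
    truth <- truth[order(truth$id), , drop = FALSE]
    rownames(truth) <- NULL
  }
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, truth = truth)
}

#' Write a rendered monolayer image and its ground truth
#'
#' Saves the image as a PNG (8-bit grayscale via EBImage) and, if `truth`
#' is present, a sidecar CSV with the per-disc ground truth.
#'
#' @param rendered The list returned by [render_monolayer_image()].
#' @param path PNG output path; the sidecar CSV takes the same stem with
#'   suffix `_truth.csv`.
#' @return `path`, invisibly.
#' @export
write_monolayer_png <- function(rendered, path) {
  EBImage::writeImage(EBImage::Image(t(rendered$image)), path)
  if (nrow(rendered$truth) > 0)
    utils::write.csv(rendered$truth,
                     sub("\\.[A-Za-z]+$", "_truth.csv", path),
                     row.names = FALSE)
  invisible(path)
}
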