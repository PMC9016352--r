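# Quantification formulas for sedimentation blots, FRAP recovery traces and
# droplet morphology.

#' Supernatant fraction of a sedimentation assay
#'
#' `S / (S + C)` for band intensities of the supernatant and condensate
#' (pellet) fractions; the same form serves RIPA fractionations,
#' `S / (S + I)` with the insoluble fraction as second argument.
#'
#' @param supernatant_intensity,pellet_intensity non-negative band
#'   intensities, not both zero.
#' @return ratio in `[0, 1]`.
#' @examples
#' sedimentation_ratio(1, 3)  # 0.25
#' @export
sedimentation_ratio <- function(supernatant_intensity, pellet_intensity) {
  if (any(supernatant_intensity < 0) || any(pellet_intensity < 0))
    stop("band intensities must be non-negative")
  tot <- supernatant_intensity + pellet_intensity
  if (any(tot == 0)) stop("both intensities are zero")
  supernatant_intensity / tot
}

#' FRAP trace container
#'
#' @param times frame times, s.
#' @param roi_bleached mean gray values of the bleached area (ROI1).
#' @param roi_whole mean gray values of the whole droplet (ROI2).
#' @param roi_background mean background gray values (ROI3).
#' @param bleach_index index of the first post-bleach frame (>= 2).
#' @return object of class `frap_trace`.
#' @export
frap_trace <- function(times, roi_bleached, roi_whole, roi_background,
                       bleach_index) {
  n <- length(times)
  if (length(roi_bleached) != n || length(roi_whole) != n ||
      length(roi_background) != n)
    stop("all ROI series must have the same length as times")
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 2L) stop("bleach_index must be >= 2 (need a prebleach frame)")
  structure(list(times = times, roi_bleached = roi_bleached,
                 roi_whole = roi_whole, roi_background = roi_background,
                 bleach_index = bleach_index), class = "frap_trace")
}

#' Normalized FRAP recovery
#'
#' Background-corrected, acquisition-bleaching-corrected intensity
#' \eqn{I(t) = (ROI1(t) - ROI3(t)) / (ROI2(t) - ROI3(t))}, divided by the
#' mean of `I` over the `prebleach_window` frames immediately before the
#' bleach, so the prebleach level normalizes to 1.
#'
#' @param trace a [frap_trace()].
#' @param prebleach_window number of prebleach frames averaged (default 1).
#' @return data.frame with `time` and `intensity`.
#' @export
frap_normalize <- function(trace, prebleach_window = 1L) {
  stopifnot(inherits(trace, "frap_trace"))
  den <- trace$roi_whole - trace$roi_background
  if (any(den <= 0)) stop("ROI2 - ROI3 must be positive for all frames")
  I <- (trace$roi_bleached - trace$roi_background) / den
  pre <- seq(max(1L, trace$bleach_index - prebleach_window),
             trace$bleach_index - 1L)
  I0 <- mean(I[pre])
  if (I0 == 0) stop("prebleach intensity is zero")
  data.frame(time = trace$times, intensity = I / I0)
}

#' Area under a normalized recovery curve
#'
#' Trapezoidal integral of the normalized intensity over `[t_start, t_end]`.
#'
#' @param normalized data.frame from [frap_normalize()] (columns `time`,
#'   `intensity`).
#' @param t_start,t_end integration window; must lie within the sampled
#'   times.
#' @return area (dimensionless x s).
#' @export
frap_auc <- function(normalized, t_start = min(normalized$time),
                     t_end = max(normalized$time)) {
  if (t_start >= t_end) stop("t_start must be smaller than t_end")
  if (t_start < min(normalized$time) - 1e-9 ||
      t_end > max(normalized$time) + 1e-9)
    stop("integration window outside the sampled times")
  tt <- sort(unique(c(t_start, t_end,
                      normalized$time[normalized$time > t_start &
                                      normalized$time < t_end])))
  yy <- stats::approx(normalized$time, normalized$intensity, xout = tt)$y
  pracma::trapz(tt, yy)
}

#' Segment droplets in a gray-scale image
#'
#' Bandpass (difference of Gaussians, small sigma 1 px, large sigma
#' `bandpass_large_px`), Otsu threshold, connected components, and
#' per-droplet shape metrics.  Roundness is the printed formula
#' `4 * area / (pi * major_axis^2)` (the inverse aspect ratio of the fitted
#' ellipse); circularity is the perimeter-based `4 * pi * area /
#' perimeter^2`.  Particles with circularity below `min_circularity` or
#' area below `min_area_px` pixels are excluded.
#'
#' @param image 2-D numeric matrix (gray values) or an `EBImage::Image`.
#' @param bandpass_large_px large Gaussian sigma of the bandpass, px.
#' @param min_area_px minimum retained area, px (default 3).
#' @param min_circularity minimum retained circularity (default 0.3).
#' @return list with `table` (data.frame: `label`, `area`, `perimeter`,
#'   `major_axis`, `roundness`, `circularity`, `cx`, `cy`) and `labels`
#'   (the filtered label image).  An image without detectable droplets gives
#'   an empty table.
#' @export
segment_droplets <- function(image, bandpass_large_px = 20, min_area_px = 3,
                             min_circularity = 0.3) {
  img <- EBImage::Image(as.matrix(image))
  if (length(dim(img)) != 2) stop("expected a single 2-D grayscale image")
  rng <- range(as.numeric(img))
  if (diff(rng) == 0)
    return(list(table = empty_droplet_table(), labels = img * 0))
  img <- (img - rng[1]) / (rng[2] - rng[1])
  lo <- EBImage::gblur(img, sigma = 1)
  hi <- EBImage::gblur(img, sigma = bandpass_large_px)
  bp <- lo - hi
  bp <- bp - min(bp)
  if (max(bp) > 0) bp <- bp / max(bp)
  thr <- EBImage::otsu(bp, range = c(0, 1))
  mask <- bp > thr
  labels <- EBImage::bwlabel(mask)
  nobj <- max(labels)
  if (nobj == 0)
    return(list(table = empty_droplet_table(), labels = labels))
  shp <- EBImage::computeFeatures.shape(labels)
  mom <- EBImage::computeFeatures.moment(labels)
  area <- shp[, "s.area"]
  per <- shp[, "s.perimeter"]
  roundness <- 4 * area / (pi * mom[, "m.majoraxis"]^2)
  circularity <- 4 * pi * area / pmax(per, .Machine$double.eps)^2
  tab <- data.frame(label = seq_len(nobj), area = area, perimeter = per,
                    major_axis = mom[, "m.majoraxis"],
                    roundness = roundness,
                    circularity = pmin(circularity, 1.2),
                    cx = mom[, "m.cx"], cy = mom[, "m.cy"])
  keep <- tab$area >= min_area_px & tab$circularity >= min_circularity
  dropped <- tab$label[!keep]
  if (length(dropped)) {
    lab <- as.matrix(labels)
    lab[lab %in% dropped] <- 0L
    labels <- EBImage::Image(lab)
  }
  tab <- tab[keep, , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, labels = labels)
}

empty_droplet_table <- function() {
  data.frame(label = integer(0), area = numeric(0), perimeter = numeric(0),
             major_axis = numeric(0), roundness = numeric(0),
             circularity = numeric(0), cx = numeric(0), cy = numeric(0))
}
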