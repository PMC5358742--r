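#' Segmentation parameters
#'
#' Per-pixel rules that separate plant from soil: keep a pixel iff its
#' saturation is at least \code{saturation_min} and its hue falls inside one
#' of the \code{keep_hue_ranges}. The defaults (saturation 0.15, hue 10-160
#' degrees, i.e. brown through green) suit canopy imagery over grey-brown
#' soil; both are tunable and should be re-tuned for other cameras or soils.
#'
#' @param saturation_min minimum saturation in \code{[0, 1]}.
#' @param keep_hue_ranges list of half-open \code{c(lo, hi)} degree intervals
#'   within \code{[0, 360)}; must not overlap.
#' @return A list of class \code{segmentation_params}.
#' @export
segmentation_params <- function(saturation_min = 0.15,
                                keep_hue_ranges = list(c(10, 160))) {
  if (saturation_min < 0 || saturation_min > 1) {
    stop("saturation_min must lie in [0, 1]")
  }
  for (rg in keep_hue_ranges) {
    if (length(rg) != 2 || rg[1] >= rg[2] || rg[1] < 0 || rg[2] > 360) {
      stop("each hue range must be c(lo, hi) with 0 <= lo < hi <= 360")
    }
  }
  if (length(keep_hue_ranges) > 1) {
    m <- do.call(rbind, keep_hue_ranges)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] < m[-nrow(m), 2])) stop("hue ranges must not overlap")
  }
  structure(list(saturation_min = saturation_min,
                 keep_hue_ranges = keep_hue_ranges),
            class = "segmentation_params")
}

#' Colour-chart calibration of an RGB image
#'
#' Fits an independent per-channel affine map (gain and offset) from observed
#' to reference colour-chart patch means by least squares, applies it to the
#' image and clips to \code{[0, 255]}. With no chart the image passes through
#' unchanged with a warning; a degenerate chart (zero variance in a channel)
#' falls back to the identity for that channel with a warning.
#'
#' @param image an RGB array (see [as_rgb_image()]).
#' @param chart_observed,chart_reference matrices of patch mean RGBs
#'   (rows = patches, 3 columns), typically 24 rows; or \code{NULL}.
#' @return The calibrated image, with the fitted transform attached as
#'   attribute \code{"calibration"} (list with \code{gain} and \code{offset},
#'   3 each).
#' @export
calibrate_image <- function(image, chart_observed = NULL, chart_reference = NULL) {
  image <- as_rgb_image(image)
  if (is.null(chart_observed) || is.null(chart_reference)) {
    warning("no colour chart supplied; image passed through uncalibrated")
    attr(image, "calibration") <- list(gain = rep(1, 3), offset = rep(0, 3))
    return(image)
  }
  chart_observed <- as.matrix(chart_observed)
  chart_reference <- as.matrix(chart_reference)
  stopifnot(ncol(chart_observed) == 3, ncol(chart_reference) == 3,
            nrow(chart_observed) == nrow(chart_reference))
  gain <- rep(1, 3); offset <- rep(0, 3)
  for (ch in 1:3) {
    x <- chart_observed[, ch]; y <- chart_reference[, ch]
    if (stats::sd(x) < .Machine$double.eps^0.5) {
      warning("degenerate chart channel ", ch, "; identity transform used")
      next
    }
    fit <- stats::lm.fit(cbind(1, x), y)
    if (fit$coefficients[2] <= 0) {
      warning("non-positive fitted gain in channel ", ch, "; identity used")
      next
    }
    offset[ch] <- fit$coefficients[1]
    gain[ch] <- fit$coefficients[2]
  }
  out <- image
  for (ch in 1:3) {
    out[, , ch] <- pmax(0, pmin(255, gain[ch] * image[, , ch] + offset[ch]))
  }
  out <- as_rgb_image(out)
  attr(out, "calibration") <- list(gain = gain, offset = offset)
  out
}

#' Threshold an HSV image into a foreground mask
#'
#' Pure per-pixel predicate: a pixel is foreground iff its saturation is at
#' least \code{saturation_min} and its hue lies in one of the kept half-open
#' hue intervals. Low-saturation (grey) soil and hues that are neither green
#' nor brown are removed here; debris of plant colour survives and is dealt
#' with by [clean_mask()].
#'
#' @param hsv an \code{hsv_image} from [rgb_to_hsv()].
#' @param params a [segmentation_params()].
#' @return Logical \code{H x W} mask.
#' @export
threshold_segment <- function(hsv, params = segmentation_params()) {
  stopifnot(inherits(hsv, "hsv_image"))
  keep <- hsv$s >= params$saturation_min &
    matrix(hue_in_ranges(as.vector(hsv$h), params$keep_hue_ranges),
           nrow(hsv$h), ncol(hsv$h))
  keep
}

# label connected components; EBImage::bwlabel is 4-connected, so for
# 8-connectivity merge labels that touch diagonally with a union-find pass
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8 && max(lab) > 1) {
    H <- nrow(lab); W <- ncol(lab)
    a <- lab[-H, -W]; b <- lab[-1, -1]   # down-right diagonal pairs
    c_ <- lab[-H, -1]; d <- lab[-1, -W]  # down-left diagonal pairs
    pairs <- rbind(
      cbind(as.vector(a), as.vector(b)),
      cbind(as.vector(c_), as.vector(d))
    )
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                   drop = FALSE]
    if (nrow(pairs) > 0) {
      parent <- seq_len(max(lab))
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_along(parent), find, integer(1))
      relab <- match(root, sort(unique(root)))
      lab[lab > 0] <- relab[lab[lab > 0]]
    }
  }
  lab
}

#' Keep only the largest connected component of a mask
#'
#' Removes debris and noise by retaining the single largest connected
#' foreground component (the plant canopy). Components are 8-connected by
#' default (diagonal neighbours count). On an area tie the component whose
#' first pixel comes earliest in row-major scan order (rows top to bottom,
#' left to right within a row) is kept.
#'
#' @param mask logical \code{H x W} mask with at least one \code{TRUE} pixel.
#' @param connectivity 8 (default) or 4.
#' @return Logical mask containing only the largest component.
#' @export
clean_mask <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) stop("no foreground found: mask is empty")
  lab <- label_components(mask, connectivity)
  n_comp <- max(lab)
  if (n_comp == 1) return(lab == 1)
  area <- tabulate(lab[lab > 0], nbins = n_comp)
  best <- which(area == max(area))
  if (length(best) > 1) {
    # row-major index of each component's first pixel decides the tie
    H <- nrow(lab); W <- ncol(lab)
    rm_idx <- (row(lab) - 1) * W + col(lab)
    first <- vapply(best, function(k) min(rm_idx[lab == k]), numeric(1))
    best <- best[which.min(first)]
  }
  lab == best
}

#' Full image preprocessing: calibrate, segment, clean, apply mask
#'
#' Composition of the preprocessing stages: optional chart calibration,
#' RGB to HSV conversion, saturation/hue thresholding, largest-component
#' cleanup, and application of the final mask to the original RGB image
#' (background pixels zeroed).
#'
#' @param image RGB array.
#' @param params [segmentation_params()].
#' @param chart_observed,chart_reference optional calibration chart patch
#'   means; both \code{NULL} skips calibration silently.
#' @param connectivity component connectivity for [clean_mask()].
#' @return List with \code{masked} (RGB array, background zeroed) and
#'   \code{mask} (logical matrix).
#' @export
preprocess <- function(image, params = segmentation_params(),
                       chart_observed = NULL, chart_reference = NULL,
                       connectivity = 8) {
  image <- as_rgb_image(image)
  if (!is.null(chart_observed) && !is.null(chart_reference)) {
    image <- calibrate_image(image, chart_observed, chart_reference)
  }
  hsv <- rgb_to_hsv(image)
  raw <- threshold_segment(hsv, params)
  if (!any(raw)) stop("no foreground found: segmentation removed every pixel")
  mask <- clean_mask(raw, connectivity)
  masked <- image
  for (ch in 1:3) masked[, , ch] <- image[, , ch] * mask
  list(masked = as_rgb_image(masked), mask = mask)
}

#' Read an RGB image file
#'
#' Reads a PNG file into the 0-255 array format used throughout the package.
#' @param path file path to a PNG image.
#' @return An RGB array (see [as_rgb_image()]).
#' @export
read_rgb_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  as_rgb_image(round(px[, , 1:3, drop = FALSE] * 255))
}
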