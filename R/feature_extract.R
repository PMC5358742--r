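#' Hue partition for canopy discoloration
#'
#' The three hue bands (degrees, half-open \code{[lo, hi)}) used to classify
#' canopy pixels as necrotic brown, chlorotic yellow or healthy green.
#' Defaults: brown 10-40, yellow 40-70, green 70-160. The bands must be
#' disjoint and should lie inside the segmentation keep range so every canopy
#' pixel falls in (at most) one band.
#'
#' @param brown,yellow,green \code{c(lo, hi)} degree intervals.
#' @return A list of class \code{hue_partition}.
#' @export
hue_partition <- function(brown = c(10, 40), yellow = c(40, 70),
                          green = c(70, 160)) {
  bands <- list(brown = brown, yellow = yellow, green = green)
  for (b in bands) {
    if (length(b) != 2 || b[1] >= b[2] || b[1] < 0 || b[2] > 360) {
      stop("each band must be c(lo, hi) with 0 <= lo < hi <= 360")
    }
  }
  m <- do.call(rbind, bands)
  m <- m[order(m[, 1]), ]
  if (any(m[-1, 1] < m[-nrow(m), 2])) stop("hue bands must be disjoint")
  structure(bands, class = "hue_partition")
}

#' Percent-yellow and percent-brown canopy features
#'
#' Reduces a masked canopy to the two-feature signature of iron deficiency
#' chlorosis: the percentage of canopy pixels whose hue falls in the yellow
#' (chlorosis) band and in the brown (necrosis) band. Pixels inside the mask
#' whose hue falls in no band count toward the denominator only, so
#' yellow + brown never exceeds 100.
#'
#' @param image RGB array.
#' @param mask logical canopy mask (non-empty), same height/width.
#' @param partition a [hue_partition()].
#' @return Named numeric vector \code{c(yellow_pct, brown_pct)}.
#' @examples
#' out <- generate_canopy(canopy_spec(yellow_frac = 0.25, seed = 3))
#' compute_features(out$image, out$truth$canopy_mask)
#' @export
compute_features <- function(image, mask, partition = hue_partition()) {
  image <- as_rgb_image(image)
  stopifnot(is.matrix(mask), all(dim(mask) == dim(image)[1:2]))
  if (!any(mask)) stop("empty mask: no canopy pixels to extract features from")
  hsv <- rgb_to_hsv(image)
  h <- hsv$h[mask]
  n <- length(h)
  c(
    yellow_pct = 100 * sum(h >= partition$yellow[1] & h < partition$yellow[2]) / n,
    brown_pct = 100 * sum(h >= partition$brown[1] & h < partition$brown[2]) / n
  )
}
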