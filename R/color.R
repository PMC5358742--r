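#' Convert an RGB canopy image to HSV
#'
#' Applies the standard hexcone transform to an 8-bit RGB raster. Hue is
#' returned in degrees on \code{[0, 360)} with 0 = red, saturation and value
#' on \code{[0, 1]}. Achromatic pixels (R = G = B) get hue 0 and saturation 0.
#'
#' @param image numeric array \code{H x W x 3} with channel values in
#'   \code{[0, 255]} (see [as_rgb_image()]).
#' @return An object of class \code{hsv_image}: a list with matrices
#'   \code{h} (degrees), \code{s} and \code{v}, each \code{H x W}.
#' @examples
#' img <- array(0, c(2, 2, 3)); img[1, 1, ] <- c(255, 0, 0)
#' rgb_to_hsv(as_rgb_image(img))$h[1, 1]  # 0 degrees
#' @export
rgb_to_hsv <- function(image) {
  image <- as_rgb_image(image)
  d <- dim(image)
  flat <- rbind(
    as.vector(image[, , 1]),
    as.vector(image[, , 2]),
    as.vector(image[, , 3])
  )
  hsv <- grDevices::rgb2hsv(flat, maxColorValue = 255)
  out <- list(
    h = matrix(hsv[1, ] * 360, d[1], d[2]),
    s = matrix(hsv[2, ], d[1], d[2]),
    v = matrix(hsv[3, ], d[1], d[2])
  )
  class(out) <- "hsv_image"
  out
}

#' Validate and coerce an RGB raster
#'
#' @param image numeric array \code{H x W x 3}, values in \code{[0, 255]}.
#' @param min_dim minimum allowed height/width.
#' @return The validated array with class attribute \code{rgb_image}.
#' @export
as_rgb_image <- function(image, min_dim = 16) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("`image` must be an H x W x 3 array")
  }
  if (any(dim(image)[1:2] < min_dim)) {
    stop("image must be at least ", min_dim, " x ", min_dim, " pixels")
  }
  if (anyNA(image) || min(image) < 0 || max(image) > 255) {
    stop("channel values must lie in [0, 255]")
  }
  if (!inherits(image, "rgb_image")) class(image) <- c("rgb_image", class(image))
  image
}

# Vectorised HSV -> RGB (0..255, unrounded). h in degrees, s and v in [0,1].
# Inverse of the hexcone transform; used by the canopy generator.
hsv_to_rgb255 <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
    ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
    ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
    ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b) * 255
}

# Hue membership in a list of half-open [lo, hi) degree intervals.
hue_in_ranges <- function(h, ranges) {
  keep <- rep(FALSE, length(h))
  for (rg in ranges) keep <- keep | (h >= rg[1] & h < rg[2])
  keep
}
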