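#' Specification of a synthetic canopy image
#'
#' Parameters for the synthetic generator that emulates a top-down RGB image
#' of a single soybean plot: a connected canopy of leaflet discs with known
#' green/yellow/brown pixel fractions over a low-saturation soil texture,
#' optionally with small plant-debris blobs on the soil.
#'
#' The generator's hue bands match the extraction defaults
#' (brown 10-40, yellow 40-70, green 70-160 degrees; see [hue_partition()]),
#' with a margin inside each band so 8-bit quantisation cannot move a pixel
#' across a band edge. Soil pixels keep saturation below 0.12 so the default
#' segmentation threshold of 0.15 separates them by construction.
#'
#' @param width,height frame size in pixels (>= 16).
#' @param canopy_radius radius in pixels of the central canopy disc; leaflet
#'   discs extend to about 1.35 x this radius, which must fit in the frame.
#' @param n_leaflets number of leaflet discs drawn around the centre.
#' @param yellow_frac,brown_frac target fractions of canopy pixels carrying
#'   yellow (chlorotic) and brown (necrotic) hue; both in \code{[0, 1]} and
#'   summing to at most 1.
#' @param soil_palette matrix of RGB rows (0-255) of low-chroma soil tones.
#' @param n_debris number of debris blobs (plant-coloured, on soil).
#' @param debris_size debris blob radius in pixels.
#' @param illumination_jitter length-2 multiplicative range applied to pixel
#'   value (brightness); hue and saturation are unaffected.
#' @param seed integer; identical spec + seed gives a bit-identical image.
#' @return A list of class \code{canopy_spec}.
#' @export
canopy_spec <- function(width = 96, height = 96,
                        canopy_radius = round(min(width, height) * 0.3),
                        n_leaflets = 7,
                        yellow_frac = 0, brown_frac = 0,
                        soil_palette = default_soil_palette(),
                        n_debris = 0, debris_size = 3,
                        illumination_jitter = c(0.9, 1.1),
                        seed = 1L) {
  spec <- list(
    width = as.integer(width), height = as.integer(height),
    canopy_radius = canopy_radius, n_leaflets = as.integer(n_leaflets),
    yellow_frac = yellow_frac, brown_frac = brown_frac,
    soil_palette = soil_palette, n_debris = as.integer(n_debris),
    debris_size = debris_size, illumination_jitter = illumination_jitter,
    seed = as.integer(seed)
  )
  if (spec$width < 16 || spec$height < 16) stop("frame must be at least 16 x 16")
  for (f in c("yellow_frac", "brown_frac")) {
    if (spec[[f]] < 0 || spec[[f]] > 1) {
      stop(f, " must lie in [0, 1], got ", spec[[f]])
    }
  }
  if (spec$yellow_frac + spec$brown_frac > 1) {
    stop("yellow_frac + brown_frac must not exceed 1")
  }
  if (1.35 * spec$canopy_radius >= min(spec$width, spec$height) / 2) {
    stop("canopy larger than frame: reduce canopy_radius")
  }
  if (spec$n_debris > 0 && spec$debris_size >= spec$canopy_radius) {
    stop("debris_size must be smaller than canopy_radius")
  }
  class(spec) <- "canopy_spec"
  spec
}

#' Default low-chroma soil palette
#'
#' Grey-tan tones whose channel spread keeps saturation under 0.12 even after
#' the generator's per-pixel brightness offset, so the default segmentation
#' threshold removes soil.
#' @return A numeric matrix with RGB rows in 0-255.
#' @export
default_soil_palette <- function() {
  rbind(
    c(125, 120, 113),
    c(140, 135, 127),
    c(112, 108, 102),
    c(150, 146, 139),
    c(132, 127, 121)
  )
}

# Interior hue bands (margin ~4 degrees inside the extraction bands) so that
# 8-bit RGB quantisation never moves a generated pixel across a band edge.
.gen_bands <- list(
  green  = c(76, 154),
  yellow = c(45, 65),
  brown  = c(15, 35)
)

#' Generate a synthetic canopy image with exact ground truth
#'
#' Draws a connected canopy (central disc plus overlapping leaflet discs),
#' assigns exactly \code{round(frac * n_canopy)} canopy pixels to the yellow
#' and brown hue bands (the rest green), renders soil and optional debris,
#' and returns the 8-bit RGB image together with the exact pixel-count
#' ground truth.
#'
#' @param spec a [canopy_spec()].
#' @return A list with elements \code{image} (\code{H x W x 3}, 0-255
#'   integers) and \code{truth}, itself a list: \code{canopy_mask},
#'   \code{debris_mask} (logical \code{H x W}), \code{true_yellow_pct},
#'   \code{true_brown_pct} (percent of canopy pixels, exact counts).
#' @examples
#' out <- generate_canopy(canopy_spec(yellow_frac = 0.3, brown_frac = 0.1, seed = 7))
#' out$truth$true_yellow_pct
#' @export
generate_canopy <- function(spec) {
  if (!inherits(spec, "canopy_spec")) spec <- do.call(canopy_spec, spec)
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  col_idx <- matrix(rep(seq_len(W), each = H), H, W)
  row_idx <- matrix(rep(seq_len(H), times = W), H, W)

  disc <- function(x0, y0, r) {
    (col_idx - x0)^2 + (row_idx - y0)^2 <= r^2
  }

  r <- spec$canopy_radius
  canopy <- disc(cx, cy, r)
  if (spec$n_leaflets > 0) {
    ang <- 2 * pi * seq_len(spec$n_leaflets) / spec$n_leaflets +
      stats::runif(spec$n_leaflets, -0.25, 0.25)
    for (k in seq_len(spec$n_leaflets)) {
      canopy <- canopy | disc(cx + 0.8 * r * cos(ang[k]),
                              cy + 0.8 * r * sin(ang[k]), 0.55 * r)
    }
  }

  # soil background: palette tone + common brightness offset per pixel,
  # preserving the channel spread (hence the low saturation)
  npx <- H * W
  tone <- spec$soil_palette[sample.int(nrow(spec$soil_palette), npx, replace = TRUE), ,
                            drop = FALSE]
  offset <- stats::runif(npx, -15, 25)
  img <- tone + offset
  img[] <- pmax(0, pmin(255, img))

  # canopy pixels: exact band counts, hue drawn inside the band interiors
  can_idx <- which(canopy)
  n_c <- length(can_idx)
  n_y <- round(spec$yellow_frac * n_c)
  n_b <- round(spec$brown_frac * n_c)
  perm <- sample(can_idx)
  idx_y <- perm[seq_len(n_y)]
  idx_b <- perm[n_y + seq_len(n_b)]
  idx_g <- perm[-seq_len(n_y + n_b)]
  if (n_y + n_b == 0) idx_g <- perm

  jit <- stats::runif(1, spec$illumination_jitter[1], spec$illumination_jitter[2])
  paint <- function(idx, band) {
    if (length(idx) == 0) return(invisible(NULL))
    h <- stats::runif(length(idx), .gen_bands[[band]][1], .gen_bands[[band]][2])
    s <- stats::runif(length(idx), 0.55, 0.95)
    v <- pmin(1, stats::runif(length(idx), 0.55, 0.9) * jit)
    img[idx, ] <<- round(hsv_to_rgb255(h, s, v))
  }
  paint(idx_g, "green"); paint(idx_y, "yellow"); paint(idx_b, "brown")

  # debris: small plant-hued blobs disjoint from the canopy
  debris <- matrix(FALSE, H, W)
  if (spec$n_debris > 0) {
    placed <- 0L; tries <- 0L
    while (placed < spec$n_debris && tries < 200L) {
      tries <- tries + 1L
      x0 <- stats::runif(1, spec$debris_size + 1, W - spec$debris_size)
      y0 <- stats::runif(1, spec$debris_size + 1, H - spec$debris_size)
      blob <- disc(x0, y0, spec$debris_size)
      # disjoint with one-pixel clearance so it cannot 8-connect to the canopy
      halo <- disc(x0, y0, spec$debris_size + 1.6)
      if (any(halo & (canopy | debris))) next
      didx <- which(blob)
      h <- stats::runif(length(didx), .gen_bands$green[1], .gen_bands$green[2])
      s <- stats::runif(length(didx), 0.55, 0.9)
      v <- stats::runif(length(didx), 0.45, 0.8)
      img[didx, ] <- round(hsv_to_rgb255(h, s, v))
      debris <- debris | blob
      placed <- placed + 1L
    }
  }

  image <- array(0, c(H, W, 3))
  image[, , 1] <- img[, 1]; image[, , 2] <- img[, 2]; image[, , 3] <- img[, 3]
  # debris repaint may overlap soil only; canopy band counts stay exact
  truth <- list(
    canopy_mask = canopy,
    debris_mask = debris,
    true_yellow_pct = 100 * n_y / n_c,
    true_brown_pct = 100 * n_b / n_c
  )
  list(image = as_rgb_image(image), truth = truth)
}

#' Ordinal score from ground-truth discoloration fractions
#'
#' The fixture labeling rule used by the synthetic data: a generative map from
#' (yellow\%, brown\%) to an IDC-like 1-5 score. The cutoffs are fixture
#' parameters of this package's simulations, not estimates from field data.
#'
#' @param yellow_pct,brown_pct percent of canopy pixels (vectors recycle).
#' @return Integer scores in 1..5.
#' @export
label_from_features <- function(yellow_pct, brown_pct) {
  n <- max(length(yellow_pct), length(brown_pct))
  y <- rep_len(yellow_pct, n); b <- rep_len(brown_pct, n)
  score <- integer(n)
  score[b >= 15] <- 5L
  score[score == 0L & (y >= 50 | (b >= 5 & b < 15))] <- 4L
  score[score == 0L & y >= 25 & b < 5] <- 3L
  score[score == 0L & y >= 5 & b < 2] <- 2L
  score[score == 0L & y < 5 & b < 1] <- 1L
  # remaining combinations (e.g. moderate yellow with 2 <= B < 5): treat as 3
  score[score == 0L] <- 3L
  score
}

#' Generate a labeled synthetic canopy image set
#'
#' Samples per-class (yellow, brown) fraction clusters that are well separated
#' in feature space (adjacent class centres about five within-class standard
#' deviations apart along the discriminating axis), renders each image,
#' optionally runs the segmentation + feature-extraction pipeline, and labels
#' each image from its ground-truth fractions via [label_from_features()].
#'
#' @param n number of images.
#' @param seed integer seed controlling the whole set.
#' @param img_size frame side in pixels.
#' @param n_debris debris blobs per image.
#' @param extract if \code{TRUE} (default) run [preprocess()] and
#'   [compute_features()] on every image and include the extracted features.
#' @param dir optional directory; when given, images are written as PNG files
#'   and a \code{manifest.csv} with the ground truth and labels.
#' @return A data frame with columns \code{image_id}, \code{true_yellow_pct},
#'   \code{true_brown_pct}, \code{label}, and (when \code{extract})
#'   \code{yellow_pct}, \code{brown_pct}.
#' @export
generate_canopy_set <- function(n, seed = 1L, img_size = 80, n_debris = 0,
                                extract = TRUE, dir = NULL) {
  set.seed(seed)
  # class-conditional cluster centres (Y%, B%) and s.d.; adjacent classes are
  # ~5 sigma apart along the axis that separates them under the label rule
  centres <- rbind(
    c(2, 0.2), c(15, 0.6), c(36, 2.5), c(62, 8), c(35, 30)
  )
  sds <- rbind(
    c(0.8, 0.1), c(2.0, 0.2), c(2.2, 0.4), c(2.4, 1.2), c(3.0, 2.5)
  )
  cls <- sample(rep_len(1:5, n))
  y_frac <- pmin(0.95, pmax(0, stats::rnorm(n, centres[cls, 1], sds[cls, 1]) / 100))
  b_frac <- pmin(0.95, pmax(0, stats::rnorm(n, centres[cls, 2], sds[cls, 2]) / 100))
  over <- y_frac + b_frac > 1
  y_frac[over] <- 1 - b_frac[over]
  seeds <- sample.int(.Machine$integer.max, n)

  rows <- vector("list", n)
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  params <- segmentation_params()
  part <- hue_partition()
  for (i in seq_len(n)) {
    sp <- canopy_spec(width = img_size, height = img_size,
                      yellow_frac = y_frac[i], brown_frac = b_frac[i],
                      n_debris = n_debris, seed = seeds[i])
    out <- generate_canopy(sp)
    row <- data.frame(
      image_id = sprintf("img%04d", i),
      true_yellow_pct = out$truth$true_yellow_pct,
      true_brown_pct = out$truth$true_brown_pct
    )
    if (extract) {
      pp <- preprocess(out$image, params)
      fv <- compute_features(out$image, pp$mask, part)
      row$yellow_pct <- fv[["yellow_pct"]]
      row$brown_pct <- fv[["brown_pct"]]
    }
    if (!is.null(dir)) {
      png::writePNG(out$image / 255, file.path(dir, paste0(row$image_id, ".png")))
    }
    rows[[i]] <- row
  }
  res <- do.call(rbind, rows)
  res$label <- label_from_features(res$true_yellow_pct, res$true_brown_pct)
  if (!is.null(dir)) {
    utils::write.csv(res, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  res
}
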