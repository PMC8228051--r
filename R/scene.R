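#' Configuration for a synthetic mine scene
#'
#' Parametrizes the generator of labeled synthetic open-pit mine scenes:
#' contiguous patches of green vegetation against yellowish-brown barren
#' ground, with a controllable vegetation fraction and per-channel colour
#' noise. The defaults encode the visual description of the imagery the
#' pipeline targets: vegetation hues in the green band (75--165 degrees),
#' barren ground in the yellow-brown band (25--55 degrees).
#'
#' @param width,height Scene dimensions in pixels (positive integers).
#' @param target_prevalence Fraction of vegetation pixels in (0, 1).
#' @param patch_scale Correlation length of the patch process, in pixels;
#'   radius of the box smoothing applied to the underlying random field.
#' @param vegetation_hue_range,barren_hue_range Hue intervals in degrees,
#'   each within `[0, 360)`; disjoint by default.
#' @param vegetation_sv_range,barren_sv_range Saturation and value intervals
#'   in `[0, 1]`, given as `list(s = c(lo, hi), v = c(lo, hi))`.
#' @param noise_sd Standard deviation of additive i.i.d. Gaussian noise per
#'   8-bit channel (0 disables noise).
#' @param seed Integer RNG seed; `NULL` uses the current RNG stream.
#'
#' @return An object of class `scene_config`.
#' @seealso [generate_scene()]
#' @export
scene_config <- function(width, height,
                         target_prevalence = 0.7382,
                         patch_scale = 32,
                         vegetation_hue_range = c(75, 165),
                         barren_hue_range = c(25, 55),
                         vegetation_sv_range = list(s = c(0.35, 0.85),
                                                    v = c(0.25, 0.75)),
                         barren_sv_range = list(s = c(0.25, 0.65),
                                                v = c(0.45, 0.85)),
                         noise_sd = 10,
                         seed = NULL) {
  width <- as.integer(width)
  height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 1L || height < 1L)
    stop("scene dimensions must be positive integers", call. = FALSE)
  if (!is.numeric(target_prevalence) || length(target_prevalence) != 1L ||
      target_prevalence <= 0 || target_prevalence >= 1)
    stop("target_prevalence must lie strictly between 0 and 1", call. = FALSE)
  if (patch_scale < 1) stop("patch_scale must be >= 1", call. = FALSE)
  check_hue <- function(r, what) {
    if (length(r) != 2L || any(r < 0) || any(r >= 360) || r[1] > r[2])
      stop(what, " must be an increasing interval within [0, 360)",
           call. = FALSE)
  }
  check_hue(vegetation_hue_range, "vegetation_hue_range")
  check_hue(barren_hue_range, "barren_hue_range")
  check_sv <- function(r, what) {
    ok <- is.list(r) && all(c("s", "v") %in% names(r)) &&
      all(vapply(r[c("s", "v")],
                 function(x) length(x) == 2L && all(x >= 0) && all(x <= 1) &&
                   x[1] <= x[2], logical(1)))
    if (!ok) stop(what, " must be list(s = c(lo, hi), v = c(lo, hi)) in [0,1]",
                  call. = FALSE)
  }
  check_sv(vegetation_sv_range, "vegetation_sv_range")
  check_sv(barren_sv_range, "barren_sv_range")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(width = width, height = height,
                 target_prevalence = target_prevalence,
                 patch_scale = patch_scale,
                 vegetation_hue_range = vegetation_hue_range,
                 barren_hue_range = barren_hue_range,
                 vegetation_sv_range = vegetation_sv_range,
                 barren_sv_range = barren_sv_range,
                 noise_sd = noise_sd, seed = seed),
            class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("scene_config: %d x %d px, target prevalence %.4f, noise sd %.1f\n",
              x$width, x$height, x$target_prevalence, x$noise_sd))
  invisible(x)
}

# Separable box blur with edge replication; radius r in pixels.
box_blur <- function(m, r) {
  r <- as.integer(max(1, round(r)))
  blur1 <- function(v) {
    n <- length(v)
    padded <- c(rep(v[1], r), v, rep(v[n], r))
    cs <- cumsum(padded)
    (cs[(2L * r + 1L):(n + 2L * r)] - c(0, cs[seq_len(n - 1L)])) / (2L * r + 1L)
  }
  m <- apply(m, 2L, blur1)
  t(apply(m, 1L, blur1))
}

# Vectorized hexcone HSV -> RGB; h in degrees, s, v in [0,1].
# Returns a 3-column matrix of real-valued intensities in [0, 255].
hsv_to_rgb255 <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t_ <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  sel <- function(i0) i == i0
  r[sel(0)] <- v[sel(0)]; g[sel(0)] <- t_[sel(0)]; b[sel(0)] <- p[sel(0)]
  r[sel(1)] <- q[sel(1)]; g[sel(1)] <- v[sel(1)]; b[sel(1)] <- p[sel(1)]
  r[sel(2)] <- p[sel(2)]; g[sel(2)] <- v[sel(2)]; b[sel(2)] <- t_[sel(2)]
  r[sel(3)] <- p[sel(3)]; g[sel(3)] <- q[sel(3)]; b[sel(3)] <- v[sel(3)]
  r[sel(4)] <- t_[sel(4)]; g[sel(4)] <- p[sel(4)]; b[sel(4)] <- v[sel(4)]
  r[sel(5)] <- v[sel(5)]; g[sel(5)] <- p[sel(5)]; b[sel(5)] <- q[sel(5)]
  cbind(r, g, b) * 255
}

# Shrink a hue interval by a quantization guard so that 8-bit rounding of the
# rendered pixel cannot push its hue outside the configured interval.
guarded_hue_range <- function(range, guard = 4) {
  if (diff(range) > 2 * guard) range + c(guard, -guard) else range
}

#' Generate a labeled synthetic mine scene
#'
#' Draws a smoothed uniform random field, assigns the top
#' `round(target_prevalence * n)` field values to vegetation (which yields
#' contiguous, pit-like patches and pins the realized prevalence to the
#' target within half a pixel), colours vegetation and barren pixels from
#' their configured hue/saturation/value distributions, then adds clipped
#' 8-bit Gaussian channel noise.
#'
#' @param config A [scene_config()].
#' @return An object of class `labeled_scene`: a list with `rgb`, an
#'   `height x width x 3` integer array of 8-bit intensities, and `mask`, an
#'   `height x width` binary matrix (1 = vegetation).
#' @examples
#' sc <- generate_scene(scene_config(64, 64, seed = 1))
#' realized_prevalence(sc)
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  run <- function() {
    h <- config$height; w <- config$width; n <- h * w
    field <- box_blur(matrix(stats::runif(n), nrow = h, ncol = w),
                      config$patch_scale)
    n_veg <- max(1L, min(n - 1L, as.integer(round(config$target_prevalence * n))))
    mask <- matrix(0L, h, w)
    mask[order(field, decreasing = TRUE)[seq_len(n_veg)]] <- 1L

    veg <- mask == 1L
    hue <- sat <- val <- numeric(n)
    vh <- guarded_hue_range(config$vegetation_hue_range)
    bh <- guarded_hue_range(config$barren_hue_range)
    hue[veg] <- stats::runif(sum(veg), vh[1], vh[2])
    hue[!veg] <- stats::runif(sum(!veg), bh[1], bh[2])
    sv <- config$vegetation_sv_range
    sat[veg] <- stats::runif(sum(veg), sv$s[1], sv$s[2])
    val[veg] <- stats::runif(sum(veg), sv$v[1], sv$v[2])
    sv <- config$barren_sv_range
    sat[!veg] <- stats::runif(sum(!veg), sv$s[1], sv$s[2])
    val[!veg] <- stats::runif(sum(!veg), sv$v[1], sv$v[2])

    rgb <- hsv_to_rgb255(hue, sat, val)
    if (config$noise_sd > 0)
      rgb <- rgb + stats::rnorm(length(rgb), sd = config$noise_sd)
    rgb <- array(as.integer(pmin(255, pmax(0, round(rgb)))), dim = c(h, w, 3L))
    structure(list(rgb = rgb, mask = mask), class = "labeled_scene")
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

#' @export
print.labeled_scene <- function(x, ...) {
  cat(sprintf("labeled_scene: %d x %d px, vegetation prevalence %.4f\n",
              nrow(x$mask), ncol(x$mask), realized_prevalence(x)))
  invisible(x)
}

#' Fraction of vegetation pixels in a scene mask
#'
#' @param scene A `labeled_scene`.
#' @return The fraction of mask pixels equal to 1.
#' @export
realized_prevalence <- function(scene) {
  stopifnot(inherits(scene, "labeled_scene"))
  if (length(scene$mask) == 0L) stop("empty scene", call. = FALSE)
  mean(scene$mask == 1L)
}

#' Write / read a labeled scene as paired PNG files
#'
#' The RGB raster is written to `<path>_rgb.png` and the mask to
#' `<path>_mask.png` as a single-channel image with values {0, 255} for
#' {barren, vegetation}. The round trip is lossless.
#'
#' @param scene A `labeled_scene`.
#' @param path Path prefix (no extension).
#' @return `write_scene` invisibly returns the two file paths; `read_scene`
#'   returns the reconstructed `labeled_scene`.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "labeled_scene"))
  rgb_path <- paste0(path, "_rgb.png")
  mask_path <- paste0(path, "_mask.png")
  png::writePNG(scene$rgb / 255, rgb_path)
  png::writePNG(scene$mask / 1, mask_path)   # {0,1} -> bytes {0,255}
  invisible(c(rgb = rgb_path, mask = mask_path))
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  rgb_path <- paste0(path, "_rgb.png")
  mask_path <- paste0(path, "_mask.png")
  rgb <- round(png::readPNG(rgb_path) * 255)
  if (length(dim(rgb)) != 3L || dim(rgb)[3] < 3L)
    stop("rgb raster must have 3 channels", call. = FALSE)
  rgb <- array(as.integer(rgb[, , 1:3]), dim = c(dim(rgb)[1:2], 3L))
  mask_raw <- png::readPNG(mask_path)
  if (length(dim(mask_raw)) == 3L) mask_raw <- mask_raw[, , 1L]
  mask255 <- round(mask_raw * 255)
  if (!all(mask255 %in% c(0, 255)))
    stop("mask file must contain only the byte values 0 and 255",
         call. = FALSE)
  if (!all(dim(mask255) == dim(rgb)[1:2]))
    stop("rgb raster and mask have mismatched dimensions", call. = FALSE)
  structure(list(rgb = rgb,
                 mask = matrix(as.integer(mask255 / 255), nrow = nrow(mask255))),
            class = "labeled_scene")
}
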