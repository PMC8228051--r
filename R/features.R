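#' Convert 8-bit RGB channels to HSV fractions
#'
#' Standard hexcone conversion (via [grDevices::rgb2hsv()]) with every
#' component scaled to `[0, 1]`; hue is reported as a fraction of the circle
#' (degrees / 360).
#'
#' @param r,g,b Numeric vectors of channel intensities in `[0, 255]`.
#' @return A matrix with columns `h`, `s`, `v`, one row per input pixel.
#' @examples
#' rgb_to_hsv(0, 255, 0)  # pure green: h = 1/3, s = 1, v = 1
#' @export
rgb_to_hsv <- function(r, g, b) {
  if (any(c(r, g, b) < 0) || any(c(r, g, b) > 255) ||
      anyNA(c(r, g, b)))
    stop("channel intensities must lie in [0, 255]", call. = FALSE)
  out <- t(grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255))
  colnames(out) <- c("h", "s", "v")
  out
}

#' Per-pixel colour features for RBM visible units
#'
#' Flattens a scene into one row per pixel in row-major (raster) order. The
#' feature vector is `(r/255, g/255, b/255, h, s, v)` -- the three normalized
#' colour channels plus hue, saturation and value -- so every visible unit
#' lies in `[0, 1]`. Labels are copied from the scene mask.
#'
#' @param scene A `labeled_scene`.
#' @return An object of class `pixel_dataset`: list with `features`
#'   (`n x 6` matrix, columns `r,g,b,h,s,v`), `labels` (integer vector in
#'   {0, 1}, 1 = vegetation) and `d` (feature dimension).
#' @export
extract_features <- function(scene) {
  stopifnot(inherits(scene, "labeled_scene"))
  h <- dim(scene$rgb)[1]; w <- dim(scene$rgb)[2]
  # row-major pixel order: transpose each channel plane before flattening
  r <- as.vector(t(scene$rgb[, , 1L]))
  g <- as.vector(t(scene$rgb[, , 2L]))
  b <- as.vector(t(scene$rgb[, , 3L]))
  hsv <- rgb_to_hsv(r, g, b)
  feats <- cbind(r = r / 255, g = g / 255, b = b / 255, hsv)
  pixel_dataset(feats, as.integer(as.vector(t(scene$mask))))
}

#' Construct a pixel dataset
#'
#' @param features `n x d` numeric matrix with entries in `[0, 1]`.
#' @param labels Integer vector in {0, 1} of length `n` (1 = vegetation).
#' @return An object of class `pixel_dataset`.
#' @export
pixel_dataset <- function(features, labels) {
  features <- as.matrix(features)
  if (nrow(features) < 1L) stop("dataset must be nonempty", call. = FALSE)
  if (anyNA(features) || any(features < 0) || any(features > 1))
    stop("features must lie in [0, 1]", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != nrow(features))
    stop("feature and label counts differ", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1", call. = FALSE)
  structure(list(features = features, labels = labels, d = ncol(features)),
            class = "pixel_dataset")
}

#' @export
print.pixel_dataset <- function(x, ...) {
  cat(sprintf("pixel_dataset: %d pixels x %d features, prevalence %.4f\n",
              nrow(x$features), x$d, mean(x$labels)))
  invisible(x)
}

dataset_rows <- function(data, idx) {
  pixel_dataset(data$features[idx, , drop = FALSE], data$labels[idx])
}

#' Split a pixel dataset into train and test parts
#'
#' Seeded uniform pixel-wise split; the two parts are disjoint and exhaustive.
#'
#' @param data A `pixel_dataset`.
#' @param test_fraction Fraction held out for testing, in (0, 1).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return `list(train = , test = )` of `pixel_dataset`s.
#' @export
split_dataset <- function(data, test_fraction, seed = NULL) {
  stopifnot(inherits(data, "pixel_dataset"))
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  n <- nrow(data$features)
  n_test <- round(n * test_fraction)
  if (n_test < 1L || n_test >= n)
    stop("split would leave an empty train or test part", call. = FALSE)
  draw <- function() sample.int(n, n_test)
  test_idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(train = dataset_rows(data, -test_idx),
       test = dataset_rows(data, sort(test_idx)))
}

#' Uniform subsample of a pixel dataset
#'
#' @param data A `pixel_dataset`.
#' @param n Number of pixels to keep (without replacement).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A `pixel_dataset` with exactly `n` rows.
#' @export
subsample <- function(data, n, seed = NULL) {
  stopifnot(inherits(data, "pixel_dataset"))
  n <- as.integer(n)
  if (n < 1L || n > nrow(data$features))
    stop("n must lie in [1, number of pixels]", call. = FALSE)
  draw <- function() sample.int(nrow(data$features), n)
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  dataset_rows(data, idx)
}

#' Write / read a pixel dataset as CSV
#'
#' Columns `r,g,b,h,s,v,label`; intended for small fixtures and debugging.
#'
#' @param data A `pixel_dataset`.
#' @param path File path.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "pixel_dataset"))
  df <- as.data.frame(data$features)
  df$label <- data$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path)
  pixel_dataset(as.matrix(df[, setdiff(names(df), "label"), drop = FALSE]),
                df$label)
}
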