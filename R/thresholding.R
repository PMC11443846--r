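#' Pooled pixel-intensity histogram of an image batch
#'
#' Tallies, over all images, the number of pixels at each intensity 0..255.
#' The result guides the choice of the background cut-off for nucleus
#' segmentation: the intensity where the distribution flattens out marks the
#' transition from background to signal.
#'
#' @param images List of grayscale rasters (integer matrices in `[0, 255]`),
#'   or a `channel_batch`, in which case the marker channel is used.
#' @return A tibble with columns `intensity` (0..255) and `count`, carrying
#'   attributes `n_images` and `n_pixels`.
#' @export
batch_intensity_histogram <- function(images) {
  if (inherits(images, "channel_batch")) images <- images$marker
  if (!is.list(images) || length(images) == 0) {
    abort("empty image batch", class = "fociquant_empty_batch")
  }
  counts <- integer(256)
  for (img in images) {
    counts <- counts + tabulate(as.integer(img) + 1L, nbins = 256L)
  }
  out <- tibble(intensity = 0:255, count = counts)
  attr(out, "n_images") <- length(images)
  attr(out, "n_pixels") <- sum(counts)
  class(out) <- c("intensity_histogram", class(out))
  out
}

#' Suggest a background cut-off from a batch intensity histogram
#'
#' The suggestion is the absolute difference between the mean pixel intensity
#' of the whole batch and the mean recomputed after removing the dominant
#' intensity (the fullest histogram bin, usually the dark background mode),
#' rounded to the nearest integer. When the histogram is concentrated in a
#' single bin the suggestion is 0.
#'
#' @param hist A tibble from [batch_intensity_histogram()].
#' @return Integer intensity in `[0, 255]`.
#' @export
suggest_cutoff <- function(hist) {
  counts <- as.numeric(hist$count)
  n <- sum(counts)
  if (n <= 0) abort("empty histogram", class = "fociquant_empty_batch")
  i <- 0:255
  d <- which.max(counts) - 1L             # dominant intensity, ties -> smallest
  mu_all <- sum(i * counts) / n
  n_excl <- n - counts[d + 1L]
  mu_excl <- if (n_excl > 0) (sum(i * counts) - d * counts[d + 1L]) / n_excl else mu_all
  s <- round_half_up(abs(mu_excl - mu_all))
  as.integer(min(max(s, 0), 255))
}

# between-class variance for every candidate threshold t = 0..255 of an
# intensity histogram; returns the 256-vector (0 where a class is empty)
otsu_between_class_variance <- function(counts) {
  counts <- as.numeric(counts)
  n <- sum(counts)
  i <- 0:255
  w0 <- cumsum(counts)
  s0 <- cumsum(counts * i)
  w1 <- n - w0
  total <- s0[256]
  sigma <- numeric(256)
  ok <- w0 > 0 & w1 > 0
  sigma[ok] <- (total * w0[ok] / n - s0[ok])^2 * n / (w0[ok] * w1[ok])
  sigma
}

#' Otsu global threshold with a background floor
#'
#' Computes the Otsu threshold (the split maximizing between-class variance)
#' over the image histogram, after excluding pixels darker than `floor` —
#' the user's background cut-off — from the histogram. Foreground is every
#' pixel strictly above the threshold and not below the floor. Ties in the
#' variance sweep resolve to the smallest threshold.
#'
#' Degenerate inputs (image constant after flooring, or all pixels below the
#' floor) yield an empty mask and threshold 255 with a warning, so one blank
#' frame never aborts a batch.
#'
#' @param image Grayscale raster (integer matrix in `[0, 255]`).
#' @param floor Background cut-off in `[0, 255]`; pixels below it are
#'   excluded from the histogram and can never be foreground.
#' @return A list with `threshold` (integer) and `mask` (0/1 integer matrix).
#' @export
otsu_threshold <- function(image, floor = 0L) {
  stopifnot(is.matrix(image))
  if (floor < 0 || floor > 255) {
    abort("floor must be in [0, 255]", class = "fociquant_invalid_parameter")
  }
  v <- as.integer(image)
  kept <- v[v >= floor]
  empty <- function() {
    warn("degenerate image: no intensity split exists; returning empty mask")
    list(threshold = 255L,
         mask = matrix(0L, nrow(image), ncol(image)))
  }
  if (length(kept) == 0) return(empty())
  counts <- tabulate(kept + 1L, nbins = 256L)
  sigma <- otsu_between_class_variance(counts)
  if (max(sigma) <= 0) return(empty())   # constant after flooring
  t <- which.max(sigma) - 1L             # smallest maximizer
  mask <- matrix(as.integer(image > t & image >= floor),
                 nrow(image), ncol(image))
  list(threshold = as.integer(max(t, floor)), mask = mask)
}

# OpenCV-convention Gaussian kernel for a given odd aperture:
# sigma = 0.3 * ((k - 1) * 0.5 - 1) + 0.8, normalized to sum 1
gaussian_kernel_1d <- function(block_size) {
  sigma <- 0.3 * ((block_size - 1) * 0.5 - 1) + 0.8
  x <- seq_len(block_size) - 1 - (block_size - 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# reflect-101 index vector: n valid indices padded by r on each side,
# mirroring about the edge pixel without repeating it (period 2n - 2)
reflect_index <- function(n, r) {
  if (n == 1) return(rep(1L, n + 2 * r))
  idx <- seq.int(1 - r, n + r)
  period <- 2L * (n - 1L)
  m <- (idx - 1L) %% period
  m <- ifelse(m >= n, period - m, m)
  as.integer(m + 1L)
}

#' Adaptive Gaussian-C local threshold
#'
#' Binarizes an image against a per-pixel threshold `T(p) = G(p) - c_offset`,
#' where `G(p)` is the Gaussian-weighted mean of the `block_size` x
#' `block_size` neighborhood of `p` (kernel = outer product of a 1D Gaussian
#' with the conventional aperture-derived sigma, normalized to sum 1; the
#' image is mirror-extended at its borders). A pixel is foreground iff its
#' value is strictly greater than `T(p)`. This is the local-contrast operator
#' used to pick out compact bright foci against the varying intensity inside
#' a nucleus.
#'
#' Note the sign convention: larger `c_offset` lowers the threshold and grows
#' the foreground. On a perfectly flat region a positive `c_offset` marks
#' every pixel foreground; use a negative offset to demand that foci stand
#' out above their local surroundings.
#'
#' A pixel exactly equal to its local threshold is background (strict
#' inequality). Because the weighted mean is computed in floating point, this
#' tie rule is enforced with a `1e-9` guard, so neighborhoods whose weighted
#' mean coincides exactly with the center value resolve deterministically
#' regardless of summation order.
#'
#' @param image Grayscale raster (integer matrix in `[0, 255]`).
#' @param block_size Odd neighborhood width in pixels, at least 3.
#' @param c_offset Signed intensity offset subtracted from the local mean.
#' @return 0/1 integer matrix, same shape as `image`.
#' @export
adaptive_gaussian_mask <- function(image, block_size = 11L, c_offset = 2) {
  stopifnot(is.matrix(image))
  if (length(block_size) != 1 || block_size < 3 || block_size %% 2 != 1) {
    abort("block_size must be an odd integer >= 3",
          class = "fociquant_invalid_parameter")
  }
  g <- gaussian_kernel_1d(block_size)
  r <- (block_size - 1L) / 2L
  n <- nrow(image); m <- ncol(image)
  # separable convolution with reflect-101 padding
  pr <- image[reflect_index(n, r), , drop = FALSE]
  tmp <- matrix(0, n, m)
  for (j in seq_len(block_size)) {
    tmp <- tmp + g[j] * pr[j:(j + n - 1L), , drop = FALSE]
  }
  pc <- tmp[, reflect_index(m, r), drop = FALSE]
  loc <- matrix(0, n, m)
  for (j in seq_len(block_size)) {
    loc <- loc + g[j] * pc[, j:(j + m - 1L), drop = FALSE]
  }
  matrix(as.integer(image - (loc - c_offset) > 1e-9), n, m)
}
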