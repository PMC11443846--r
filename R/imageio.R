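#' Read a single-channel 8-bit grayscale image
#'
#' Decodes a JPEG, PNG or TIFF file and returns an integer matrix of pixel
#' intensities in `[0, 255]` (rows are image rows). RGB images are converted
#' to luminance with the BT.601 weights `0.299 R + 0.587 G + 0.114 B` and
#' rounded half-up; images of more than 8 bits per sample are rescaled
#' linearly so that the maximum representable value maps to 255. An alpha
#' channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return Integer matrix with attribute `source_name` (the file's basename).
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(64), 8, 8), f)
#' img <- load_gray_image(f)
#' range(img)
load_gray_image <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("image file does not exist: ", path), class = "fociquant_decode_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      abort(paste0("unsupported image format '.", ext, "': ", path),
            class = "fociquant_decode_error")
    ),
    error = function(e) {
      if (inherits(e, "fociquant_decode_error")) stop(e)
      abort(paste0("cannot decode image file ", path, ": ", conditionMessage(e)),
            class = "fociquant_decode_error")
    }
  )
  if (is.list(raw)) {
    abort(paste0("multi-page TIFF is not supported: ", path),
          class = "fociquant_decode_error")
  }
  if (length(raw) == 0 || any(dim(raw)[1:2] == 0)) {
    abort(paste0("zero-sized image: ", path), class = "fociquant_invalid_input")
  }
  # readers return values in [0, 1]; 1 is the maximum representable value
  # of the source bit depth, so scaling by 255 implements max-value mapping
  if (length(dim(raw)) == 3) {
    nch <- dim(raw)[3]
    g01 <- if (nch >= 3) {
      0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3]
    } else {
      raw[, , 1]  # gray + alpha
    }
    g01 <- matrix(g01, dim(raw)[1], dim(raw)[2])
  } else {
    g01 <- raw
  }
  px <- matrix(as.integer(round_half_up(255 * g01)),
               nrow = nrow(g01), ncol = ncol(g01))
  px[px < 0L] <- 0L
  px[px > 255L] <- 255L
  attr(px, "source_name") <- basename(path)
  px
}

image_file_pattern <- "\\.(png|tif|tiff|jpg|jpeg)$"

list_image_files <- function(dir) {
  files <- list.files(dir, pattern = image_file_pattern, ignore.case = TRUE)
  # byte-wise (C locale) order: deterministic across platforms and locales
  sort(files, method = "radix")
}

#' Discover and load a paired marker/damage image batch
#'
#' Enumerates image files (JPEG/PNG/TIFF) in the two folders, sorts each list
#' lexicographically (byte order), pairs them by rank, loads every image and
#' checks that paired images share dimensions. The two folders must hold the
#' same number of images.
#'
#' @param marker_dir Folder of nuclear/cell marker images (DAPI/NeuN-style).
#' @param damage_dir Folder of DNA-damage marker images (gamma-H2AX-style).
#' @return A tibble of class `channel_batch` with one row per pair: columns
#'   `pair_id`, `marker_name`, `damage_name`, and list-columns `marker`,
#'   `damage` holding the loaded grayscale rasters.
#' @export
discover_batch <- function(marker_dir, damage_dir) {
  for (d in c(marker_dir, damage_dir)) {
    if (!dir.exists(d)) abort(paste0("input folder does not exist: ", d),
                              class = "fociquant_invalid_input")
  }
  mf <- list_image_files(marker_dir)
  df <- list_image_files(damage_dir)
  if (length(mf) == 0 || length(df) == 0) {
    abort(paste0("empty image folder: ",
                 if (length(mf) == 0) marker_dir else damage_dir),
          class = "fociquant_empty_batch")
  }
  if (length(mf) != length(df)) {
    abort(sprintf(
      "batch mismatch: %d marker images in %s but %d damage images in %s",
      length(mf), marker_dir, length(df), damage_dir),
      class = "fociquant_batch_mismatch")
  }
  if (!identical(tools::file_path_sans_ext(mf), tools::file_path_sans_ext(df))) {
    warn("marker and damage filenames differ; images are paired by sorted rank")
  }
  marker <- lapply(file.path(marker_dir, mf), load_gray_image)
  damage <- lapply(file.path(damage_dir, df), load_gray_image)
  for (i in seq_along(marker)) {
    if (!identical(dim(marker[[i]]), dim(damage[[i]]))) {
      abort(sprintf("shape mismatch in pair %d: %s is %dx%d but %s is %dx%d",
                    i, mf[i], nrow(marker[[i]]), ncol(marker[[i]]),
                    df[i], nrow(damage[[i]]), ncol(damage[[i]])),
            class = "fociquant_shape_mismatch")
    }
  }
  out <- tibble(
    pair_id = seq_along(mf),
    marker_name = mf,
    damage_name = df,
    marker = marker,
    damage = damage
  )
  class(out) <- c("channel_batch", class(out))
  out
}

# fixed 22-color palette (RGB in 0..255); label k gets color
# palette[(k - 1) %% 22 + 1]; black is reserved for background
label_palette <- function() {
  hex <- c(
    "#E6194B", "#3CB44B", "#FFE119", "#4363D8", "#F58231", "#911EB4",
    "#46F0F0", "#F032E6", "#BCF60C", "#FABEBE", "#008080", "#E6BEFF",
    "#9A6324", "#FFFAC8", "#800000", "#AAFFC3", "#808000", "#FFD8B1",
    "#000075", "#FF69B4", "#00FF7F", "#7FFF00"
  )
  t(grDevices::col2rgb(hex))
}

label_rgb_array <- function(labels) {
  pal <- label_palette()
  np <- nrow(pal)
  arr <- array(0, dim = c(nrow(labels), ncol(labels), 3))
  fg <- which(labels > 0L)
  if (length(fg)) {
    idx <- (labels[fg] - 1L) %% np + 1L
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[fg] <- pal[idx, ch] / 255
      arr[, , ch] <- plane
    }
  }
  arr
}

#' Write a label map as a color-coded PNG
#'
#' Background (label 0) is black; each positive label is drawn in a distinct
#' deterministic color taken from a fixed palette, indexed by label id modulo
#' the palette size.
#'
#' @param labels Integer matrix of component labels (0 = background).
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_label_image <- function(labels, path) {
  stopifnot(is.matrix(labels))
  ok <- tryCatch({
    png::writePNG(label_rgb_array(labels), path); TRUE
  }, error = function(e) {
    abort(paste0("cannot write image ", path, ": ", conditionMessage(e)),
          class = "fociquant_io_error")
  })
  invisible(path)
}

#' Overlay detected foci on a raw image
#'
#' Renders the raw grayscale image and recolors every labeled focus pixel
#' with the label palette, then writes the result as an RGB PNG.
#'
#' @param raw Grayscale raster (integer matrix in `[0, 255]`).
#' @param foci_labels Label map of detected foci, same shape as `raw`.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_overlay <- function(raw, foci_labels, path) {
  if (!identical(dim(raw), dim(foci_labels))) {
    abort("raw image and label map have different shapes",
          class = "fociquant_invalid_input")
  }
  g <- raw / 255
  arr <- array(rep(g, 3), dim = c(nrow(raw), ncol(raw), 3))
  pal <- label_palette()
  np <- nrow(pal)
  fg <- which(foci_labels > 0L)
  if (length(fg)) {
    idx <- (foci_labels[fg] - 1L) %% np + 1L
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[fg] <- pal[idx, ch] / 255
      arr[, , ch] <- plane
    }
  }
  tryCatch(png::writePNG(arr, path), error = function(e) {
    abort(paste0("cannot write image ", path, ": ", conditionMessage(e)),
          class = "fociquant_io_error")
  })
  invisible(path)
}

write_gray_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}
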