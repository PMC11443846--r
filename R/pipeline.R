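#' Analysis parameter set
#'
#' Bundles and validates the user-facing parameters of a batch run: the
#' background cut-off used when thresholding the marker channel, the pixel
#' area window a connected component must fall in to count as a nucleus, and
#' the minimum pixel area of a DNA-damage focus, plus the fixed algorithm
#' knobs (connectivity, adaptive-threshold aperture and offset, optional
#' exclusion of nuclei touching the image border).
#'
#' @param intensity_cutoff Background cut-off in `[0, 255]` for marker
#'   thresholding; pixels below it are ignored entirely.
#' @param marker_area_min,marker_area_max Nucleus area window in pixels.
#' @param foci_area_min Minimum focus area in pixels (>= 1; 1 keeps
#'   everything, 3 reproduces a "larger than 2 pixels" rule).
#' @param connectivity Neighbor rule for component labeling, 4 or 8.
#' @param block_size Adaptive-threshold neighborhood width (odd, >= 3).
#' @param c_offset Adaptive-threshold offset; the local threshold is the
#'   Gaussian-weighted neighborhood mean minus this value.
#' @param exclude_edge_nuclei Drop nuclei whose bounding box touches the
#'   image border (default `FALSE`).
#' @return A validated list of class `analysis_params`.
#' @export
analysis_params <- function(intensity_cutoff = 0L,
                            marker_area_min = 1L,
                            marker_area_max = Inf,
                            foci_area_min = 1L,
                            connectivity = 8L,
                            block_size = 11L,
                            c_offset = 2,
                            exclude_edge_nuclei = FALSE) {
  bad <- function(msg) abort(msg, class = "fociquant_invalid_parameter")
  if (intensity_cutoff < 0 || intensity_cutoff > 255) bad("intensity_cutoff must be in [0, 255]")
  if (marker_area_min < 1) bad("marker_area_min must be >= 1")
  if (is.finite(marker_area_max) && marker_area_max < marker_area_min) {
    bad("marker_area_max must be >= marker_area_min")
  }
  if (foci_area_min < 1) bad("foci_area_min must be >= 1")
  if (!connectivity %in% c(4, 8)) bad("connectivity must be 4 or 8")
  if (block_size < 3 || block_size %% 2 != 1) bad("block_size must be odd and >= 3")
  structure(list(
    intensity_cutoff = as.integer(intensity_cutoff),
    marker_area_min = marker_area_min,
    marker_area_max = marker_area_max,
    foci_area_min = foci_area_min,
    connectivity = as.integer(connectivity),
    block_size = as.integer(block_size),
    c_offset = c_offset,
    exclude_edge_nuclei = isTRUE(exclude_edge_nuclei)
  ), class = "analysis_params")
}

relabel_to <- function(labels, kept_labels) {
  lut <- integer(max(labels, 1L) + 1L)
  lut[kept_labels + 1L] <- seq_along(kept_labels)
  matrix(lut[labels + 1L], nrow(labels), ncol(labels))
}

#' Detect nuclei in a marker image
#'
#' Thresholds the marker channel (Otsu over the histogram above the
#' background cut-off), labels connected components, and keeps components
#' whose area lies in the marker window; optionally drops components touching
#' the image border. Surviving nuclei are renumbered 1..k in detection order.
#'
#' @param marker Grayscale marker raster.
#' @param params An [analysis_params()] object.
#' @return List with `labels` (nucleus label map), `regions` (tibble with
#'   `nucleus_id` + region measurements) and `threshold` (the applied Otsu
#'   threshold).
#' @export
detect_nuclei <- function(marker, params) {
  stopifnot(inherits(params, "analysis_params"))
  th <- otsu_threshold(marker, params$intensity_cutoff)
  cc <- label_components(th$mask, params$connectivity)
  keep <- filter_by_area(cc$regions, params$marker_area_min, params$marker_area_max)
  if (params$exclude_edge_nuclei && nrow(keep) > 0) {
    keep <- dplyr::filter(keep,
      .data$row_min > 1, .data$col_min > 1,
      .data$row_max <= nrow(marker), .data$col_max <= ncol(marker))
  }
  labels <- relabel_to(cc$labels, keep$label)
  regions <- dplyr::mutate(keep, nucleus_id = dplyr::row_number(),
                           .before = 1)
  regions$label <- regions$nucleus_id
  list(labels = labels, regions = regions, threshold = th$threshold)
}

#' Detect DNA-damage foci inside detected nuclei
#'
#' Computes the adaptive Gaussian-C mask over the whole damage image (so
#' block artifacts from per-nucleus crops cannot arise), intersects it with
#' each nucleus's pixel set, labels the intersection, and keeps components at
#' least `foci_area_min` pixels large. Signal outside every nucleus is
#' discarded.
#'
#' @param damage Grayscale damage raster, same shape as the nucleus map.
#' @param nucleus_labels Nucleus label map from [detect_nuclei()].
#' @param params An [analysis_params()] object.
#' @return List with `foci` (tibble: `nucleus_id`, `focus_id`, `area`, bbox
#'   and centroid columns) and `labels` (label map of all retained foci,
#'   numbered globally).
#' @export
detect_foci <- function(damage, nucleus_labels, params) {
  stopifnot(inherits(params, "analysis_params"))
  if (!identical(dim(damage), dim(nucleus_labels))) {
    abort("damage image and nucleus label map have different shapes",
          class = "fociquant_invalid_input")
  }
  mask <- adaptive_gaussian_mask(damage, params$block_size, params$c_offset)
  n_nuc <- max(nucleus_labels, 0L)
  foci_labels <- matrix(0L, nrow(damage), ncol(damage))
  out <- vector("list", n_nuc)
  next_lab <- 0L
  for (k in seq_len(n_nuc)) {
    sel <- nucleus_labels == k
    rows <- range(which(rowSums(sel) > 0))
    cols <- range(which(colSums(sel) > 0))
    sub <- mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE] *
      (sel[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE])
    cc <- label_components(sub, params$connectivity)
    keep <- filter_by_area(cc$regions, params$foci_area_min, Inf)
    if (nrow(keep) > 0) {
      lm <- relabel_to(cc$labels, keep$label)
      patch <- foci_labels[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
      patch[lm > 0] <- lm[lm > 0] + next_lab
      foci_labels[rows[1]:rows[2], cols[1]:cols[2]] <- patch
      keep <- dplyr::mutate(keep,
        nucleus_id = k,
        focus_id = dplyr::row_number(),
        label = .data$focus_id + next_lab,
        row_min = .data$row_min + rows[1] - 1L,
        row_max = .data$row_max + rows[1] - 1L,
        col_min = .data$col_min + cols[1] - 1L,
        col_max = .data$col_max + cols[1] - 1L,
        centroid_row = .data$centroid_row + rows[1] - 1,
        centroid_col = .data$centroid_col + cols[1] - 1)
      next_lab <- next_lab + nrow(keep)
      out[[k]] <- keep
    }
  }
  foci <- dplyr::bind_rows(out)
  if (nrow(foci) == 0) {
    foci <- tibble(nucleus_id = integer(), focus_id = integer(),
                   label = integer(), area = integer(),
                   row_min = integer(), col_min = integer(),
                   row_max = integer(), col_max = integer(),
                   centroid_row = numeric(), centroid_col = numeric())
  } else {
    foci <- dplyr::select(foci, "nucleus_id", "focus_id", "label", "area",
                          "row_min", "col_min", "row_max", "col_max",
                          "centroid_row", "centroid_col")
  }
  list(foci = foci, labels = foci_labels)
}

# full analysis of one marker/damage pair, returning records and label maps
analyze_pair <- function(marker, damage, params, image_name = "image") {
  nuc <- detect_nuclei(marker, params)
  foc <- detect_foci(damage, nuc$labels, params)
  if (nrow(nuc$regions) == 0) {
    records <- tibble(image_name = character(), nucleus_id = integer(),
                      nucleus_area_px = integer(), foci_count = integer(),
                      mean_foci_area_px = numeric(), total_foci_area_px = numeric())
  } else {
    agg <- dplyr::summarise(dplyr::group_by(foc$foci, .data$nucleus_id),
                            foci_count = dplyr::n(),
                            total_foci_area_px = sum(.data$area))
    records <- dplyr::left_join(
      dplyr::transmute(nuc$regions, nucleus_id = .data$nucleus_id,
                       nucleus_area_px = .data$area),
      agg, by = "nucleus_id")
    records <- dplyr::mutate(records,
      foci_count = dplyr::coalesce(.data$foci_count, 0L),
      total_foci_area_px = dplyr::coalesce(.data$total_foci_area_px, 0),
      mean_foci_area_px = ifelse(.data$foci_count > 0,
                                 .data$total_foci_area_px / .data$foci_count, 0),
      image_name = image_name)
    records <- dplyr::select(records, "image_name", "nucleus_id",
                             "nucleus_area_px", "foci_count",
                             "mean_foci_area_px", "total_foci_area_px")
  }
  list(records = records, nuclei = nuc, foci = foc)
}

#' Quantify DNA damage for one marker/damage image pair
#'
#' Runs nucleus detection and focus detection and returns one row per
#' retained nucleus: the focus count, the mean focus area and the total
#' damaged area, all in pixels. Nuclei with no foci are reported with a
#' count of 0 and a mean of 0 so group averages are taken over all analysed
#' cells.
#'
#' @param marker,damage Grayscale rasters of identical shape.
#' @param params An [analysis_params()] object.
#' @param image_name Name recorded in the `image_name` column.
#' @return Tibble with columns `image_name`, `nucleus_id`,
#'   `nucleus_area_px`, `foci_count`, `mean_foci_area_px`,
#'   `total_foci_area_px`.
#' @export
quantify_pair <- function(marker, damage, params, image_name = "image") {
  analyze_pair(marker, damage, params, image_name)$records
}

format_mean_2dp <- function(x) sprintf("%.2f", round_half_up(x, 2))

#' Run the full batch analysis and write the output tree
#'
#' Processes every marker/damage pair of a batch and writes, under
#' `output_root/output_name`: the three diagnostic image folders
#' `Output_images_nucleus`, `Output_images_DNAdamage` and
#' `Output_images_overlaid` (one PNG per input image); `Quantification.csv`
#' (one row per nucleus, mean areas printed with 2 decimals, half-up);
#' `Given_parameters.csv` (all parameters plus tool version and timestamp);
#' and the batch diagnostics `pixel_intensity.csv`/`.png` and
#' `MARKER_size.csv`/`.png`. A degenerate image (nothing to segment) is
#' logged and skipped, never aborting the batch. The name `Results` is
#' reserved and refused, and a pre-existing output folder is never touched.
#'
#' @param batch A `channel_batch` from [discover_batch()].
#' @param params An [analysis_params()] object.
#' @param output_name Name of the output folder (not `"Results"`).
#' @param output_root Directory under which the output folder is created.
#' @return An object of class `foci_run`: list with `records` (the
#'   quantification tibble), `images` (per-image summary), `params`,
#'   `output_dir` and `manifest` (files written). Use [tidy()] and
#'   [glance()] to extract tidy summaries.
#' @export
run_batch <- function(batch, params, output_name, output_root = ".") {
  stopifnot(inherits(params, "analysis_params"))
  if (!is.character(output_name) || length(output_name) != 1 ||
      !nzchar(output_name)) {
    abort("output_name must be a non-empty string",
          class = "fociquant_invalid_output")
  }
  if (identical(output_name, "Results")) {
    abort("output name 'Results' is reserved; choose a name describing your dataset",
          class = "fociquant_invalid_output")
  }
  out_dir <- file.path(output_root, output_name)
  if (dir.exists(out_dir) || file.exists(out_dir)) {
    abort(paste0("output folder already exists and will not be touched: ", out_dir),
          class = "fociquant_invalid_output")
  }
  dirs <- file.path(out_dir, c("Output_images_nucleus", "Output_images_DNAdamage",
                               "Output_images_overlaid"))
  for (d in dirs) dir.create(d, recursive = TRUE)
  manifest <- character(0)
  note <- function(p) manifest <<- c(manifest, p)

  png_name <- function(f) paste0(tools::file_path_sans_ext(f), ".png")
  all_records <- vector("list", nrow(batch))
  img_summary <- vector("list", nrow(batch))
  regions_per_image <- vector("list", nrow(batch))

  for (i in seq_len(nrow(batch))) {
    res <- analyze_pair(batch$marker[[i]], batch$damage[[i]], params,
                        image_name = batch$marker_name[i])
    all_records[[i]] <- res$records
    regions_per_image[[i]] <- res$nuclei$regions
    img_summary[[i]] <- tibble(
      image_name = batch$marker_name[i],
      n_nuclei = nrow(res$nuclei$regions),
      n_foci = nrow(res$foci$foci),
      otsu_threshold = res$nuclei$threshold
    )
    note(write_label_image(res$nuclei$labels,
                           file.path(dirs[1], png_name(batch$marker_name[i]))))
    note(write_label_image(res$foci$labels,
                           file.path(dirs[2], png_name(batch$damage_name[i]))))
    note(write_overlay(batch$damage[[i]], res$foci$labels,
                       file.path(dirs[3], png_name(batch$damage_name[i]))))
  }

  records <- dplyr::bind_rows(all_records)
  if (nrow(records) == 0) {
    records <- tibble(image_name = character(), nucleus_id = integer(),
                      nucleus_area_px = integer(), foci_count = integer(),
                      mean_foci_area_px = numeric(), total_foci_area_px = numeric())
  }

  quant_path <- file.path(out_dir, "Quantification.csv")
  quant_out <- dplyr::mutate(records,
    mean_foci_area_px = format_mean_2dp(.data$mean_foci_area_px))
  readr::write_csv(quant_out, quant_path)
  note(quant_path)

  gp <- tibble(
    parameter = c("intensity_cutoff", "marker_area_min", "marker_area_max",
                  "foci_area_min", "connectivity", "block_size", "c_offset",
                  "exclude_edge_nuclei", "tool_version", "timestamp"),
    value = c(params$intensity_cutoff, params$marker_area_min,
              params$marker_area_max, params$foci_area_min,
              params$connectivity, params$block_size, params$c_offset,
              params$exclude_edge_nuclei,
              as.character(packageVersion("fociquant")),
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  )
  gp_path <- file.path(out_dir, "Given_parameters.csv")
  readr::write_csv(gp, gp_path)
  note(gp_path)

  hist <- batch_intensity_histogram(batch$marker)
  hist_path <- file.path(out_dir, "pixel_intensity.csv")
  readr::write_csv(hist, hist_path)
  note(hist_path)
  cutoff <- suggest_cutoff(hist)
  note(save_plot(plot_intensity_histogram(hist, cutoff),
                 file.path(out_dir, "pixel_intensity.png")))

  sizes <- marker_size_histogram(regions_per_image)
  size_path <- file.path(out_dir, "MARKER_size.csv")
  readr::write_csv(sizes, size_path)
  note(size_path)
  note(save_plot(plot_marker_sizes(sizes),
                 file.path(out_dir, "MARKER_size.png")))

  structure(list(
    records = records,
    images = dplyr::bind_rows(img_summary),
    params = params,
    output_dir = out_dir,
    suggested_cutoff = cutoff,
    manifest = manifest
  ), class = "foci_run")
}

#' @export
print.foci_run <- function(x, ...) {
  cat("<foci_run> ", nrow(x$images), " image pair(s), ",
      nrow(x$records), " nuclei\n", sep = "")
  cat("  output: ", x$output_dir, "\n", sep = "")
  if (nrow(x$records) > 0) {
    cat(sprintf("  mean foci/nucleus: %.2f; mean total damaged area: %.2f px\n",
                mean(x$records$foci_count), mean(x$records$total_foci_area_px)))
  }
  invisible(x)
}

#' Tidy the per-nucleus records of a run
#'
#' @param x A `foci_run` object.
#' @param ... Unused.
#' @return The per-nucleus quantification tibble.
#' @export
tidy.foci_run <- function(x, ...) x$records

#' One-row summary of a batch run
#'
#' @param x A `foci_run` object.
#' @param ... Unused.
#' @return A one-row tibble: image, nucleus and focus counts, mean foci per
#'   nucleus, mean focus area and mean total damaged area per nucleus.
#' @export
glance.foci_run <- function(x, ...) {
  r <- x$records
  tibble(
    n_images = nrow(x$images),
    n_nuclei = nrow(r),
    n_foci = sum(r$foci_count),
    mean_foci_count = if (nrow(r)) mean(r$foci_count) else NA_real_,
    mean_foci_area = if (nrow(r)) mean(r$mean_foci_area_px) else NA_real_,
    mean_total_foci_area = if (nrow(r)) mean(r$total_foci_area_px) else NA_real_
  )
}
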