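#' Label connected components of a binary mask
#'
#' Two-pass run-based labeling with union-find. Foreground runs are extracted
#' row by row and merged with overlapping runs of the previous row (touching
#' corners count as overlap under 8-connectivity). Components are numbered
#' 1..n in raster-scan order of each component's first pixel, so labeling is
#' fully deterministic.
#'
#' @param mask 0/1 integer matrix.
#' @param connectivity 4 (edge neighbors) or 8 (edge + corner neighbors).
#' @return A list with `labels` (integer matrix, 0 = background) and
#'   `regions`, a tibble with one row per component: `label`, `area`,
#'   half-open bounding box `row_min`, `col_min`, `row_max`, `col_max`
#'   (1-based; `row_max`/`col_max` exclusive) and `centroid_row`,
#'   `centroid_col` (means of member pixel coordinates).
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4L, 8L)) {
    abort("connectivity must be 4 or 8", class = "fociquant_invalid_parameter")
  }
  n <- nrow(mask); m <- ncol(mask)
  empty <- function() list(
    labels = matrix(0L, n, m),
    regions = tibble(label = integer(), area = integer(),
                     row_min = integer(), col_min = integer(),
                     row_max = integer(), col_max = integer(),
                     centroid_row = numeric(), centroid_col = numeric())
  )
  fgmat <- mask != 0
  if (!any(fgmat)) return(empty())

  # extract foreground runs per row: (row, start col, end col)
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  for (r in seq_len(n)) {
    row <- fgmat[r, ]
    if (!any(row)) next
    d <- diff(c(FALSE, row, FALSE))
    s <- which(d == 1L)
    e <- which(d == -1L) - 1L
    run_row <- c(run_row, rep.int(r, length(s)))
    run_s <- c(run_s, s)
    run_e <- c(run_e, e)
  }
  nr <- length(run_row)

  # union-find over runs
  parent <- seq_len(nr)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8L) 1L else 0L
  prev_idx <- integer(0); prev_r <- -1L
  row_start <- 1L
  while (row_start <= nr) {
    r <- run_row[row_start]
    row_end <- row_start
    while (row_end < nr && run_row[row_end + 1L] == r) row_end <- row_end + 1L
    cur_idx <- row_start:row_end
    if (r == prev_r + 1L) {
      for (i in cur_idx) {
        for (j in prev_idx) {
          if (run_s[i] <= run_e[j] + slack && run_e[i] >= run_s[j] - slack) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
          }
        }
      }
    }
    prev_idx <- cur_idx
    prev_r <- r
    row_start <- row_end + 1L
  }
  root <- vapply(seq_len(nr), find, integer(1))

  # number components by raster order of their first run (runs are already
  # in raster order, so the first occurrence of each root gives the order)
  first <- !duplicated(root)
  lab_of_root <- setNames(seq_len(sum(first)), root[first])
  run_lab <- unname(lab_of_root[as.character(root)])

  labels <- matrix(0L, n, m)
  for (k in seq_len(nr)) {
    labels[run_row[k], run_s[k]:run_e[k]] <- run_lab[k]
  }

  len <- run_e - run_s + 1L
  area <- as.integer(rowsum(len, run_lab))
  sum_r <- rowsum(as.numeric(run_row) * len, run_lab)[, 1]
  sum_c <- rowsum((run_s + run_e) / 2 * len, run_lab)[, 1]
  regions <- tibble(
    label = sort(unique(run_lab)),
    area = area,
    row_min = as.integer(tapply(run_row, run_lab, min)),
    col_min = as.integer(tapply(run_s, run_lab, min)),
    row_max = as.integer(tapply(run_row, run_lab, max)) + 1L,
    col_max = as.integer(tapply(run_e, run_lab, max)) + 1L,
    centroid_row = unname(sum_r) / area,
    centroid_col = unname(sum_c) / area
  )
  list(labels = labels, regions = regions)
}

#' Keep regions whose pixel area lies in a window
#'
#' The size gate of the pipeline: markers (nuclei) are filtered with a
#' bounded window, foci with a lower bound only (`max_area = Inf`).
#'
#' @param regions Region tibble (from [label_components()]).
#' @param min_area Minimum pixel area, at least 1.
#' @param max_area Maximum pixel area, or `Inf` for unbounded.
#' @return The filtered region tibble, original order preserved.
#' @export
filter_by_area <- function(regions, min_area, max_area = Inf) {
  if (min_area < 1) {
    abort("min_area must be >= 1", class = "fociquant_invalid_parameter")
  }
  if (is.finite(max_area) && max_area < min_area) {
    abort("max_area must be >= min_area", class = "fociquant_invalid_parameter")
  }
  dplyr::filter(regions, .data$area >= min_area, .data$area <= max_area)
}

#' Histogram of detected marker (nucleus) sizes
#'
#' Bins the pixel areas of all detected regions across a batch, mirroring the
#' size-distribution plot used to choose the marker area window.
#'
#' @param regions_per_image List of region tibbles (one per image), or a
#'   single region tibble.
#' @param bin_width Bin width in pixels (default 100).
#' @return Tibble with columns `bin_low`, `bin_high`, `count`; zero rows when
#'   there are no regions.
#' @export
marker_size_histogram <- function(regions_per_image, bin_width = 100) {
  if (is.data.frame(regions_per_image)) regions_per_image <- list(regions_per_image)
  areas <- unlist(lapply(regions_per_image, function(r) r$area))
  if (is.null(areas) || length(areas) == 0) {
    return(tibble(bin_low = numeric(), bin_high = numeric(), count = integer()))
  }
  bin <- floor(areas / bin_width)
  tab <- table(bin)
  lo <- as.numeric(names(tab)) * bin_width
  tibble(bin_low = lo, bin_high = lo + bin_width,
         count = as.integer(tab))
}
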