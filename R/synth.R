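#' @name synthetic-scenes
#' @title Ground-truthed synthetic marker/damage scenes
#' @description
#' The generator emulates the inputs the pipeline is built for: a marker
#' channel holding bright elliptical nuclei on a dark background (DAPI/NeuN
#' style) and a damage channel holding compact bright foci inside those
#' nuclei (gamma-H2AX style), optionally pan-nuclear damage filling a whole
#' nucleus. Every geometric quantity is recorded after rasterization, so the
#' ground truth is exact at the pixel level and the full pipeline can be
#' validated without any microscopy data.
NULL

# pixels (integer centers) inside an ellipse; returns cbind(row, col)
rasterize_ellipse <- function(cr, cc, a, b, theta, shape) {
  H <- shape[1]; W <- shape[2]
  r0 <- max(1L, floor(cr - a)); r1 <- min(H, ceiling(cr + a))
  c0 <- max(1L, floor(cc - a)); c1 <- min(W, ceiling(cc + a))
  if (r0 > r1 || c0 > c1) return(cbind(row = integer(), col = integer()))
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - cr, length(rows), length(cols))
  dx <- matrix(cols - cc, length(rows), length(cols), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = rows[idx[, 1]], col = cols[idx[, 2]])
}

rasterize_disk <- function(cr, cc, radius, shape) {
  H <- shape[1]; W <- shape[2]
  r0 <- max(1L, floor(cr - radius)); r1 <- min(H, ceiling(cr + radius))
  c0 <- max(1L, floor(cc - radius)); c1 <- min(W, ceiling(cc + radius))
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - cr, length(rows), length(cols))
  dx <- matrix(cols - cc, length(rows), length(cols), byrow = TRUE)
  idx <- which(dy^2 + dx^2 <= radius^2, arr.ind = TRUE)
  cbind(row = rows[idx[, 1]], col = cols[idx[, 2]])
}

#' Generate a synthetic scene description
#'
#' Places `n_nuclei` elliptical nuclei by seeded rejection sampling (pairwise
#' separated by at least 2 px unless `allow_overlap`), scaling each ellipse
#' until its rasterized pixel count falls inside `area_range`, then scatters
#' hard-disk foci fully inside each nucleus (pairwise well separated). A
#' seeded fraction of nuclei can instead carry pan-nuclear damage. All
#' recorded areas are exact rasterized pixel counts; the same seed always
#' yields the same scene.
#'
#' @param n_nuclei Number of nuclei to place.
#' @param image_shape `c(height, width)` in pixels.
#' @param area_range Nucleus pixel-area interval, e.g. `c(1000, 2500)`.
#' @param foci_count_range Integer interval of foci per nucleus.
#' @param foci_radius_range Focus radius interval in pixels.
#' @param pan_nuclear_fraction Probability a nucleus carries pan-nuclear
#'   damage instead of discrete foci.
#' @param noise_sigma Standard deviation of additive Gaussian noise applied
#'   to the rendered damage channel (intensity units).
#' @param marker_intensity,foci_intensity,background_level Render intensities.
#' @param soft_foci Render foci with a Gaussian radial profile instead of
#'   hard disks; ground-truth area is then the half-maximum disk.
#' @param allow_overlap Allow nuclei to overlap (clump emulation).
#' @param seed Integer seed; scenes are bit-reproducible given the seed.
#' @param name Scene name, used as the `image_name` of its ground truth.
#' @return An object of class `synthetic_scene`.
#' @export
generate_scene <- function(n_nuclei,
                           image_shape = c(512L, 512L),
                           area_range = c(1000, 2500),
                           foci_count_range = c(0L, 12L),
                           foci_radius_range = c(2, 4),
                           pan_nuclear_fraction = 0,
                           noise_sigma = 0,
                           marker_intensity = 200L,
                           foci_intensity = 180L,
                           background_level = 10L,
                           soft_foci = FALSE,
                           allow_overlap = FALSE,
                           seed = 1L,
                           name = "scene") {
  stopifnot(length(image_shape) == 2, area_range[1] <= area_range[2],
            foci_count_range[1] <= foci_count_range[2],
            foci_radius_range[1] <= foci_radius_range[2])
  H <- image_shape[1]; W <- image_shape[2]
  with_seed(seed, {
    nuclei <- list(); foci <- list()
    centers <- matrix(numeric(0), 0, 2); radii <- numeric(0)
    for (i in seq_len(max(n_nuclei, 0L))) {
      placed <- FALSE
      for (attempt in seq_len(10000L)) {
        target <- runif(1, area_range[1], area_range[2])
        q <- runif(1, 0.6, 0.95)          # axis ratio b/a
        theta <- runif(1, 0, pi)
        b <- sqrt(target * q / pi); a <- b / q
        if (2 * (a + 3) >= min(H, W)) next
        cr <- runif(1, 1 + a + 2, H - a - 2)
        cc <- runif(1, 1 + a + 2, W - a - 2)
        if (!allow_overlap && nrow(centers) > 0) {
          d <- sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2)
          if (any(d <= a + radii + 2)) next
        }
        # rescale until the rasterized count lands inside the window
        ok <- FALSE
        for (it in seq_len(25L)) {
          px <- rasterize_ellipse(cr, cc, a, b, theta, image_shape)
          n_px <- nrow(px)
          if (n_px >= area_range[1] && n_px <= area_range[2]) { ok <- TRUE; break }
          if (n_px == 0) break
          s <- sqrt(mean(area_range) / n_px)
          a <- a * s; b <- b * s
          if (cr - a < 2 || cr + a > H - 1 || cc - a < 2 || cc + a > W - 1) break
        }
        if (!ok) next
        # re-validate after rescaling (the axes may have grown)
        if (min(px[, 1]) < 2 || max(px[, 1]) > H - 1 ||
            min(px[, 2]) < 2 || max(px[, 2]) > W - 1) next
        if (!allow_overlap && nrow(centers) > 0) {
          d <- sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2)
          if (any(d <= a + radii + 2)) next
        }
        centers <- rbind(centers, c(cr, cc)); radii <- c(radii, a)
        first_row <- min(px[, 1])
        first_col <- min(px[px[, 1] == first_row, 2])
        nuclei[[i]] <- tibble(
          center_row = cr, center_col = cc, semi_major = a, semi_minor = b,
          theta = theta, area_px = nrow(px),
          first_row = first_row, first_col = first_col,
          pan_nuclear = runif(1) < pan_nuclear_fraction
        )
        placed <- TRUE
        break
      }
      if (!placed) {
        abort(sprintf(
          "could not place %d disjoint nuclei in a %dx%d frame; use a larger frame",
          n_nuclei, H, W), class = "fociquant_placement_error")
      }
    }
    nuclei <- dplyr::bind_rows(nuclei)
    if (nrow(nuclei) > 0) {
      ord <- order(nuclei$first_row, nuclei$first_col)
      nuclei <- dplyr::mutate(nuclei[ord, ], nucleus_id = dplyr::row_number(),
                              .before = 1)
    } else {
      nuclei <- tibble(nucleus_id = integer(), center_row = numeric(),
                       center_col = numeric(), semi_major = numeric(),
                       semi_minor = numeric(), theta = numeric(),
                       area_px = integer(), first_row = integer(),
                       first_col = integer(), pan_nuclear = logical())
    }

    for (i in seq_len(nrow(nuclei))) {
      nuc <- nuclei[i, ]
      if (nuc$pan_nuclear) next
      n_target <- foci_count_range[1] +
        sample.int(foci_count_range[2] - foci_count_range[1] + 1L, 1L) - 1L
      if (n_target == 0) next
      npx <- rasterize_ellipse(nuc$center_row, nuc$center_col, nuc$semi_major,
                               nuc$semi_minor, nuc$theta, image_shape)
      member <- matrix(FALSE, H, W)
      member[npx] <- TRUE
      fc <- matrix(numeric(0), 0, 2); fr <- numeric(0)
      placed_foci <- list()
      for (j in seq_len(n_target)) {
        for (attempt in seq_len(2000L)) {
          radius <- runif(1, foci_radius_range[1], foci_radius_range[2])
          pick <- npx[sample.int(nrow(npx), 1L), ]
          dr <- pick[[1]]; dc <- pick[[2]]
          if (nrow(fc) > 0 &&
              any(sqrt((fc[, 1] - dr)^2 + (fc[, 2] - dc)^2) <= radius + fr + 4)) next
          dpx <- rasterize_disk(dr, dc, radius, image_shape)
          if (nrow(dpx) == 0 || !all(member[dpx])) next
          fc <- rbind(fc, c(dr, dc)); fr <- c(fr, radius)
          placed_foci[[length(placed_foci) + 1L]] <- tibble(
            nucleus_id = nuc$nucleus_id, focus_id = length(placed_foci) + 1L,
            row = dr, col = dc, radius = radius,
            intensity = as.numeric(foci_intensity), area_px = nrow(dpx))
          break
        }
        # attempts exhausted: the nucleus simply holds fewer foci
      }
      if (length(placed_foci)) foci[[length(foci) + 1L]] <- dplyr::bind_rows(placed_foci)
    }
    foci <- if (length(foci)) dplyr::bind_rows(foci) else
      tibble(nucleus_id = integer(), focus_id = integer(), row = numeric(),
             col = numeric(), radius = numeric(), intensity = numeric(),
             area_px = integer())

    structure(list(
      name = name, image_shape = as.integer(image_shape),
      nuclei = nuclei, foci = foci,
      marker_intensity = marker_intensity,
      foci_intensity = foci_intensity,
      background_level = background_level,
      noise_sigma = noise_sigma, soft_foci = soft_foci,
      pan_nuclear_fraction = pan_nuclear_fraction,
      area_range = area_range, seed = as.integer(seed)
    ), class = "synthetic_scene")
  })
}

#' Render a synthetic scene to an image pair
#'
#' The marker channel is the background level with each nucleus ellipse
#' filled at the marker intensity (noise-free by design: the marker stain is
#' the cleaner channel and keeping it exact makes nucleus-level ground truth
#' unambiguous). The damage channel is the background with focus disks (or a
#' whole-nucleus fill for pan-nuclear damage) plus seeded additive Gaussian
#' noise, rounded and clipped to `[0, 255]`.
#'
#' @param scene A `synthetic_scene`.
#' @return List with integer matrices `marker` and `damage`.
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  H <- scene$image_shape[1]; W <- scene$image_shape[2]
  bg <- scene$background_level
  marker <- matrix(as.numeric(bg), H, W)
  damage <- matrix(as.numeric(bg), H, W)
  for (i in seq_len(nrow(scene$nuclei))) {
    nuc <- scene$nuclei[i, ]
    px <- rasterize_ellipse(nuc$center_row, nuc$center_col, nuc$semi_major,
                            nuc$semi_minor, nuc$theta, scene$image_shape)
    marker[px] <- scene$marker_intensity
    if (nuc$pan_nuclear) damage[px] <- scene$foci_intensity
  }
  for (j in seq_len(nrow(scene$foci))) {
    f <- scene$foci[j, ]
    if (scene$soft_foci) {
      s <- f$radius / sqrt(2 * log(2))  # half-maximum at the nominal radius
      ext <- ceiling(3 * f$radius)
      r0 <- max(1L, f$row - ext); r1 <- min(H, f$row + ext)
      c0 <- max(1L, f$col - ext); c1 <- min(W, f$col + ext)
      rows <- r0:r1; cols <- c0:c1
      dy <- matrix(rows - f$row, length(rows), length(cols))
      dx <- matrix(cols - f$col, length(rows), length(cols), byrow = TRUE)
      prof <- bg + (f$intensity - bg) * exp(-(dy^2 + dx^2) / (2 * s^2))
      damage[rows, cols] <- pmax(damage[rows, cols], prof)
    } else {
      dpx <- rasterize_disk(f$row, f$col, f$radius, scene$image_shape)
      damage[dpx] <- f$intensity
    }
  }
  if (scene$noise_sigma > 0) {
    damage <- with_seed(scene$seed + 1L,
                        damage + rnorm(length(damage), 0, scene$noise_sigma))
  }
  clip8 <- function(m) {
    m <- round_half_up(m)
    m[m < 0] <- 0; m[m > 255] <- 255
    matrix(as.integer(m), H, W)
  }
  list(marker = clip8(marker), damage = clip8(damage))
}

#' Ground-truth quantification records of a scene
#'
#' The per-nucleus table a perfect detector would output: one row per
#' nucleus, in the same detection order (raster order of each nucleus's
#' first pixel) and with the same schema as the pipeline's quantification
#' table. A pan-nuclear nucleus counts as a single focus covering the whole
#' nucleus.
#'
#' @param scene A `synthetic_scene`.
#' @return Tibble with columns `image_name`, `nucleus_id`,
#'   `nucleus_area_px`, `foci_count`, `mean_foci_area_px`,
#'   `total_foci_area_px`.
#' @export
ground_truth_records <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (nrow(scene$nuclei) == 0) {
    return(tibble(image_name = character(), nucleus_id = integer(),
                  nucleus_area_px = integer(), foci_count = integer(),
                  mean_foci_area_px = numeric(), total_foci_area_px = numeric()))
  }
  agg <- dplyr::summarise(dplyr::group_by(scene$foci, .data$nucleus_id),
                          foci_count = dplyr::n(),
                          total_foci_area_px = sum(.data$area_px))
  rec <- dplyr::left_join(
    dplyr::transmute(scene$nuclei, nucleus_id = .data$nucleus_id,
                     nucleus_area_px = .data$area_px,
                     pan = .data$pan_nuclear),
    agg, by = "nucleus_id")
  rec <- dplyr::mutate(rec,
    foci_count = ifelse(.data$pan, 1L, dplyr::coalesce(.data$foci_count, 0L)),
    total_foci_area_px = ifelse(.data$pan, .data$nucleus_area_px,
                                dplyr::coalesce(.data$total_foci_area_px, 0)),
    mean_foci_area_px = ifelse(.data$foci_count > 0,
                               .data$total_foci_area_px / .data$foci_count, 0),
    image_name = scene$name)
  dplyr::select(rec, "image_name", "nucleus_id", "nucleus_area_px",
                "foci_count", "mean_foci_area_px", "total_foci_area_px")
}

#' Parameters matched to a synthetic scene
#'
#' The analysis parameters a user with full knowledge of the scene would
#' enter: the background level as the cut-off (the synthetic background is a
#' single flat intensity, so a higher cut-off would leave the Otsu stage
#' nothing to split), the nucleus area window used by the generator, and an
#' adaptive
#' threshold configured for compact-spot detection on a flat background
#' (`block_size = 15`, `c_offset = -25`: the local threshold sits 25
#' intensity units above the neighborhood mean, which rejects flat regions
#' and Gaussian noise up to roughly sigma 5 while keeping disk foci of the
#' generator's default contrast comfortably above threshold).
#'
#' @param scene A `synthetic_scene`.
#' @param foci_area_min Minimum focus area in pixels.
#' @param block_size,c_offset Adaptive-threshold settings.
#' @return An [analysis_params()] object.
#' @export
scene_params <- function(scene, foci_area_min = 1,
                         block_size = 15L, c_offset = -25) {
  stopifnot(inherits(scene, "synthetic_scene"))
  analysis_params(
    intensity_cutoff = scene$background_level,
    marker_area_min = scene$area_range[1],
    marker_area_max = scene$area_range[2],
    foci_area_min = foci_area_min,
    connectivity = 8L,
    block_size = block_size,
    c_offset = c_offset
  )
}

#' Simulate a ready-to-analyze folder pair
#'
#' Generates `n_images` seeded scenes, renders them, and writes
#' `out_dir/marker/` and `out_dir/damage/` (8-bit grayscale PNGs named
#' `img_001.png`, ...), the pooled `ground_truth.csv` with the
#' quantification schema, and `scene.json` recording every generator
#' parameter and per-scene seed.
#'
#' @param out_dir Output directory (must not already exist).
#' @param n_images Number of image pairs.
#' @param seed Base seed; scene `i` uses `seed + i - 1`.
#' @param ... Passed to [generate_scene()].
#' @return List with `scenes`, `ground_truth` and `out_dir`, invisibly.
#' @export
simulate_batch <- function(out_dir, n_images, seed = 1L, ...) {
  if (dir.exists(out_dir) || file.exists(out_dir)) {
    abort(paste0("output folder already exists: ", out_dir),
          class = "fociquant_invalid_output")
  }
  dir.create(file.path(out_dir, "marker"), recursive = TRUE)
  dir.create(file.path(out_dir, "damage"), recursive = TRUE)
  scenes <- vector("list", n_images)
  gts <- vector("list", n_images)
  args <- list(...)
  for (i in seq_len(n_images)) {
    nm <- sprintf("img_%03d.png", i)
    sc <- do.call(generate_scene,
                  c(list(seed = seed + i - 1L, name = nm), args))
    img <- render_scene(sc)
    write_gray_png(img$marker, file.path(out_dir, "marker", nm))
    write_gray_png(img$damage, file.path(out_dir, "damage", nm))
    scenes[[i]] <- sc
    gts[[i]] <- ground_truth_records(sc)
  }
  gt <- dplyr::bind_rows(gts)
  if (nrow(gt) == 0) {
    gt <- tibble(image_name = character(), nucleus_id = integer(),
                 nucleus_area_px = integer(), foci_count = integer(),
                 mean_foci_area_px = numeric(), total_foci_area_px = numeric())
  }
  readr::write_csv(gt, file.path(out_dir, "ground_truth.csv"))
  meta <- c(list(n_images = n_images, base_seed = seed,
                 scene_seeds = seed + seq_len(n_images) - 1L), args)
  jsonlite::write_json(meta, file.path(out_dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(scenes = scenes, ground_truth = gt, out_dir = out_dir))
}
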