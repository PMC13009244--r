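# End-to-end orchestration: configuration, per-sample run, gamma
# sensitivity harness, null-model report, and reproducible run manifests.

#' Default run configuration
#'
#' All stage parameters default to the workflow's stated operating values:
#' ratio epsilon 0.001, ratio threshold 0.4, gamma 0.75, 2x2 median
#' window, 100 px grid cells, proximity radii 10-100 px, 5000 randomized
#' null locations, 0.63 um pixels.
#'
#' @param brightfield,shg input image paths (PNG/TIFF); may be NULL when
#'   calling \code{run_sample} with in-memory images.
#' @param probe probe label (e.g. "37-42", "63-75").
#' @param out_dir output directory.
#' @param seed global seed; stage seeds derive from it.
#' @return nested list of class \code{cm_config}.
#' @export
default_config <- function(brightfield = NULL, shg = NULL,
                           probe = "probe", out_dir = "corrmap_out",
                           seed = 1L) {
  structure(list(
    inputs = list(brightfield = brightfield, shg = shg, probe = probe),
    out_dir = out_dir,
    seed = as.integer(seed),
    pixel_size_um = 0.63,
    dots = list(epsilon = 0.001, ratio_threshold = 0.4, min_area_px = 2,
                max_area_px = Inf, connectivity = 8),
    shg = list(gamma = 0.75, median_window = 2),
    segmentation = list(backend = "sauvola", min_path_px = 3),
    registration = list(enabled = TRUE, model = "rigid", metric = "ncc",
                        init_scale = 1),
    grid = list(cell_size_px = 100),
    proximity = list(radii_px = seq(10, 100, by = 10), n_random = 5000)
  ), class = "cm_config")
}

#' Read / write a run configuration (YAML)
#'
#' Serialization round-trips: parse(write(cfg)) equals cfg.
#'
#' @param path YAML file.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_in <- function(base, new) {
    for (k in names(new)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(new[[k]]))
        merge_in(base[[k]], new[[k]]) else new[[k]]
    }
    base
  }
  cfg <- merge_in(unclass(cfg), raw)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "cm_config"
  cfg
}

#' @rdname read_config
#' @param config a \code{cm_config}.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# fixed numeric formatting (9 significant digits) for byte-stable CSVs
.write_table <- function(df, path) {
  out <- df
  for (k in names(out)) {
    if (is.numeric(out[[k]]) && !is.integer(out[[k]]))
      out[[k]] <- formatC(out[[k]], digits = 9, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.stage_log <- function(stage, ...) {
  message(sprintf("[corrmap:%s] %s", stage, sprintf(...)))
}

#' Run the full per-sample workflow
#'
#' Detect transcript dots in the brightfield, preprocess and segment the
#' SHG image, register the brightfield onto the SHG frame, carry the dot
#' centroids across, aggregate on the macroscale grid, compute the
#' proximity profile and the randomized baseline, and write all tables
#' plus a JSON run manifest under \code{config$out_dir}.
#'
#' @param config a \code{cm_config}.
#' @param brightfield,shg optional in-memory images (RGB array / matrix,
#'   0-255) overriding the configured paths.
#' @param write_outputs write CSV/JSON outputs (default TRUE).
#' @return invisible list with every intermediate: dot_table, tissue_mask,
#'   fiber_table, transform, dots_shg (warped dot table), grid_table,
#'   corr_matrix, profile, normalized, null_profile, manifest.
#' @export
run_sample <- function(config, brightfield = NULL, shg = NULL,
                       write_outputs = TRUE) {
  stopifnot(inherits(config, "cm_config"))
  t0 <- Sys.time()
  if (is.null(brightfield)) {
    if (is.null(config$inputs$brightfield) ||
        !file.exists(config$inputs$brightfield))
      stop("brightfield image not found: ", config$inputs$brightfield)
    brightfield <- read_image_rgb(config$inputs$brightfield)
  }
  if (is.null(shg)) {
    if (is.null(config$inputs$shg) || !file.exists(config$inputs$shg))
      stop("SHG image not found: ", config$inputs$shg)
    shg <- read_image_gray(config$inputs$shg)
  }
  psz <- config$pixel_size_um

  .stage_log("dots", "detecting transcript dots")
  mask <- compute_tissue_mask(brightfield, pixel_size_um = psz)
  dp <- dot_params(epsilon = config$dots$epsilon,
                   ratio_threshold = config$dots$ratio_threshold,
                   min_area_px = config$dots$min_area_px,
                   max_area_px = config$dots$max_area_px,
                   connectivity = config$dots$connectivity)
  dot_table <- detect_dots(brightfield, dp, mask = mask)
  .stage_log("dots", "%d dots, tissue %.4f mm2", nrow(dot_table),
             mask$area_mm2)
  if (nrow(dot_table) == 0L) warning("no transcript dots detected")

  .stage_log("fibers", "segmenting collagen fibers (backend %s)",
             config$segmentation$backend)
  sp <- shg_params(gamma = config$shg$gamma,
                   median_window = config$shg$median_window,
                   pixel_size_um = psz)
  backend <- segmentation_backend(config$segmentation$backend)
  fiber_table <- extract_fibers(shg, sp, backend,
                                config$segmentation$min_path_px)
  .stage_log("fibers", "%d fibers", nrow(fiber_table))
  if (nrow(fiber_table) == 0L) warning("no collagen fibers segmented")

  if (isTRUE(config$registration$enabled)) {
    .stage_log("register", "registering brightfield onto SHG (%s)",
               config$registration$model)
    tfm <- register(brightfield, shg, model = config$registration$model,
                    options = list(metric = config$registration$metric,
                                   init_scale = config$registration$init_scale))
  } else {
    tfm <- transform_identity(dim(shg))
  }
  dots_shg <- dot_table
  if (nrow(dot_table)) {
    w <- warp_points(as.matrix(dot_table[, c("centroid_row",
                                             "centroid_col")]), tfm)
    dots_shg$centroid_row <- w[, 1]
    dots_shg$centroid_col <- w[, 2]
    oob <- attr(w, "out_of_bounds")
    if (!is.null(oob) && any(oob)) {
      .stage_log("register", "dropping %d dots mapped outside the SHG frame",
                 sum(oob))
      dots_shg <- dots_shg[!oob, , drop = FALSE]
    }
  }
  mask_shg <- warp_image(mask$mask * 1, tfm, "nearest",
                         output_shape = dim(shg)) > 0.5

  .stage_log("grid", "macroscale grid aggregation")
  maps <- list(
    length_um = make_property_map(fiber_table, "length_um", dim(shg)),
    orientation_rad = make_property_map(fiber_table, "orientation_rad",
                                        dim(shg)),
    tortuosity = make_property_map(fiber_table, "tortuosity", dim(shg)))
  gs <- grid_spec(config$grid$cell_size_px, dim(shg))
  grid_table <- grid_aggregate(maps, dots_shg, gs)
  corr <- correlation_matrix(grid_table)

  .stage_log("proximity", "proximity profile (%d radii)",
             length(config$proximity$radii_px))
  pp <- proximity_params(radii_px = config$proximity$radii_px,
                         pixel_size_um = psz,
                         n_random = config$proximity$n_random,
                         seed = config$seed)
  profile <- if (nrow(dots_shg)) proximity_profile(dots_shg, fiber_table, pp)
             else NULL
  normalized <- if (!is.null(profile) && !is.na(profile$mean_length_um[1]))
    normalize_profile(profile) else NULL

  .stage_log("null", "randomized baseline (n = %d)", pp$n_random)
  null_profile <- randomized_baseline(fiber_table, mask_shg, pp)

  manifest <- list(
    package_version = as.character(utils::packageVersion("corrmap")),
    probe = config$inputs$probe, seed = config$seed,
    pixel_size_um = psz,
    n_dots = nrow(dot_table), n_dots_in_shg_frame = nrow(dots_shg),
    n_fibers = nrow(fiber_table),
    tissue_area_mm2 = mask$area_mm2,
    dot_density_per_mm2 = if (mask$area_mm2 > 0)
      dot_density(dot_table, mask) else NA,
    fiber_density_per_mm2 = if (mask$area_mm2 > 0)
      fiber_density(fiber_table, mask$area_mm2) else NA,
    registration = list(model = tfm$model,
                        rotation_deg = transform_rotation(tfm) * 180 / pi,
                        translation_px = tfm$translation),
    config = unclass(config),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  result <- list(dot_table = dot_table, tissue_mask = mask,
                 tissue_mask_shg = mask_shg,
                 fiber_table = fiber_table, transform = tfm,
                 dots_shg = dots_shg, grid_table = grid_table,
                 corr_matrix = corr, profile = profile,
                 normalized = normalized, null_profile = null_profile,
                 manifest = manifest)
  if (write_outputs) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    .write_table(as.data.frame(dot_table), p("dots.csv"))
    ft <- as.data.frame(fiber_table); ft$path <- NULL
    .write_table(ft, p("fibers.csv"))
    .write_table(as.data.frame(dots_shg), p("dots_shg_frame.csv"))
    .write_table(as.data.frame(grid_table), p("grid.csv"))
    .write_table(as.data.frame(corr), p("correlation_matrix.csv"))
    if (!is.null(profile))
      .write_table(as.data.frame(profile), p("proximity.csv"))
    if (!is.null(normalized))
      .write_table(as.data.frame(normalized), p("proximity_normalized.csv"))
    .write_table(as.data.frame(null_profile), p("proximity_null.csv"))
    write_transform(tfm, p("transform.json"))
    manifest$config$dots$max_area_px <-
      if (is.infinite(manifest$config$dots$max_area_px)) "Inf"
      else manifest$config$dots$max_area_px
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(result)
}

#' Gamma sensitivity harness
#'
#' Re-runs SHG preprocessing, segmentation and fiber measurement for each
#' gamma and reports the per-gamma mean fiber length, fiber count, and the
#' cross-gamma spread - the stability check for the power-law
#' preprocessing step.
#'
#' @param shg raw SHG matrix (or path).
#' @param config a \code{cm_config}.
#' @param gammas gamma values (default 0.70, 0.75, 0.80).
#' @return data.frame: gamma, n_fibers, mean_length_um, mean_tortuosity;
#'   the spread (max - min of mean length) in attribute
#'   \code{"spread_um"}.
#' @export
run_gamma_sensitivity <- function(shg, config = default_config(),
                                  gammas = c(0.70, 0.75, 0.80)) {
  if (is.character(shg)) shg <- read_image_gray(shg)
  backend <- segmentation_backend(config$segmentation$backend)
  rows <- lapply(gammas, function(g) {
    sp <- shg_params(gamma = g, median_window = config$shg$median_window,
                     pixel_size_um = config$pixel_size_um)
    ft <- extract_fibers(shg, sp, backend, config$segmentation$min_path_px)
    data.frame(gamma = g, n_fibers = nrow(ft),
               mean_length_um = mean(ft$length_um),
               mean_tortuosity = mean(ft$tortuosity, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  attr(out, "spread_um") <- max(out$mean_length_um) - min(out$mean_length_um)
  out
}

#' Experimental-vs-baseline null model report
#'
#' Convenience wrapper producing side-by-side normalized profiles and the
#' slope comparison for a sample that has already been run (or in-memory
#' tables).
#'
#' @param result output of \code{run_sample} (or a list with
#'   \code{dots_shg}, \code{fiber_table}, and a tissue mask in the SHG
#'   frame under \code{tissue_mask_shg} or \code{tissue_mask}).
#' @param params a \code{cm_proximity_params}.
#' @return list: \code{experimental}, \code{baseline} (normalized
#'   profiles), \code{slope_experimental}, \code{slope_baseline},
#'   \code{comparison} (joined per-radius table).
#' @export
run_null_model <- function(result, params = proximity_params()) {
  mask <- result$tissue_mask_shg
  if (is.null(mask)) mask <- result$tissue_mask
  prof <- proximity_profile(result$dots_shg, result$fiber_table, params)
  null <- randomized_baseline(result$fiber_table, mask, params)
  ne <- normalize_profile(prof)
  nn <- normalize_profile(null)
  list(experimental = ne, baseline = nn,
       slope_experimental = profile_slope(ne),
       slope_baseline = profile_slope(nn),
       comparison = data.frame(radius_um = ne$radius_um,
                               experimental = ne$normalized,
                               baseline = nn$normalized))
}
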