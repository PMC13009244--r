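# Synthetic paired-scene generator with exact ground truth.
#
# Emulates the two modalities the pipeline consumes: a grayscale SHG image
# of curvilinear bright collagen fibers on a dark noisy background, and an
# RGB brightfield image of reddish low-green-ratio transcript dots on a
# hematoxylin-like stained-tissue background. Fiber paths are smooth
# biased-angle random walks rendered pixel by pixel, so every fiber metric
# has an exact path-based ground truth; dot and background colors are
# constrained so the chromatic-ratio classes are separated by construction.

# run expr with a private RNG state, restoring the caller's stream
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Fiber scene specification
#'
#' @param image_shape c(rows, cols) in pixels.
#' @param n_fibers number of fibers to place.
#' @param length_range curvilinear length range in micrometers, sampled
#'   uniformly (default 8-45 um, spanning short normal-muscle fibers to the
#'   long fibers of fibrotic tissue).
#' @param orientation_range fiber base orientations are drawn uniformly
#'   from this interval of [0, pi) (default the full interval).
#' @param tortuosity_target target path tortuosity (>= 1, default 1.15);
#'   controls the dispersion of the heading random walk via the worm-like
#'   chain relation. The recorded ground truth is always the realized
#'   path value, not the target.
#' @param fiber_intensity rendered skeleton intensity, 0-255 (default 180).
#' @param fiber_width_px rendered width, 1-3 px (default 2; use 1 for
#'   exact skeleton-identity experiments).
#' @param background_level,background_noise_sd background mean and Gaussian
#'   noise sd in intensity units (defaults 10 and 8).
#' @param min_separation_px minimum Chebyshev clearance between distinct
#'   fibers (default 2, so fibers never become 8-connected).
#' @param pixel_size_um um per pixel (default 0.63).
#' @param seed integer RNG seed.
#' @return list of class \code{cm_fiber_scene_spec}.
#' @export
fiber_scene_spec <- function(image_shape = c(256L, 256L), n_fibers = 30L,
                             length_range = c(8, 45),
                             orientation_range = c(0, pi),
                             tortuosity_target = 1.15,
                             fiber_intensity = 180, fiber_width_px = 2L,
                             background_level = 10, background_noise_sd = 8,
                             min_separation_px = 2L, pixel_size_um = 0.63,
                             seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 16),
            n_fibers >= 0, min(length_range) > 0,
            tortuosity_target >= 1, pixel_size_um > 0,
            fiber_width_px %in% 1:3, background_noise_sd >= 0)
  structure(list(image_shape = as.integer(image_shape),
                 n_fibers = as.integer(n_fibers),
                 length_range = as.numeric(length_range),
                 orientation_range = as.numeric(orientation_range),
                 tortuosity_target = tortuosity_target,
                 fiber_intensity = fiber_intensity,
                 fiber_width_px = as.integer(fiber_width_px),
                 background_level = background_level,
                 background_noise_sd = background_noise_sd,
                 min_separation_px = as.integer(min_separation_px),
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "cm_fiber_scene_spec")
}

# heading-walk dispersion for a target tortuosity, via the worm-like-chain
# end-to-end relation <R^2> = 2 Lp (L - Lp (1 - exp(-L/Lp))), Lp = 1/sigma^2
.sigma_for_tau <- function(tau, n_steps) {
  if (tau <= 1 + 1e-9) return(0)
  f <- function(sigma) {
    lp <- 1 / sigma^2
    r2 <- 2 * lp * (n_steps - lp * (1 - exp(-n_steps / lp)))
    n_steps / sqrt(r2) - tau
  }
  if (f(1.2) < 0) return(1.2)  # extremely tortuous: cap dispersion
  stats::uniroot(f, c(1e-4, 1.2), tol = 1e-6)$root
}

# grow one simple 8-connected pixel chain; returns n x 2 matrix (0-based)
# or NULL if the walk got stuck before reaching the minimum length
.grow_fiber_path <- function(shape, target_len_px, theta0, sigma, blocked) {
  nr <- shape[1]; nc <- shape[2]
  own <- matrix(FALSE, nr, nc)
  start <- c(stats::runif(1, 1, nr - 2), stats::runif(1, 1, nc - 2))
  p0 <- round(start)
  if (blocked[p0[1] + 1L, p0[2] + 1L]) return(NULL)
  path <- matrix(0L, nrow = ceiling(target_len_px) * 2L + 8L, ncol = 2L)
  path[1L, ] <- p0
  own[p0[1] + 1L, p0[2] + 1L] <- TRUE
  npix <- 1L
  pos <- start
  theta <- theta0
  len <- 0
  max_iter <- ceiling(target_len_px) * 6L + 40L
  for (it in seq_len(max_iter)) {
    placed <- FALSE
    for (try in 1:8) {
      th <- theta + stats::rnorm(1, 0, sigma)
      new_pos <- pos + c(sin(th), cos(th))
      cand <- round(new_pos)
      if (all(cand == path[npix, ])) { pos <- new_pos; theta <- th
                                       placed <- TRUE; break }
      if (cand[1] < 0 || cand[1] > nr - 1 || cand[2] < 0 || cand[2] > nc - 1)
        next
      if (blocked[cand[1] + 1L, cand[2] + 1L]) next
      # chain simplicity: among the candidate's 8 neighbors, the only own
      # pixel must be the current chain head (and candidate itself unused)
      if (own[cand[1] + 1L, cand[2] + 1L]) next
      rr <- max(cand[1], 1L):min(cand[1] + 2L, nr)
      cc <- max(cand[2], 1L):min(cand[2] + 2L, nc)
      if (sum(own[rr, cc]) != 1L) next
      d <- abs(cand - path[npix, ])
      if (max(d) != 1L) next
      npix <- npix + 1L
      path[npix, ] <- cand
      own[cand[1] + 1L, cand[2] + 1L] <- TRUE
      len <- len + if (sum(d) == 2L) sqrt(2) else 1
      pos <- new_pos; theta <- th
      placed <- TRUE
      break
    }
    if (!placed) break
    if (len >= target_len_px && npix >= 3L) break
  }
  if (len < target_len_px * 0.6 || npix < 3L) return(NULL)
  path[seq_len(npix), , drop = FALSE]
}

#' Generate a synthetic SHG fiber image with ground truth
#'
#' @param spec a \code{cm_fiber_scene_spec}.
#' @return list: \code{image} (matrix, 0-255), \code{fiber_table}
#'   (\code{cm_fiber_table} with the generating paths and their exact
#'   metrics), \code{spec}.
#' @export
generate_fiber_image <- function(spec = fiber_scene_spec()) {
  stopifnot(inherits(spec, "cm_fiber_scene_spec"))
  .with_seed(spec$seed, {
    nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
    blocked <- matrix(FALSE, nr, nc)
    paths <- vector("list", spec$n_fibers)
    placed <- 0L
    fails <- 0L
    max_fails <- 40L * max(spec$n_fibers, 1L)
    while (placed < spec$n_fibers) {
      len_um <- stats::runif(1, spec$length_range[1], spec$length_range[2])
      len_px <- len_um / spec$pixel_size_um
      th0 <- stats::runif(1, spec$orientation_range[1],
                          spec$orientation_range[2])
      if (stats::runif(1) < 0.5) th0 <- th0 + pi  # random direction sign
      sigma <- .sigma_for_tau(spec$tortuosity_target, ceiling(len_px))
      p <- .grow_fiber_path(spec$image_shape, len_px, th0, sigma, blocked)
      if (is.null(p)) {
        fails <- fails + 1L
        if (fails > max_fails)
          stop("fiber placement failure: image too small or too crowded ",
               "for the requested scene (placed ", placed, " of ",
               spec$n_fibers, ")")
        next
      }
      placed <- placed + 1L
      paths[[placed]] <- p
      # block a Chebyshev margin around the new fiber
      s <- spec$min_separation_px
      for (i in seq_len(nrow(p))) {
        rr <- max(p[i, 1] - s, 0L):min(p[i, 1] + s, nr - 1L)
        cc <- max(p[i, 2] - s, 0L):min(p[i, 2] + s, nc - 1L)
        blocked[rr + 1L, cc + 1L] <- TRUE
      }
    }
    img <- matrix(spec$background_level, nr, nc) +
      matrix(stats::rnorm(nr * nc, 0, spec$background_noise_sd), nr, nc)
    fiber_mask <- matrix(FALSE, nr, nc)
    for (p in paths[seq_len(placed)])
      fiber_mask[cbind(p[, 1] + 1L, p[, 2] + 1L)] <- TRUE
    if (spec$fiber_width_px == 2L) {
      fiber_mask <- fiber_mask | .shift_mat(fiber_mask, 1, 0, FALSE) |
        .shift_mat(fiber_mask, 0, 1, FALSE) | .shift_mat(fiber_mask, 1, 1, FALSE)
    } else if (spec$fiber_width_px == 3L) {
      acc <- fiber_mask
      for (dr in -1:1) for (dc in -1:1)
        acc <- acc | .shift_mat(fiber_mask, dr, dc, FALSE)
      fiber_mask <- acc
    }
    img[fiber_mask] <- spec$fiber_intensity +
      stats::rnorm(sum(fiber_mask), 0, spec$background_noise_sd / 2)
    img <- pmin(pmax(img, 0), 255)
    tab <- build_fiber_table(paths[seq_len(placed)], spec$pixel_size_um,
                             backend_id = "ground_truth")
    list(image = img, fiber_table = tab, spec = spec)
  })
}

#' Dot scene specification
#'
#' Default color models: dots R 100-160, G 10-40, B 20-60 (chromatic ratio
#' always below 0.4); background R 150-200, G 130-180, B 170-220
#' (hematoxylin-like), with G raised where needed so every background pixel
#' keeps its ratio at or above the detection threshold - the two ratio
#' classes are separated by construction.
#'
#' @param image_shape c(rows, cols).
#' @param n_dots number of dots.
#' @param dot_radius_range disc radius range in pixels, sampled uniformly
#'   as integers (default 2-4).
#' @param dot_color,background_color lists of per-channel integer ranges
#'   \code{list(R =, G =, B =)}.
#' @param tissue_shape "rect" (inset rectangle), "ellipse", or a logical
#'   matrix mask.
#' @param enrichment optional coupling rule: \code{list(fiber_table =,
#'   radius_px = 15, length_quantile = 0.5)} places dot centers only within
#'   \code{radius_px} of skeleton pixels of fibers whose length is at or
#'   above the given quantile.
#' @param ratio_threshold the detector threshold the color classes are
#'   separated against (default 0.4).
#' @param min_gap_px extra clearance between dot discs beyond the sum of
#'   radii (default 3, so discs never become 8-connected).
#' @param seed integer RNG seed.
#' @return list of class \code{cm_dot_scene_spec}.
#' @export
dot_scene_spec <- function(image_shape = c(256L, 256L), n_dots = 25L,
                           dot_radius_range = c(2L, 4L),
                           dot_color = list(R = c(100, 160), G = c(10, 40),
                                            B = c(20, 60)),
                           background_color = list(R = c(150, 200),
                                                   G = c(130, 180),
                                                   B = c(170, 220)),
                           tissue_shape = "rect", enrichment = NULL,
                           ratio_threshold = 0.4, min_gap_px = 3L,
                           seed = 1L) {
  stopifnot(length(image_shape) == 2L, n_dots >= 0,
            min(dot_radius_range) >= 1)
  structure(list(image_shape = as.integer(image_shape),
                 n_dots = as.integer(n_dots),
                 dot_radius_range = as.integer(dot_radius_range),
                 dot_color = dot_color, background_color = background_color,
                 tissue_shape = tissue_shape, enrichment = enrichment,
                 ratio_threshold = ratio_threshold,
                 min_gap_px = as.integer(min_gap_px),
                 seed = as.integer(seed)),
            class = "cm_dot_scene_spec")
}

.make_tissue_mask <- function(shape, tissue_shape) {
  nr <- shape[1]; nc <- shape[2]
  if (is.matrix(tissue_shape)) {
    stopifnot(all(dim(tissue_shape) == shape))
    return(tissue_shape != 0)
  }
  mr <- round(nr * 0.08); mc <- round(nc * 0.08)
  if (identical(tissue_shape, "rect")) {
    m <- matrix(FALSE, nr, nc)
    m[(mr + 1):(nr - mr), (mc + 1):(nc - mc)] <- TRUE
    m
  } else if (identical(tissue_shape, "ellipse")) {
    r <- matrix(0:(nr - 1), nr, nc)
    c_ <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
    ((r - (nr - 1) / 2) / ((nr - 1) / 2 - mr))^2 +
      ((c_ - (nc - 1) / 2) / ((nc - 1) / 2 - mc))^2 <= 1
  } else stop("unknown tissue_shape")
}

# sample channel values and clamp G so ratio = G/(R+B+eps) stays on the
# requested side of the threshold
.sample_colors <- function(n, model, side, thr, eps = 0.001) {
  R <- round(stats::runif(n, model$R[1], model$R[2]))
  G <- round(stats::runif(n, model$G[1], model$G[2]))
  B <- round(stats::runif(n, model$B[1], model$B[2]))
  if (side == "above") {            # background: ratio >= thr
    G <- pmax(G, ceiling(thr * (R + B + eps)) + 1)
  } else {                          # dots: ratio < thr
    G <- pmin(G, pmax(floor(thr * (R + B + eps)) - 1, 0))
  }
  cbind(R, G, B)
}

#' Generate a synthetic brightfield dot image with ground truth
#'
#' @param spec a \code{cm_dot_scene_spec}.
#' @return list: \code{image} (rows x cols x 3 array, 0-255),
#'   \code{dot_table} (\code{cm_dot_table} of exact centroids and areas),
#'   \code{tissue_mask} (logical matrix), \code{spec}.
#' @export
generate_brightfield_image <- function(spec = dot_scene_spec()) {
  stopifnot(inherits(spec, "cm_dot_scene_spec"))
  .with_seed(spec$seed, {
    nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
    mask <- .make_tissue_mask(spec$image_shape, spec$tissue_shape)
    img <- array(0, c(nr, nc, 3))
    # near-white slide background outside the tissue
    n_out <- sum(!mask)
    for (k in 1:3) {
      ch <- matrix(0, nr, nc)
      ch[!mask] <- round(stats::runif(n_out, 245, 255))
      img[, , k] <- ch
    }
    n_in <- sum(mask)
    bg <- .sample_colors(n_in, spec$background_color, "above",
                         spec$ratio_threshold)
    for (k in 1:3) {
      ch <- img[, , k]; ch[mask] <- bg[, k]; img[, , k] <- ch
    }
    # candidate centers
    cand <- mask
    if (!is.null(spec$enrichment)) {
      en <- spec$enrichment
      ft <- en$fiber_table
      rad <- if (is.null(en$radius_px)) 15L else as.integer(en$radius_px)
      q <- if (is.null(en$length_quantile)) 0.5 else en$length_quantile
      cutoff <- stats::quantile(ft$length_um, q)
      fm <- matrix(FALSE, nr, nc)
      for (i in which(ft$length_um >= cutoff)) {
        p <- ft$path[[i]]
        fm[cbind(p[, 1] + 1L, p[, 2] + 1L)] <- TRUE
      }
      brush <- EBImage::makeBrush(2L * rad + 1L, shape = "disc")
      fm <- matrix(as.numeric(
        EBImage::dilate(EBImage::Image(fm * 1), brush)) > 0.5, nr, nc)
      cand <- cand & fm
      if (!any(cand)) stop("enrichment rule leaves no placeable area")
    }
    cand_idx <- which(cand)
    centers <- matrix(0L, spec$n_dots, 2L)
    radii <- integer(spec$n_dots)
    placed <- 0L
    tries <- 0L
    max_tries <- 400L * max(spec$n_dots, 1L)
    disc_offsets <- function(r) {
      o <- expand.grid(dr = -r:r, dc = -r:r)
      o[o$dr^2 + o$dc^2 <= r^2, ]
    }
    # bucket placed centers so the clearance check stays O(1) per try
    rmax <- spec$dot_radius_range[2]
    cs <- 2L * rmax + spec$min_gap_px
    buckets <- new.env(hash = TRUE)
    while (placed < spec$n_dots) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("dot placement failure: requested dots exceed placeable area ",
             "(placed ", placed, " of ", spec$n_dots, ")")
      i <- cand_idx[sample.int(length(cand_idx), 1L)]
      cr <- (i - 1L) %% nr; cc <- (i - 1L) %/% nr   # 0-based center
      r <- if (spec$dot_radius_range[1] == spec$dot_radius_range[2])
        spec$dot_radius_range[1] else
        sample(spec$dot_radius_range[1]:spec$dot_radius_range[2], 1L)
      off <- disc_offsets(r)
      pr <- cr + off$dr; pc <- cc + off$dc
      if (min(pr) < 0 || max(pr) > nr - 1 || min(pc) < 0 || max(pc) > nc - 1)
        next
      if (!all(mask[cbind(pr + 1L, pc + 1L)])) next
      kb <- c(cr %/% cs, cc %/% cs)
      near <- integer(0)
      for (or_ in -1:1) for (oc in -1:1) {
        b <- buckets[[paste(kb[1] + or_, kb[2] + oc)]]
        if (!is.null(b)) near <- c(near, b)
      }
      if (length(near)) {
        dd <- sqrt((centers[near, 1] - cr)^2 + (centers[near, 2] - cc)^2)
        if (any(dd < radii[near] + r + spec$min_gap_px)) next
      }
      placed <- placed + 1L
      centers[placed, ] <- c(cr, cc)
      radii[placed] <- r
      bk <- paste(kb[1], kb[2])
      buckets[[bk]] <- c(buckets[[bk]], placed)
      cols <- .sample_colors(nrow(off), spec$dot_color, "below",
                             spec$ratio_threshold)
      for (k in 1:3) {
        ch <- img[, , k]
        ch[cbind(pr + 1L, pc + 1L)] <- cols[, k]
        img[, , k] <- ch
      }
    }
    areas <- vapply(radii[seq_len(placed)],
                    function(r) nrow(disc_offsets(r)), 0L)
    tab <- data.frame(id = seq_len(placed),
                      centroid_row = as.numeric(centers[seq_len(placed), 1]),
                      centroid_col = as.numeric(centers[seq_len(placed), 2]),
                      area_px = areas)
    class(tab) <- c("cm_dot_table", "data.frame")
    list(image = img, dot_table = tab, tissue_mask = mask, spec = spec)
  })
}

#' Generate a registered pair of synthetic modalities
#'
#' Renders the SHG fiber scene and the brightfield dot scene on a shared
#' grid, then (optionally) warps the brightfield by a known misalignment so
#' registration recovery can be validated. The applied transform follows
#' the package convention: it maps the delivered (misaligned) brightfield
#' coordinates into the SHG frame.
#'
#' @param fiber_spec a \code{cm_fiber_scene_spec}.
#' @param dot_spec a \code{cm_dot_scene_spec} with the same image_shape.
#' @param misalignment a \code{cm_transform} or NULL for identity.
#' @return list: \code{shg}, \code{brightfield} (as delivered, possibly
#'   misaligned), and \code{ground_truth} with \code{fiber_table},
#'   \code{dot_table} (SHG frame), \code{dot_table_moving} (delivered
#'   brightfield frame), \code{tissue_mask} (SHG frame),
#'   \code{applied_transform}.
#' @export
generate_paired_sample <- function(fiber_spec, dot_spec,
                                   misalignment = NULL) {
  if (!all(fiber_spec$image_shape == dot_spec$image_shape))
    stop("fiber and dot scenes must share image_shape")
  shg <- generate_fiber_image(fiber_spec)
  bf <- generate_brightfield_image(dot_spec)
  shape <- fiber_spec$image_shape
  if (is.null(misalignment)) misalignment <- transform_identity(shape)
  misalignment$fixed_shape <- shape
  misalignment$moving_shape <- shape
  identityish <- misalignment$model == "rigid" &&
    max(abs(misalignment$A - diag(2))) < 1e-12 &&
    max(abs(misalignment$translation)) < 1e-12
  if (identityish) {
    delivered <- bf$image
    dots_moving <- as.matrix(bf$dot_table[, c("centroid_row", "centroid_col")])
  } else {
    inv <- invert_transform(misalignment)
    delivered <- warp_image(bf$image, inv, "nearest", output_shape = shape,
                            fill = 250)
    dots_moving <- warp_points(
      as.matrix(bf$dot_table[, c("centroid_row", "centroid_col")]), inv)
  }
  dot_table_moving <- bf$dot_table
  dot_table_moving$centroid_row <- dots_moving[, 1]
  dot_table_moving$centroid_col <- dots_moving[, 2]
  list(shg = shg$image, brightfield = delivered,
       ground_truth = list(fiber_table = shg$fiber_table,
                           dot_table = bf$dot_table,
                           dot_table_moving = dot_table_moving,
                           tissue_mask = bf$tissue_mask,
                           applied_transform = misalignment),
       fiber_spec = fiber_spec, dot_spec = dot_spec)
}

#' Write a synthetic sample bundle to disk
#'
#' SHG as 8-bit grayscale TIFF, brightfield as RGB PNG, ground-truth tables
#' as CSV, and a JSON sidecar with seeds, specs and the applied transform.
#'
#' @param bundle output of \code{generate_paired_sample}.
#' @param dir destination directory (created if missing).
#' @export
write_sample_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(bundle$shg, file.path(dir, "shg.tif"))
  write_image(bundle$brightfield, file.path(dir, "brightfield.png"))
  gt <- bundle$ground_truth
  utils::write.csv(as.data.frame(gt$dot_table),
                   file.path(dir, "dots_truth.csv"), row.names = FALSE)
  ft <- as.data.frame(gt$fiber_table)
  ft$path <- NULL
  utils::write.csv(ft, file.path(dir, "fibers_truth.csv"), row.names = FALSE)
  tfm <- gt$applied_transform
  meta <- list(
    fiber_seed = bundle$fiber_spec$seed, dot_seed = bundle$dot_spec$seed,
    image_shape = bundle$fiber_spec$image_shape,
    pixel_size_um = bundle$fiber_spec$pixel_size_um,
    applied_transform = list(model = tfm$model, A = tfm$A,
                             translation = tfm$translation,
                             center = tfm$center))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
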