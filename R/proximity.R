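# Microscale proximity analysis: collagen fiber features within concentric
# circles centered on transcript dots, normalized decay profiles,
# isolated-dot fractions, and the randomized (complete spatial randomness)
# null model.

#' Proximity analysis parameters
#'
#' @param radii_px strictly increasing radii in pixels (default 10, 20,
#'   ..., 100; at 0.63 um/px these span about 6.3-63 um).
#' @param pixel_size_um um per pixel (default 0.63).
#' @param n_random number of randomized pseudo-dot locations for the null
#'   model (default 5000).
#' @param seed RNG seed for the null model.
#' @return list of class \code{cm_proximity_params}.
#' @export
proximity_params <- function(radii_px = seq(10, 100, by = 10),
                             pixel_size_um = 0.63, n_random = 5000L,
                             seed = 1L) {
  stopifnot(all(diff(radii_px) > 0), all(radii_px > 0), n_random >= 1,
            pixel_size_um > 0)
  structure(list(radii_px = as.numeric(radii_px),
                 pixel_size_um = pixel_size_um,
                 n_random = as.integer(n_random), seed = as.integer(seed)),
            class = "cm_proximity_params")
}

# minimum dot-to-fiber distances (n_dots x n_fibers). The "grid" method
# buckets skeleton pixels into square cells of side max_radius and only
# visits pixels in cells overlapping each dot's disc; distances beyond
# max_radius are reported as Inf. Contractually equal to brute force for
# every radius <= max_radius.
.min_dist_matrix <- function(dots, fiber_table, max_radius = Inf,
                             method = c("grid", "bruteforce")) {
  method <- match.arg(method)
  nd <- nrow(dots); nf <- nrow(fiber_table)
  out <- matrix(Inf, nd, nf)
  if (nd == 0L || nf == 0L) return(out)
  dr <- dots$centroid_row; dc <- dots$centroid_col
  px <- do.call(rbind, fiber_table$path)
  fid <- rep(seq_len(nf), times = vapply(fiber_table$path, nrow, 0L))
  if (method == "bruteforce" || !is.finite(max_radius)) {
    for (f in seq_len(nf)) {
      p <- fiber_table$path[[f]]
      d2min <- rep(Inf, nd)
      for (i in seq_len(nrow(p)))
        d2min <- pmin(d2min, (dr - p[i, 1])^2 + (dc - p[i, 2])^2)
      out[, f] <- sqrt(d2min)
    }
    return(out)
  }
  s <- max_radius
  kr <- floor(px[, 1] / s); kc <- floor(px[, 2] / s)
  key <- paste(kr, kc)
  buckets <- split(seq_len(nrow(px)), key)
  dkr <- floor(dr / s); dkc <- floor(dc / s)
  for (i in seq_len(nd)) {
    best <- rep(Inf, nf)
    for (or_ in -1:1) for (oc in -1:1) {
      b <- buckets[[paste(dkr[i] + or_, dkc[i] + oc)]]
      if (is.null(b)) next
      d2 <- (px[b, 1] - dr[i])^2 + (px[b, 2] - dc[i])^2
      mn <- tapply(d2, fid[b], min)
      ids <- as.integer(names(mn))
      best[ids] <- pmin(best[ids], mn)
    }
    best <- sqrt(best)
    best[best > max_radius] <- Inf
    out[i, ] <- best
  }
  out
}

#' Fibers within a radius of a dot
#'
#' A fiber is included if any of its skeleton pixels lies within
#' \code{radius_px} (Euclidean) of the dot centroid - i.e. the fiber lies
#' in the circular region partially or fully.
#'
#' @param dot numeric length-2 centroid (row, col) or one-row dot table.
#' @param fiber_table a \code{cm_fiber_table} in the same frame.
#' @param radius_px radius in pixels.
#' @param method "grid" (bucketed spatial index, default) or "bruteforce";
#'   the two are contractually identical.
#' @return integer vector of included fiber ids.
#' @export
fibers_within_radius <- function(dot, fiber_table, radius_px,
                                 method = c("grid", "bruteforce")) {
  if (is.data.frame(dot))
    dot <- c(dot$centroid_row[1], dot$centroid_col[1])
  dots <- data.frame(centroid_row = dot[1], centroid_col = dot[2])
  d <- .min_dist_matrix(dots, fiber_table, max_radius = radius_px,
                        method = match.arg(method))
  fiber_table$id[which(d[1, ] <= radius_px)]
}

#' Proximity profile of collagen features around transcript dots
#'
#' For every dot and radius, fibers with any skeleton pixel inside the
#' circle contribute once (unweighted) to the dot's per-radius feature
#' means; dots with no fiber in the circle are excluded from feature means
#' at that radius and counted in the isolated fraction instead. Dot-level
#' means are then averaged across dots, with SEM = sd across contributing
#' dots / sqrt(n). Orientation uses the axial circular mean at both levels.
#'
#' @param dot_table a \code{cm_dot_table} (>= 1 dot), SHG frame.
#' @param fiber_table a \code{cm_fiber_table}, SHG frame.
#' @param params a \code{cm_proximity_params}.
#' @param method distance method, see \code{fibers_within_radius}.
#' @return data.frame of class \code{cm_proximity_profile}, one row per
#'   radius: radius_px, radius_um, mean_fiber_count, mean_length_um,
#'   sem_length_um, mean_orientation_rad, sem_orientation_rad,
#'   mean_tortuosity, sem_tortuosity, isolated_fraction,
#'   n_dots_contributing.
#' @export
proximity_profile <- function(dot_table, fiber_table,
                              params = proximity_params(),
                              method = c("grid", "bruteforce")) {
  if (nrow(dot_table) == 0L) stop("proximity profile requires >= 1 dot")
  radii <- params$radii_px
  nd <- nrow(dot_table)
  dmat <- .min_dist_matrix(dot_table, fiber_table,
                           max_radius = max(radii),
                           method = match.arg(method))
  res <- lapply(radii, function(r) {
    inc <- dmat <= r                       # nd x nf inclusion
    cnt <- rowSums(inc)
    contributing <- cnt > 0
    n <- sum(contributing)
    per_dot <- function(values, circular = FALSE) {
      if (n == 0L) return(c(NA_real_, NA_real_))
      v <- vapply(which(contributing), function(i) {
        vals <- values[inc[i, ]]
        vals <- vals[!is.na(vals)]
        if (!length(vals)) return(NA_real_)
        if (circular) .axial_mean(vals) else mean(vals)
      }, 0)
      v <- v[!is.na(v)]
      if (!length(v)) return(c(NA_real_, NA_real_))
      if (circular) c(.axial_mean(v), .axial_sem(v))
      else c(mean(v), if (length(v) > 1) stats::sd(v) / sqrt(length(v))
             else NA_real_)
    }
    len <- per_dot(fiber_table$length_um)
    ori <- per_dot(fiber_table$orientation_rad, circular = TRUE)
    tor <- per_dot(fiber_table$tortuosity)
    data.frame(radius_px = r, radius_um = r * params$pixel_size_um,
               mean_fiber_count = mean(cnt),
               mean_length_um = len[1], sem_length_um = len[2],
               mean_orientation_rad = ori[1], sem_orientation_rad = ori[2],
               mean_tortuosity = tor[1], sem_tortuosity = tor[2],
               isolated_fraction = 1 - n / nd,
               n_dots_contributing = n)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "params") <- params
  attr(out, "n_dots") <- nd
  class(out) <- c("cm_proximity_profile", "data.frame")
  out
}

#' Normalize a proximity profile to its smallest radius
#'
#' Divides the chosen feature by its value at the smallest radius (the
#' profile maximum in decaying profiles) and fits an ordinary least-squares
#' slope of the normalized values against radius in micrometers.
#'
#' @param profile a \code{cm_proximity_profile}.
#' @param feature column to normalize (default "mean_length_um").
#' @return data.frame of class \code{cm_normalized_profile} with columns
#'   radius_px, radius_um, value, normalized; the slope (per um) and the
#'   reference value are attributes.
#' @export
normalize_profile <- function(profile, feature = "mean_length_um") {
  v <- profile[[feature]]
  if (is.null(v)) stop("unknown feature: ", feature)
  ref <- v[1]
  if (is.na(ref)) stop("feature undefined at the smallest radius; ",
                       "cannot normalize")
  out <- data.frame(radius_px = profile$radius_px,
                    radius_um = profile$radius_um,
                    value = v, normalized = v / ref)
  fit_ok <- !is.na(out$normalized)
  slope <- if (sum(fit_ok) >= 2)
    unname(stats::coef(stats::lm(normalized ~ radius_um,
                                 data = out[fit_ok, ]))[2])
  else NA_real_
  attr(out, "slope_per_um") <- slope
  attr(out, "reference_value") <- ref
  attr(out, "feature") <- feature
  class(out) <- c("cm_normalized_profile", "data.frame")
  out
}

#' Slope of a normalized profile
#' @param normalized a \code{cm_normalized_profile}.
#' @export
profile_slope <- function(normalized) attr(normalized, "slope_per_um")

#' Randomized-baseline proximity profile (null model)
#'
#' Samples pseudo-dot locations uniformly from the tissue-mask pixels
#' (complete spatial randomness on the tissue support) with a fixed seed
#' and recomputes the full proximity profile on them, exposing the purely
#' geometric component of any observed proximity trend.
#'
#' @param fiber_table a \code{cm_fiber_table}, SHG frame.
#' @param tissue_mask logical matrix or \code{cm_tissue_mask}.
#' @param params a \code{cm_proximity_params}; \code{n_random} and
#'   \code{seed} control the randomization.
#' @param method distance method.
#' @return a \code{cm_proximity_profile} for the randomized dots.
#' @export
randomized_baseline <- function(fiber_table, tissue_mask,
                                params = proximity_params(),
                                method = c("grid", "bruteforce")) {
  m <- if (inherits(tissue_mask, "cm_tissue_mask")) tissue_mask$mask
       else tissue_mask != 0
  idx <- which(m)
  if (length(idx) == 0L) stop("empty tissue mask: null model undefined")
  nr <- nrow(m)
  pick <- .with_seed(params$seed,
                     idx[sample.int(length(idx), params$n_random,
                                    replace = TRUE)])
  pseudo <- data.frame(id = seq_along(pick),
                       centroid_row = as.numeric((pick - 1L) %% nr),
                       centroid_col = as.numeric((pick - 1L) %/% nr),
                       area_px = 1L)
  class(pseudo) <- c("cm_dot_table", "data.frame")
  proximity_profile(pseudo, fiber_table, params, method = method)
}

#' Compare two proximity profiles
#'
#' Per-radius differences (a minus b) of the isolated fraction and of the
#' normalized feature values, with SEMs propagated in quadrature.
#'
#' @param profile_a,profile_b \code{cm_proximity_profile}s on identical
#'   radii.
#' @param feature feature to normalize and difference.
#' @return data.frame: radius_px, radius_um, d_normalized,
#'   d_isolated_fraction, sem_quadrature.
#' @export
compare_probes <- function(profile_a, profile_b,
                           feature = "mean_length_um") {
  if (!isTRUE(all.equal(profile_a$radius_px, profile_b$radius_px)))
    stop("profiles must share identical radii")
  na <- normalize_profile(profile_a, feature)
  nb <- normalize_profile(profile_b, feature)
  sem_col <- sub("^mean_", "sem_", feature)
  sa <- profile_a[[sem_col]] / attr(na, "reference_value")
  sb <- profile_b[[sem_col]] / attr(nb, "reference_value")
  data.frame(radius_px = profile_a$radius_px,
             radius_um = profile_a$radius_um,
             d_normalized = na$normalized - nb$normalized,
             d_isolated_fraction = profile_a$isolated_fraction -
               profile_b$isolated_fraction,
             sem_quadrature = sqrt(sa^2 + sb^2))
}

#' @export
print.cm_proximity_profile <- function(x, ...) {
  cat(sprintf("<cm_proximity_profile: %d radii, %d dots>\n", nrow(x),
              attr(x, "n_dots")))
  print(utils::head(as.data.frame(x), nrow(x)), ...)
  invisible(x)
}

#' Plot a proximity profile
#'
#' Mean feature value against radius in micrometers with SEM error bars.
#'
#' @param x a \code{cm_proximity_profile}.
#' @param feature column to draw.
#' @export
plot.cm_proximity_profile <- function(x, feature = "mean_length_um", ...) {
  v <- x[[feature]]
  sem <- x[[sub("^mean_", "sem_", feature)]]
  graphics::plot(x$radius_um, v, type = "b", pch = 16,
                 xlab = "radius (um)", ylab = feature, ...)
  if (!is.null(sem)) {
    ok <- !is.na(sem)
    graphics::arrows(x$radius_um[ok], (v - sem)[ok], x$radius_um[ok],
                     (v + sem)[ok], angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}
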