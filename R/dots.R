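# Transcript dot detection in brightfield RGB images by chromatic-ratio
# thresholding: chromogenic RNAscope dots are reddish, so their green share
# G / (R + B) is low compared with the surrounding stained tissue.

#' Dot detection parameters
#'
#' @param epsilon small constant added to the ratio denominator to avoid
#'   division by zero (default 0.001).
#' @param ratio_threshold pixels with ratio below this are candidate dot
#'   pixels (default 0.4).
#' @param min_area_px minimum component area kept (default 2; suppresses
#'   isolated dark specks).
#' @param max_area_px optional maximum component area (default Inf).
#' @param connectivity component connectivity, 4 or 8 (default 8).
#' @param max_eccentricity optional circularity guard: components whose
#'   pixel-covariance eccentricity exceeds this are dropped. Off (Inf) by
#'   default - no shape filter is part of the core detection rule.
#' @return list of class \code{cm_dot_params}.
#' @export
dot_params <- function(epsilon = 0.001, ratio_threshold = 0.4,
                       min_area_px = 2L, max_area_px = Inf,
                       connectivity = 8L, max_eccentricity = Inf) {
  stopifnot(epsilon > 0, ratio_threshold > 0, ratio_threshold < 1,
            min_area_px >= 1, connectivity %in% c(4, 8))
  structure(list(epsilon = epsilon, ratio_threshold = ratio_threshold,
                 min_area_px = as.integer(min_area_px),
                 max_area_px = max_area_px,
                 connectivity = as.integer(connectivity),
                 max_eccentricity = max_eccentricity),
            class = "cm_dot_params")
}

#' Chromatic ratio map
#'
#' Per-pixel \code{G / (R + B + epsilon)}; finite everywhere by virtue of
#' the epsilon term.
#'
#' @param rgb rows x cols x 3 array, channel order R, G, B.
#' @param epsilon denominator guard (default 0.001).
#' @return matrix of ratio values.
#' @export
compute_ratio_map <- function(rgb, epsilon = 0.001) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("ratio map requires a 3-channel RGB image")
  if (min(rgb) < 0) stop("negative channel values")
  out <- rgb[, , 2] / (rgb[, , 1] + rgb[, , 3] + epsilon)
  matrix(out, dim(rgb)[1], dim(rgb)[2])
}

#' Detect transcript dots
#'
#' Thresholds the chromatic ratio map (ratio < threshold = candidate dot
#' pixel), labels connected components at the configured connectivity,
#' discards components below the minimum area, and records each surviving
#' component's unweighted mean-position centroid and pixel-count area.
#' Perfectly black pixels have ratio 0, so detection should normally be
#' restricted to the tissue via \code{mask}.
#'
#' @param rgb rows x cols x 3 array, 0-255.
#' @param params a \code{cm_dot_params}.
#' @param mask optional logical matrix restricting detection to tissue
#'   pixels (a \code{cm_tissue_mask} is accepted).
#' @return data.frame of class \code{cm_dot_table}: id, centroid_row,
#'   centroid_col (0-based, sub-pixel), area_px; parameters echoed in
#'   attributes.
#' @export
detect_dots <- function(rgb, params = dot_params(), mask = NULL) {
  ratio <- compute_ratio_map(rgb, params$epsilon)
  cand <- ratio < params$ratio_threshold
  if (!is.null(mask)) {
    m <- if (inherits(mask, "cm_tissue_mask")) mask$mask else mask
    stopifnot(all(dim(m) == dim(cand)))
    cand <- cand & (m != 0)
  }
  lab <- label_components(cand, params$connectivity)
  tab <- .components_to_table(lab)
  keep <- tab$area_px >= params$min_area_px & tab$area_px <= params$max_area_px
  if (is.finite(params$max_eccentricity) && nrow(tab)) {
    ecc <- .component_eccentricity(lab, tab$id)
    keep <- keep & ecc <= params$max_eccentricity
  }
  tab <- tab[keep, , drop = FALSE]
  tab$id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "params") <- params
  class(tab) <- c("cm_dot_table", "data.frame")
  tab
}

.components_to_table <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0L)
    return(data.frame(id = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), area_px = integer()))
  nr <- nrow(lab)
  l <- lab[idx]
  r <- (idx - 1L) %% nr       # 0-based rows
  c_ <- (idx - 1L) %/% nr     # 0-based cols
  area <- tabulate(l)
  data.frame(
    id = seq_along(area),
    centroid_row = as.numeric(rowsum(r, l) / area),
    centroid_col = as.numeric(rowsum(c_, l) / area),
    area_px = as.integer(area)
  )
}

# eccentricity of each component from its pixel covariance
.component_eccentricity <- function(lab, ids) {
  idx <- which(lab > 0)
  nr <- nrow(lab)
  l <- lab[idx]
  r <- (idx - 1L) %% nr; c_ <- (idx - 1L) %/% nr
  vapply(ids, function(i) {
    rr <- r[l == i]; cc <- c_[l == i]
    if (length(rr) < 3L) return(0)
    ev <- eigen(stats::cov(cbind(rr, cc)), only.values = TRUE)$values
    if (ev[1] <= 0) return(0)
    sqrt(1 - pmax(ev[2], 0) / ev[1])
  }, 0)
}

#' Compute a tissue mask from a brightfield image
#'
#' Tissue is darker than the near-white slide background: pixels whose
#' luminance falls below an Otsu threshold are tissue, followed by
#' morphological closing (disc radius 5) and hole filling. The physical
#' area follows from the pixel count and pixel size.
#'
#' @param rgb rows x cols x 3 array, 0-255.
#' @param pixel_size_um um per pixel (default 0.63).
#' @param closing_radius radius of the closing disc in pixels (default 5).
#' @return list of class \code{cm_tissue_mask}: \code{mask} (logical
#'   matrix), \code{area_mm2}, \code{pixel_size_um}.
#' @export
compute_tissue_mask <- function(rgb, pixel_size_um = 0.63,
                                closing_radius = 5L) {
  lum <- luminance(rgb)
  if (diff(range(lum)) < 1e-9) {
    mask <- matrix(FALSE, nrow(lum), ncol(lum))
  } else {
    thr <- otsu_threshold(lum)
    mask <- lum < thr
    if (any(mask) && closing_radius >= 1) {
      brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L,
                                  shape = "disc")
      m <- EBImage::closing(EBImage::Image(mask * 1), brush)
      m <- EBImage::fillHull(m)
      mask <- matrix(as.numeric(m) > 0.5, nrow(lum), ncol(lum))
    }
  }
  if (!any(mask)) warning("tissue mask is empty")
  structure(list(mask = mask,
                 area_mm2 = sum(mask) * pixel_size_um^2 * 1e-6,
                 pixel_size_um = pixel_size_um),
            class = "cm_tissue_mask")
}

#' Dot density per square millimeter
#'
#' @param dots a \code{cm_dot_table}.
#' @param mask a \code{cm_tissue_mask} (or a number, the area in mm^2).
#' @return dots per mm^2.
#' @export
dot_density <- function(dots, mask) {
  area <- if (inherits(mask, "cm_tissue_mask")) mask$area_mm2 else mask
  if (!is.numeric(area) || area <= 0)
    stop("dot density undefined for zero-area tissue mask")
  nrow(dots) / area
}

#' @export
print.cm_dot_table <- function(x, ...) {
  cat(sprintf("<cm_dot_table: %d dots>\n", nrow(x)))
  if (nrow(x)) print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
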