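# Macroscale analysis: aggregate registered dot and fiber data on a
# uniform grid of square cells and correlate the per-cell features with a
# Spearman matrix.

#' Grid specification
#'
#' @param cell_size_px side of the square cells in pixels (default 100).
#' @param image_shape c(rows, cols) of the SHG frame being tiled; partial
#'   edge cells are kept and flagged.
#' @param include_partial keep partial edge cells (default TRUE).
#' @return list of class \code{cm_grid_spec}.
#' @export
grid_spec <- function(cell_size_px = 100L, image_shape,
                      include_partial = TRUE) {
  stopifnot(cell_size_px >= 1, length(image_shape) == 2L)
  structure(list(cell_size_px = as.integer(cell_size_px),
                 image_shape = as.integer(image_shape),
                 include_partial = isTRUE(include_partial)),
            class = "cm_grid_spec")
}

#' Aggregate property maps and dots on a grid
#'
#' Per cell: the mean of the non-sentinel property-map pixels falling in
#' the cell (pixel-weighted, since the maps carry per-pixel fiber values),
#' and the number of dot centroids whose coordinates fall in the half-open
#' cell interval \code{[k*s, (k+1)*s)}. Orientation is averaged with the
#' axial circular mean (angles doubled, averaged, halved) and reported in
#' [0, pi). Cells without skeleton pixels have their feature means flagged
#' invalid (NA), never zero-filled; dot counts are defined everywhere.
#'
#' @param property_maps named list of matrices from
#'   \code{make_property_map}; names among "length_um", "orientation_rad",
#'   "tortuosity".
#' @param dot_table a \code{cm_dot_table} in the same (SHG) frame.
#' @param grid a \code{cm_grid_spec}.
#' @return data.frame of class \code{cm_grid_table}: cell_row, cell_col,
#'   mean_length_um, mean_orientation_rad, mean_tortuosity, dot_count,
#'   n_skeleton_px, partial.
#' @export
grid_aggregate <- function(property_maps, dot_table, grid) {
  stopifnot(inherits(grid, "cm_grid_spec"))
  shp <- grid$image_shape
  for (m in property_maps)
    if (!all(dim(m) == shp))
      stop("property map shape does not match grid image_shape")
  s <- grid$cell_size_px
  ncr <- ceiling(shp[1] / s); ncc <- ceiling(shp[2] / s)
  cells <- expand.grid(cell_row = 0:(ncr - 1), cell_col = 0:(ncc - 1))
  cell_id <- cells$cell_row + cells$cell_col * ncr + 1L

  # per-pixel cell assignment (matrix layout is column-major, rows vary
  # fastest, matching expand.grid above)
  pr <- rep(0:(shp[1] - 1), times = shp[2])
  pc <- rep(0:(shp[2] - 1), each = shp[1])
  pcell <- (pr %/% s) + (pc %/% s) * ncr + 1L

  out <- cells
  agg_mean <- function(map) {
    v <- as.vector(map)
    ok <- !is.na(v)
    if (!any(ok)) return(rep(NA_real_, nrow(cells)))
    m <- rep(NA_real_, nrow(cells))
    sums <- rowsum(v[ok], pcell[ok])
    cnts <- rowsum(rep(1, sum(ok)), pcell[ok])
    m[as.integer(rownames(sums))] <- sums / cnts
    m
  }
  out$mean_length_um <- if (!is.null(property_maps$length_um))
    agg_mean(property_maps$length_um) else NA_real_
  if (!is.null(property_maps$orientation_rad)) {
    v <- as.vector(property_maps$orientation_rad)
    ok <- !is.na(v)
    m <- rep(NA_real_, nrow(cells))
    if (any(ok)) {
      sn <- rowsum(sin(2 * v[ok]), pcell[ok])
      cs <- rowsum(cos(2 * v[ok]), pcell[ok])
      m[as.integer(rownames(sn))] <- (atan2(sn, cs) / 2) %% pi
    }
    out$mean_orientation_rad <- m
  } else out$mean_orientation_rad <- NA_real_
  out$mean_tortuosity <- if (!is.null(property_maps$tortuosity))
    agg_mean(property_maps$tortuosity) else NA_real_

  skel_px <- rep(0L, nrow(cells))
  if (!is.null(property_maps[[1]])) {
    ok <- !is.na(as.vector(property_maps[[1]]))
    if (any(ok)) {
      cnt <- rowsum(rep(1L, sum(ok)), pcell[ok])
      skel_px[as.integer(rownames(cnt))] <- as.integer(cnt)
    }
  }
  out$n_skeleton_px <- skel_px

  dcount <- rep(0L, nrow(cells))
  if (nrow(dot_table)) {
    dr <- dot_table$centroid_row; dc <- dot_table$centroid_col
    inside <- dr >= 0 & dr < shp[1] & dc >= 0 & dc < shp[2]
    dcell <- (floor(dr[inside]) %/% s) + (floor(dc[inside]) %/% s) * ncr + 1L
    tb <- table(dcell)
    dcount[as.integer(names(tb))] <- as.integer(tb)
  }
  out$dot_count <- dcount
  out$partial <- (cells$cell_row + 1) * s > shp[1] |
                 (cells$cell_col + 1) * s > shp[2]
  if (!grid$include_partial) out <- out[!out$partial, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "grid") <- grid
  class(out) <- c("cm_grid_table", "data.frame")
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties); the standard
#' implementation via \code{stats::cor}.
#'
#' @param x,y paired numeric vectors; pairs with any NA are dropped.
#' @return rho in [-1, 1], or NA (flagged undefined) with fewer than 3
#'   complete pairs or zero rank variance.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Cross-feature Spearman correlation matrix
#'
#' Symmetric 4x4 matrix over \{mean length, mean orientation, mean
#' tortuosity, dot count\}, each entry computed on the cells where both
#' features are valid (pairwise-complete). Feature means are undefined in
#' fiber-free cells and those cells drop out of entries involving them;
#' dot counts are zero-filled over the grid extent.
#'
#' @param grid_table a \code{cm_grid_table}.
#' @return 4x4 numeric matrix with unit diagonal; entries with fewer than
#'   3 jointly valid cells are NA.
#' @export
correlation_matrix <- function(grid_table) {
  feats <- list(length = grid_table$mean_length_um,
                orientation = grid_table$mean_orientation_rad,
                tortuosity = grid_table$mean_tortuosity,
                dot_count = as.numeric(grid_table$dot_count))
  k <- length(feats)
  m <- matrix(NA_real_, k, k, dimnames = list(names(feats), names(feats)))
  diag(m) <- 1
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    m[i, j] <- m[j, i] <- spearman_rho(feats[[i]], feats[[j]])
  }
  m
}

#' @export
print.cm_grid_table <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<cm_grid_table: %d cells of %d px>\n", nrow(x),
              g$cell_size_px))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Render grid feature heatmaps
#'
#' Simple image() heatmaps of the per-cell features, mirroring the usual
#' macroscale panel layout.
#'
#' @param grid_table a \code{cm_grid_table}.
#' @param features which columns to draw.
#' @export
plot.cm_grid_table <- function(x, features = c("mean_length_um",
                                               "mean_orientation_rad",
                                               "mean_tortuosity",
                                               "dot_count"), ...) {
  nr <- max(x$cell_row) + 1L; nc <- max(x$cell_col) + 1L
  old <- graphics::par(mfrow = c(2, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(old))
  for (f in features) {
    m <- matrix(NA_real_, nr, nc)
    m[cbind(x$cell_row + 1L, x$cell_col + 1L)] <- as.numeric(x[[f]])
    graphics::image(t(m)[, nr:1, drop = FALSE], main = f, axes = FALSE,
                    col = grDevices::hcl.colors(64, "viridis"), ...)
  }
  invisible(x)
}
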