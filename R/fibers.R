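# SHG preprocessing, fiber segmentation/skeletonization, and the three
# per-fiber morphometrics: length, orientation, tortuosity.

#' SHG preprocessing parameters
#'
#' @param gamma power-law exponent applied to [0,1]-normalized intensities
#'   (default 0.75).
#' @param median_window side of the square median window in pixels
#'   (default 2, i.e. a 2x2 window).
#' @param pixel_size_um physical pixel size (default 0.63 um/px).
#' @return list of class \code{cm_shg_params}.
#' @export
shg_params <- function(gamma = 0.75, median_window = 2L,
                       pixel_size_um = 0.63) {
  stopifnot(gamma > 0, median_window >= 1, pixel_size_um > 0)
  structure(list(gamma = gamma, median_window = as.integer(median_window),
                 pixel_size_um = pixel_size_um), class = "cm_shg_params")
}

#' Preprocess an SHG image
#'
#' Normalizes 8-bit intensities to [0, 1], applies the gamma correction
#' \code{x^gamma}, median-filters with the configured window, and rescales
#' back to 0-255.
#'
#' @param img grayscale matrix, 0-255.
#' @param params a \code{cm_shg_params}.
#' @return preprocessed matrix, 0-255.
#' @export
preprocess_shg <- function(img, params = shg_params()) {
  if (!is.matrix(img)) stop("SHG input must be a 2D grayscale matrix")
  x <- pmin(pmax(img / 255, 0), 1)
  x <- x^params$gamma
  x <- median_filter2(x, params$median_window)
  x * 255
}

# ---- segmentation backends -------------------------------------------------
#
# A backend turns a preprocessed SHG image into a binary skeleton mask. The
# deep-learning segmenter used in the original workflow is one possible
# backend; the package ships two classical ones behind the same interface:
#   "sauvola"  - adaptive Sauvola threshold (with a global Otsu floor to
#                suppress noise-only regions) -> Zhang-Suen skeleton
#   "identity" - treats bright pixels as an already-1px-wide skeleton;
#                used with synthetically rendered skeletons and for
#                plugging in precomputed segmentations

#' Segmentation backend registry
#'
#' @param name backend id, or a function \code{(img) -> logical skeleton
#'   mask} for custom backends.
#' @param ... backend options: \code{window}, \code{k} (sauvola);
#'   \code{threshold} (identity; default half the image maximum).
#' @return function of class \code{cm_backend}.
#' @export
segmentation_backend <- function(name = c("sauvola", "identity"), ...) {
  if (is.function(name)) {
    f <- name
    attr(f, "backend_id") <- "custom"
    class(f) <- c("cm_backend", class(f))
    return(f)
  }
  name <- match.arg(name)
  opts <- list(...)
  f <- switch(name,
    sauvola = function(img) {
      window <- if (is.null(opts$window)) 15L else opts$window
      k <- if (is.null(opts$k)) 0.2 else opts$k
      if (all(img == img[1])) return(matrix(FALSE, nrow(img), ncol(img)))
      floor_t <- otsu_threshold(img)
      mask <- sauvola_threshold(img, window, k) & img > floor_t
      skeletonize(mask)
    },
    identity = function(img) {
      thr <- if (is.null(opts$threshold)) max(img) / 2 else opts$threshold
      img > thr
    }
  )
  attr(f, "backend_id") <- name
  class(f) <- c("cm_backend", class(f))
  f
}

# crossing number: count of 0->1 transitions in the cyclic 8-neighborhood
# sequence; 1 at line ends, 2 along a line (including staircase corners),
# >= 3 at true branch points
.crossing_number <- function(skel) {
  p <- lapply(list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                   c(1, 0), c(1, -1), c(0, -1), c(-1, -1)),
              function(o) .shift_mat(skel, -o[1], -o[2], FALSE))
  seqp <- c(p, p[1])
  A <- matrix(0L, nrow(skel), ncol(skel))
  for (i in 1:8) A <- A + (!seqp[[i]] & seqp[[i + 1]])
  A
}

# split a skeleton mask into junction-free branches and trace each branch
# as an ordered 8-connected path; returns list of n x 2 matrices (row, col,
# 0-based). Junctions are pixels with crossing number >= 3 (neighbor count
# alone misfires on staircase corners of a thinned skeleton).
.trace_branches <- function(skel) {
  junctions <- skel & .crossing_number(skel) >= 3
  # removing a junction pixel alone can leave its branch stubs diagonally
  # 8-connected around the hole; excise the junction's whole neighborhood
  if (any(junctions)) {
    jd <- junctions
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      jd <- jd | .shift_mat(junctions, dr, dc, FALSE)
    }
    junctions <- skel & jd
  }
  branch_mask <- skel & !junctions
  lab <- label_components(branch_mask, 8L)
  nl <- max(lab)
  if (nl == 0L) return(list())
  nr <- nrow(skel); nc <- ncol(skel)
  paths <- vector("list", nl)
  idx_all <- which(lab > 0)
  idx_all <- idx_all[order(lab[idx_all])]
  starts <- c(1L, which(diff(lab[idx_all]) > 0) + 1L, length(idx_all) + 1L)
  # within-branch pixel index lookup, shared across branches (label check
  # disambiguates touching-but-distinct branches, which cannot occur after
  # junction removal, but keeps the walk safe regardless)
  posm <- matrix(0L, nr, nc)
  posm[idx_all] <- sequence(diff(starts))
  offs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  for (b in seq_len(nl)) {
    idx <- idx_all[starts[b]:(starts[b + 1L] - 1L)]
    r <- ((idx - 1L) %% nr); c_ <- ((idx - 1L) %/% nr)   # 0-based
    n <- length(idx)
    if (n == 1L) {
      paths[[b]] <- cbind(row = r, col = c_)
      next
    }
    nbrs <- vector("list", n)
    deg <- integer(n)
    for (i in seq_len(n)) {
      rr <- r[i] + offs[, 1] + 1L; cc <- c_[i] + offs[, 2] + 1L
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      lin <- (cc[ok] - 1L) * nr + rr[ok]
      hits <- posm[lin][lab[lin] == b]
      nbrs[[i]] <- hits
      deg[i] <- length(hits)
    }
    start <- which(deg == 1L)[1]
    if (is.na(start)) start <- 1L  # closed loop: arbitrary start
    path <- integer(n)
    path[1] <- start
    visited <- logical(n)
    visited[start] <- TRUE
    for (s in 2:n) {
      cand <- nbrs[[path[s - 1L]]]
      cand <- cand[!visited[cand]]
      if (length(cand) == 0L) { path <- path[1:(s - 1L)]; break }
      # staircase ambiguity: prefer the axial neighbor so every pixel of
      # the branch is visited before the diagonal shortcut
      if (length(cand) > 1L) {
        ax <- abs(r[cand] - r[path[s - 1L]]) +
              abs(c_[cand] - c_[path[s - 1L]]) == 1L
        if (any(ax)) cand <- c(cand[ax], cand[!ax])
      }
      path[s] <- cand[1]
      visited[cand[1]] <- TRUE
    }
    path <- path[path > 0L]
    paths[[b]] <- cbind(row = r[path], col = c_[path])
  }
  paths
}

# iteratively remove terminal spur branches shorter than `prune_px`:
# short side-twigs on a thick skeleton create junctions that would
# otherwise fragment one fiber into several branches
.prune_spurs <- function(skel, prune_px = 3L, iterations = 2L) {
  for (it in seq_len(iterations)) {
    ncnt <- .neighbor_count8(skel)
    endpoints <- skel & ncnt <= 1
    branches <- .trace_branches(skel)
    removed <- FALSE
    for (p in branches) {
      if (nrow(p) >= prune_px) next
      has_end <- any(endpoints[cbind(p[, 1] + 1L, p[, 2] + 1L)])
      if (has_end) {
        skel[cbind(p[, 1] + 1L, p[, 2] + 1L)] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skel
}

#' Segment and skeletonize collagen fibers
#'
#' Runs the segmentation backend, prunes terminal spur branches shorter
#' than \code{prune_px}, splits the skeleton at junction pixels (pixels
#' with 3 or more skeleton neighbors), and traces each junction-free
#' branch as an ordered path. One branch = one fiber.
#'
#' @param img preprocessed SHG matrix.
#' @param backend a \code{cm_backend} (default the Sauvola classical
#'   backend).
#' @param min_path_px minimum branch length in pixels for inclusion
#'   (default 3; shorter branches carry no orientation or tortuosity
#'   information).
#' @param prune_px terminal branches shorter than this are removed before
#'   junction splitting (default 3; set 0 to disable, as with the identity
#'   backend where the input already is the exact skeleton).
#' @return list with \code{paths} (list of ordered n x 2 coordinate
#'   matrices, 0-based row/col), \code{skeleton} (logical matrix) and
#'   \code{backend_id}.
#' @export
segment_fibers <- function(img, backend = segmentation_backend("sauvola"),
                           min_path_px = 3L, prune_px = NULL) {
  skel <- backend(img)
  if (is.null(prune_px))
    prune_px <- if (identical(attr(backend, "backend_id"), "identity"))
      0L else 3L
  if (prune_px > 0L) skel <- .prune_spurs(skel, prune_px)
  paths <- .trace_branches(skel)
  paths <- Filter(function(p) nrow(p) >= min_path_px, paths)
  list(paths = paths, skeleton = skel,
       backend_id = attr(backend, "backend_id"))
}

# validate an ordered skeleton path: n x 2, consecutive pixels 8-adjacent
.check_path <- function(path) {
  p <- as.matrix(path)
  if (nrow(p) < 2L) stop("skeleton path must contain at least 2 pixels")
  d <- abs(diff(p))
  if (any(pmax(d[, 1], d[, 2]) != 1L))
    stop("consecutive path pixels must be 8-neighbors")
  p
}

#' Curvilinear fiber length
#'
#' Sum of step weights along the ordered skeleton path - axial steps weigh
#' 1, diagonal steps sqrt(2) - scaled by the pixel size.
#'
#' @param path ordered n x 2 matrix of skeleton pixels (row, col).
#' @param pixel_size_um um per pixel.
#' @return length in micrometers.
#' @export
fiber_length <- function(path, pixel_size_um = 0.63) {
  p <- .check_path(path)
  d <- abs(diff(p))
  steps <- ifelse(d[, 1] + d[, 2] == 2L, sqrt(2), 1)
  sum(steps) * pixel_size_um
}

#' Fiber orientation
#'
#' Angle of the endpoint-to-endpoint vector, measured from the column (x)
#' axis toward the row axis and folded into [0, pi). For closed loops
#' (identical endpoints) the orientation of the principal axis of the path
#' pixels is returned and flagged via the \code{"fallback"} attribute.
#'
#' @param path ordered n x 2 matrix (row, col).
#' @return angle in radians in [0, pi).
#' @export
fiber_orientation <- function(path) {
  p <- .check_path(path)
  d <- p[nrow(p), ] - p[1, ]
  if (all(d == 0)) {
    cc <- sweep(p, 2, colMeans(p))
    ev <- eigen(crossprod(cc))$vectors[, 1]
    a <- atan2(ev[1], ev[2]) %% pi
    attr(a, "fallback") <- "principal_axis"
    return(a)
  }
  (atan2(d[1], d[2])) %% pi
}

#' Fiber tortuosity
#'
#' Ratio of the curvilinear length to the straight-line (Euclidean)
#' endpoint distance; 1 for a straight fiber. Undefined (NA, flagged) for
#' closed loops.
#'
#' @param path ordered n x 2 matrix (row, col).
#' @param pixel_size_um um per pixel.
#' @return tortuosity ratio (>= 1), or NA for a closed loop.
#' @export
fiber_tortuosity <- function(path, pixel_size_um = 0.63) {
  p <- .check_path(path)
  d <- p[nrow(p), ] - p[1, ]
  eu <- sqrt(sum(d^2)) * pixel_size_um
  if (eu == 0) {
    out <- NA_real_
    attr(out, "closed_loop") <- TRUE
    return(out)
  }
  fiber_length(p, pixel_size_um) / eu
}

#' Build a fiber table from skeleton paths
#'
#' @param paths list of ordered n x 2 coordinate matrices.
#' @param pixel_size_um um per pixel.
#' @param backend_id segmentation backend identifier recorded in the table.
#' @return data.frame of class \code{cm_fiber_table}: id, length_um,
#'   orientation_rad, tortuosity (NA for closed loops), n_pixels, with the
#'   ordered paths in the \code{path} list-column and pixel size in
#'   attributes.
#' @export
build_fiber_table <- function(paths, pixel_size_um = 0.63,
                              backend_id = NA_character_) {
  n <- length(paths)
  tab <- data.frame(
    id = seq_len(n),
    length_um = vapply(paths, fiber_length, 0, pixel_size_um = pixel_size_um),
    orientation_rad = vapply(paths, function(p)
      as.numeric(fiber_orientation(p)), 0),
    tortuosity = vapply(paths, function(p)
      as.numeric(fiber_tortuosity(p, pixel_size_um)), 0),
    n_pixels = vapply(paths, nrow, 0L)
  )
  if (n == 0L)
    tab <- data.frame(id = integer(), length_um = numeric(),
                      orientation_rad = numeric(), tortuosity = numeric(),
                      n_pixels = integer())
  tab$path <- if (n) unname(paths) else list()
  attr(tab, "pixel_size_um") <- pixel_size_um
  attr(tab, "backend_id") <- backend_id
  class(tab) <- c("cm_fiber_table", "data.frame")
  tab
}

#' Full fiber extraction from a raw SHG image
#'
#' Convenience composition: preprocess, segment, measure.
#'
#' @param img raw SHG matrix, 0-255.
#' @param params a \code{cm_shg_params}.
#' @param backend segmentation backend.
#' @param min_path_px minimum branch length (pixels).
#' @return a \code{cm_fiber_table}.
#' @export
extract_fibers <- function(img, params = shg_params(),
                           backend = segmentation_backend("sauvola"),
                           min_path_px = 3L) {
  pre <- preprocess_shg(img, params)
  seg <- segment_fibers(pre, backend, min_path_px)
  build_fiber_table(seg$paths, params$pixel_size_um, seg$backend_id)
}

#' Per-pixel property map
#'
#' Image-shaped array in which every skeleton pixel carries its fiber's
#' value for one property; non-skeleton pixels are NA.
#'
#' @param fiber_table a \code{cm_fiber_table}.
#' @param property "length_um", "orientation_rad" or "tortuosity".
#' @param shape image shape c(rows, cols).
#' @return numeric matrix with NA sentinel off-skeleton.
#' @export
make_property_map <- function(fiber_table,
                              property = c("length_um", "orientation_rad",
                                           "tortuosity"),
                              shape) {
  property <- match.arg(property)
  out <- matrix(NA_real_, shape[1], shape[2])
  for (i in seq_len(nrow(fiber_table))) {
    p <- fiber_table$path[[i]]
    out[cbind(p[, 1] + 1L, p[, 2] + 1L)] <- fiber_table[[property]][i]
  }
  out
}

#' Fiber density
#'
#' @param fiber_table a \code{cm_fiber_table}.
#' @param area_mm2 tissue area in square millimeters.
#' @return fibers per mm^2.
#' @export
fiber_density <- function(fiber_table, area_mm2) {
  if (!is.numeric(area_mm2) || area_mm2 <= 0)
    stop("tissue area must be positive")
  nrow(fiber_table) / area_mm2
}

#' @export
print.cm_fiber_table <- function(x, ...) {
  cat(sprintf("<cm_fiber_table: %d fibers, pixel %.3g um, backend %s>\n",
              nrow(x), attr(x, "pixel_size_um"),
              attr(x, "backend_id")))
  if (nrow(x))
    print(utils::head(as.data.frame(x)[c("id", "length_um",
                                         "orientation_rad", "tortuosity",
                                         "n_pixels")]), ...)
  invisible(x)
}
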