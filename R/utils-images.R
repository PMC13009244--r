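# Low-level image utilities shared by all pipeline stages.
#
# Conventions used throughout the package:
#  * grayscale images are numeric matrices (rows x cols), intensities 0-255
#  * RGB images are numeric arrays (rows x cols x 3), intensities 0-255
#  * pixel coordinates in all tables are (row, col), 0-based, with pixel
#    centers at integer coordinates; matrix element [r+1, c+1] is pixel (r, c)

#' Convert pixel distances to micrometers
#'
#' @param px distance(s) in pixels.
#' @param pixel_size_um physical pixel size in micrometers per pixel
#'   (default 0.63, the lateral resolution of the SHG acquisition).
#' @return distance(s) in micrometers.
#' @export
px_to_um <- function(px, pixel_size_um = 0.63) {
  stopifnot(pixel_size_um > 0)
  px * pixel_size_um
}

#' @rdname px_to_um
#' @param um distance(s) in micrometers.
#' @export
um_to_px <- function(um, pixel_size_um = 0.63) {
  stopifnot(pixel_size_um > 0)
  um / pixel_size_um
}

#' Read a grayscale image from TIFF or PNG
#'
#' Intensities are returned on the 0-255 scale regardless of on-disk depth.
#'
#' @param path file path ending in .tif/.tiff/.png.
#' @return numeric matrix (rows x cols).
#' @export
read_image_gray <- function(path) {
  img <- .read_any_image(path)
  if (length(dim(img)) == 3L) img <- luminance(img * if (max(img) <= 1) 255 else 1) / 255
  img * 255
}

#' Read an RGB image from TIFF or PNG
#'
#' @param path file path.
#' @return numeric array (rows x cols x 3), intensities 0-255.
#' @export
read_image_rgb <- function(path) {
  img <- .read_any_image(path)
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("expected an RGB image with 3 channels: ", path)
  img[, , 1:3, drop = FALSE] * 255
}

.read_any_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image extension: ", ext)
  )
  img
}

#' Write a grayscale or RGB image to TIFF or PNG
#'
#' @param img matrix (grayscale) or rows x cols x 3 array (RGB), 0-255.
#' @param path destination ending in .tif/.tiff/.png.
#' @export
write_image <- function(img, path) {
  x <- pmin(pmax(img / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    png = png::writePNG(x, path),
    stop("unsupported image extension: ", ext)
  )
  invisible(path)
}

#' Luminance of an RGB image
#'
#' Rec. 601 weights; used for tissue masking and registration of brightfield
#' images.
#'
#' @param rgb rows x cols x 3 array.
#' @return matrix on the same intensity scale as the input.
#' @export
luminance <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] >= 3L)
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# shift a matrix by (dr, dc), padding with `fill`
.shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# edge-replicating shift (for filters)
.shift_edge <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1), nc)
  m[ri, ci]
}

#' Median filter with an arbitrary (possibly even) square window
#'
#' Even windows have no center pixel; the window anchored at pixel (r, c)
#' spans offsets `(0:(w-1)) - w %/% 2` in each axis, and the median of an
#' even number of values is the mean of the two middle order statistics
#' (matching the usual rank-filter behaviour of even-sized windows).
#' Borders are handled by edge replication.
#'
#' @param img numeric matrix.
#' @param w window side length in pixels (default 2).
#' @return filtered matrix.
#' @export
median_filter2 <- function(img, w = 2L) {
  stopifnot(is.matrix(img), w >= 1)
  w <- as.integer(w)
  if (w == 1L) return(img)
  offs <- (0:(w - 1L)) - w %/% 2L
  shifts <- expand.grid(dr = offs, dc = offs)
  k <- nrow(shifts)
  if (k == 4L) {
    a <- .shift_edge(img, shifts$dr[1], shifts$dc[1])
    b <- .shift_edge(img, shifts$dr[2], shifts$dc[2])
    c_ <- .shift_edge(img, shifts$dr[3], shifts$dc[3])
    d <- .shift_edge(img, shifts$dr[4], shifts$dc[4])
    # median of 4 = (sum - min - max) / 2
    return((a + b + c_ + d - pmin(a, b, c_, d) - pmax(a, b, c_, d)) / 2)
  }
  stack <- vapply(seq_len(k), function(i)
    as.vector(.shift_edge(img, shifts$dr[i], shifts$dc[i])),
    numeric(length(img)))
  med <- apply(stack, 1L, stats::median)
  matrix(med, nrow(img), ncol(img))
}

# summed-area local mean and sd over a (2*hw+1) square window, truncated at
# image borders (true statistics of the in-bounds part of the window)
.local_mean_sd <- function(img, hw) {
  nr <- nrow(img); nc <- ncol(img)
  sat <- function(m) {
    s <- apply(m, 2, cumsum)
    t(apply(s, 1, cumsum))
  }
  S1 <- sat(img); S2 <- sat(img^2)
  # pad with a leading zero row/col for clean box sums
  S1 <- rbind(0, cbind(0, S1)); S2 <- rbind(0, cbind(0, S2))
  r0 <- pmax(seq_len(nr) - hw - 1L, 0L); r1 <- pmin(seq_len(nr) + hw, nr)
  c0 <- pmax(seq_len(nc) - hw - 1L, 0L); c1 <- pmin(seq_len(nc) + hw, nc)
  box <- function(S) S[r1 + 1L, c1 + 1L, drop = FALSE] -
    S[r0 + 1L, c1 + 1L, drop = FALSE] -
    S[r1 + 1L, c0 + 1L, drop = FALSE] + S[r0 + 1L, c0 + 1L, drop = FALSE]
  n <- outer(r1 - r0, c1 - c0)
  m <- box(S1) / n
  v <- pmax(box(S2) / n - m^2, 0)
  list(mean = m, sd = sqrt(v))
}

#' Sauvola adaptive threshold
#'
#' Local threshold \code{t = m (1 + k (s / R - 1))} with window mean m and
#' standard deviation s, computed with integral images. Input is scaled to
#' [0, 1]; R is the half dynamic range (0.5).
#'
#' @param img numeric matrix, 0-255.
#' @param window odd window side length (default 15).
#' @param k sensitivity (default 0.2).
#' @return logical matrix, TRUE where the pixel exceeds the local threshold.
#' @export
sauvola_threshold <- function(img, window = 15L, k = 0.2) {
  stopifnot(is.matrix(img), window >= 3)
  x <- img / 255
  st <- .local_mean_sd(x, as.integer(window) %/% 2L)
  thr <- st$mean * (1 + k * (st$sd / 0.5 - 1))
  x > thr
}

#' Otsu global threshold
#'
#' Thin wrapper around EBImage's histogram-based Otsu on the 0-255 scale.
#'
#' @param img numeric matrix, 0-255.
#' @return threshold value on the 0-255 scale.
#' @export
otsu_threshold <- function(img, levels = 256L) {
  x <- pmin(pmax(img / 255, 0), 1)
  EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = levels) * 255
}

#' Label connected components of a binary mask
#'
#' Connectivity is selectable (4 or 8), unlike most stock labelers; components
#' are found on the pixel adjacency graph.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix; 0 = background, components numbered from 1 in
#'   raster order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask != 0
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  rank <- integer(nr * nc); rank[fg] <- seq_along(fg)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  fr <- ((fg - 1L) %% nr) + 1L
  fc <- ((fg - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (o in offs) {
    nr2 <- fr + o[1]; nc2 <- fc + o[2]
    ok <- nr2 >= 1L & nr2 <= nr & nc2 >= 1L & nc2 <= nc
    nidx <- (nc2[ok] - 1L) * nr + nr2[ok]
    ok2 <- mask[nidx]
    if (any(ok2)) {
      from <- rank[fg[ok]][ok2]
      to <- rank[nidx[ok2]]
      edges <- c(edges, rbind(from, to))
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  # renumber components in raster order of first occurrence
  first <- !duplicated(memb)
  remap <- integer(max(memb)); remap[memb[first]] <- seq_len(sum(first))
  lab[fg] <- remap[memb]
  lab
}

# count of 8-neighbors that are TRUE, for every pixel
.neighbor_count8 <- function(mask) {
  m <- mask * 1
  s <- matrix(0, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- s + .shift_mat(m, dr, dc)
  }
  s
}

#' Morphological skeletonization (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels until an 8-connected, 1-pixel-wide
#' skeleton remains.
#'
#' @param mask logical matrix.
#' @return logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  m <- mask != 0
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- lapply(list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                       c(1, 0), c(1, -1), c(0, -1), c(-1, -1)),
                  function(o) .shift_mat(m, -o[1], -o[2], FALSE))
      # p[[1]]..p[[8]] = N, NE, E, SE, S, SW, W, NW neighbor values
      B <- Reduce(`+`, lapply(p, function(x) x * 1))
      seqp <- c(p, p[1])
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (!seqp[[i]] & seqp[[i + 1]])
      if (sub == 1) {
        cond3 <- !(p[[1]] & p[[3]] & p[[5]])   # N*E*S == 0
        cond4 <- !(p[[3]] & p[[5]] & p[[7]])   # E*S*W == 0
      } else {
        cond3 <- !(p[[1]] & p[[3]] & p[[7]])   # N*E*W == 0
        cond4 <- !(p[[1]] & p[[5]] & p[[7]])   # N*S*W == 0
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & cond3 & cond4
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# axial circular mean of angles in [0, pi): double, average, halve
.axial_mean <- function(theta, na.rm = TRUE) {
  if (na.rm) theta <- theta[!is.na(theta)]
  if (length(theta) == 0L) return(NA_real_)
  a <- atan2(mean(sin(2 * theta)), mean(cos(2 * theta))) / 2
  a %% pi
}

# dispersion-based SEM for axial angles: sd of signed angular deviations
# from the axial mean, folded into (-pi/2, pi/2], divided by sqrt(n)
.axial_sem <- function(theta) {
  theta <- theta[!is.na(theta)]
  n <- length(theta)
  if (n < 2L) return(NA_real_)
  mu <- .axial_mean(theta)
  dev <- ((theta - mu + pi / 2) %% pi) - pi / 2
  stats::sd(dev) / sqrt(n)
}
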