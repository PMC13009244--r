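# Rigid/affine 2D transforms and intensity-based registration of the
# brightfield (moving) image onto the SHG (fixed) image.
#
# Direction convention: a transform maps MOVING-frame coordinates into the
# FIXED (SHG) frame; all downstream analysis runs in the SHG frame. Points
# are (row, col), 0-based. The linear part acts about `center` (default the
# moving-image center), so rotation parameters are readable:
#   p_fixed = A %*% (p_moving - center) + center + t

#' Construct a 2D spatial transform
#'
#' @param model "rigid" or "affine".
#' @param rotation rotation angle in radians (rigid; positive rotates the
#'   row axis toward the column axis).
#' @param translation numeric length-2, (rows, cols) in pixels.
#' @param A 2x2 linear matrix (affine; overrides \code{rotation}).
#' @param center rotation center (row, col); defaults to the moving-image
#'   center when shapes are supplied, else c(0, 0).
#' @param fixed_shape,moving_shape image shapes c(rows, cols), recorded for
#'   bounds checking.
#' @return object of class \code{cm_transform}.
#' @export
cm_transform <- function(model = c("rigid", "affine"), rotation = 0,
                         translation = c(0, 0), A = NULL, center = NULL,
                         fixed_shape = NULL, moving_shape = NULL) {
  model <- match.arg(model)
  if (is.null(A)) {
    A <- matrix(c(cos(rotation), -sin(rotation),
                  sin(rotation),  cos(rotation)), 2, 2, byrow = TRUE)
  } else {
    A <- matrix(as.numeric(A), 2, 2)
  }
  if (abs(det(A)) < .Machine$double.eps) stop("transform is not invertible")
  if (is.null(center)) {
    center <- if (!is.null(moving_shape)) (moving_shape - 1) / 2 else c(0, 0)
  }
  structure(list(model = model, A = A, translation = as.numeric(translation),
                 center = as.numeric(center), fixed_shape = fixed_shape,
                 moving_shape = moving_shape),
            class = "cm_transform")
}

#' Identity transform
#' @param shape image shape c(rows, cols), used for both frames.
#' @export
transform_identity <- function(shape = NULL) {
  cm_transform("rigid", 0, c(0, 0), fixed_shape = shape, moving_shape = shape)
}

#' Rotation angle of a transform, in radians
#' @param tfm a \code{cm_transform}.
#' @export
transform_rotation <- function(tfm) {
  atan2(-tfm$A[1, 2], tfm$A[1, 1])
}

#' @export
print.cm_transform <- function(x, ...) {
  cat(sprintf("<cm_transform: %s>\n", x$model))
  cat(sprintf("  rotation    %.4f deg\n", transform_rotation(x) * 180 / pi))
  cat(sprintf("  translation (%.3f, %.3f) px (row, col)\n",
              x$translation[1], x$translation[2]))
  if (x$model == "affine") {
    cat("  A =\n"); print(signif(x$A, 6))
  }
  invisible(x)
}

#' Invert a transform
#' @param tfm a \code{cm_transform}.
#' @return the inverse mapping (fixed frame into moving frame).
#' @export
invert_transform <- function(tfm) {
  Ai <- solve(tfm$A)
  # q = A (p - c) + c + t  =>  p = Ai (q - c - t) + c
  #   = Ai (q - c') + c' + t'  with c' = c + t, t' = c - c' = -t
  cm_transform(tfm$model, A = Ai, translation = -tfm$translation,
               center = tfm$center + tfm$translation,
               fixed_shape = tfm$moving_shape, moving_shape = tfm$fixed_shape)
}

#' Map points from the moving frame into the fixed frame
#'
#' Exact continuous coordinate mapping (no resampling); used to carry dot
#' centroids into the SHG frame after registration.
#'
#' @param points matrix or data.frame with two columns (row, col), 0-based.
#' @param tfm a \code{cm_transform}.
#' @return matrix with columns row, col and attribute \code{out_of_bounds},
#'   a logical vector flagging points mapped outside \code{fixed_shape}.
#' @export
warp_points <- function(points, tfm) {
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(p) <- "double"
  q <- sweep(p, 2, tfm$center) %*% t(tfm$A)
  q <- sweep(q, 2, tfm$center + tfm$translation, `+`)
  colnames(q) <- c("row", "col")
  if (!is.null(tfm$fixed_shape)) {
    oob <- q[, 1] < 0 | q[, 1] > tfm$fixed_shape[1] - 1 |
           q[, 2] < 0 | q[, 2] > tfm$fixed_shape[2] - 1
    attr(q, "out_of_bounds") <- oob
  }
  q
}

#' Resample an image from the moving frame onto the fixed grid
#'
#' @param img matrix (grayscale) or rows x cols x 3 array (RGB).
#' @param tfm a \code{cm_transform} (moving into fixed).
#' @param interpolation "linear" for intensity images, "nearest" for masks
#'   and label images.
#' @param output_shape shape of the output grid; defaults to
#'   \code{tfm$fixed_shape}, else the input shape.
#' @param fill value for pixels that map outside the input.
#' @return resampled image on the fixed grid.
#' @export
warp_image <- function(img, tfm, interpolation = c("linear", "nearest"),
                       output_shape = NULL, fill = 0) {
  interpolation <- match.arg(interpolation)
  is_rgb <- length(dim(img)) == 3L
  in_shape <- dim(img)[1:2]
  if (is.null(output_shape)) output_shape <- tfm$fixed_shape
  if (is.null(output_shape)) output_shape <- in_shape
  nr <- output_shape[1]; nc <- output_shape[2]
  inv <- invert_transform(tfm)
  grid <- cbind(rep(0:(nr - 1), times = nc), rep(0:(nc - 1), each = nr))
  src <- warp_points(grid, inv)
  one <- function(ch) {
    out <- matrix(fill, nr, nc)
    if (interpolation == "nearest") {
      r <- round(src[, 1]); c_ <- round(src[, 2])
      ok <- r >= 0 & r <= in_shape[1] - 1 & c_ >= 0 & c_ <= in_shape[2] - 1
      out[cbind(grid[ok, 1] + 1L, grid[ok, 2] + 1L)] <-
        ch[cbind(r[ok] + 1L, c_[ok] + 1L)]
    } else {
      r0 <- floor(src[, 1]); c0 <- floor(src[, 2])
      fr <- src[, 1] - r0; fc <- src[, 2] - c0
      ok <- r0 >= 0 & r0 <= in_shape[1] - 2 & c0 >= 0 & c0 <= in_shape[2] - 2
      r0k <- r0[ok] + 1L; c0k <- c0[ok] + 1L; frk <- fr[ok]; fck <- fc[ok]
      v <- ch[cbind(r0k, c0k)] * (1 - frk) * (1 - fck) +
           ch[cbind(r0k + 1L, c0k)] * frk * (1 - fck) +
           ch[cbind(r0k, c0k + 1L)] * (1 - frk) * fck +
           ch[cbind(r0k + 1L, c0k + 1L)] * frk * fck
      out[cbind(grid[ok, 1] + 1L, grid[ok, 2] + 1L)] <- v
    }
    out
  }
  if (is_rgb) {
    out <- array(fill, c(nr, nc, dim(img)[3]))
    for (k in seq_len(dim(img)[3])) out[, , k] <- one(img[, , k])
    out
  } else one(img)
}

# block-mean downsampling by an integer factor
.downsample <- function(img, f) {
  if (f == 1L) return(img)
  nr <- (nrow(img) %/% f) * f
  nc <- (ncol(img) %/% f) * f
  x <- img[1:nr, 1:nc]
  x <- (array(x, c(f, nr %/% f, nc)) |> colMeans())
  t(colMeans(array(t(x), c(f, nc %/% f, nr %/% f))))
}

# normalized cross-correlation over the jointly valid region
.metric_ncc <- function(a, b, valid) {
  x <- a[valid]; y <- b[valid]
  if (length(x) < 32L) return(-1)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(-1)
  mean((x - mean(x)) * (y - mean(y))) / (sx * sy)
}

# joint-histogram mutual information (nats)
.metric_mi <- function(a, b, valid, bins = 32L) {
  x <- a[valid]; y <- b[valid]
  if (length(x) < 64L) return(-1)
  bx <- pmin(floor((x - min(x)) / (diff(range(x)) + 1e-9) * bins), bins - 1)
  by <- pmin(floor((y - min(y)) / (diff(range(y)) + 1e-9) * bins), bins - 1)
  jt <- table(factor(bx, 0:(bins - 1)), factor(by, 0:(bins - 1))) /
    length(x)
  px <- rowSums(jt); py <- colSums(jt)
  nz <- jt > 0
  sum(jt[nz] * log(jt[nz] / outer(px, py)[nz]))
}

# integer translation (fixed relative to moving) by FFT cross-correlation
.xcorr_shift <- function(fixed, moving) {
  a <- fixed - mean(fixed)
  b <- moving - mean(moving)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  i <- which.max(cc)
  nr <- nrow(a)
  dr <- (i - 1) %% nr; dc <- (i - 1) %/% nr
  if (dr > nr / 2) dr <- dr - nr
  if (dc > ncol(a) / 2) dc <- dc - ncol(a)
  c(dr, dc)
}

.reg_score <- function(theta, tr, tc, moving, fixed, metric, scale = 1) {
  A <- NULL
  tfm <- cm_transform("rigid", rotation = theta, translation = c(tr, tc),
                      center = (dim(moving) - 1) / 2,
                      fixed_shape = dim(fixed), moving_shape = dim(moving))
  if (scale != 1) tfm$A <- tfm$A * scale
  w <- warp_image(moving, tfm, "linear", output_shape = dim(fixed),
                  fill = NA_real_)
  valid <- !is.na(w)
  w[!valid] <- 0
  fn <- if (metric == "mi") .metric_mi else .metric_ncc
  fn(fixed, w, valid)
}

#' Register a moving image onto a fixed image
#'
#' Recovers the rigid (or affine) transform mapping the moving image into
#' the fixed frame by maximizing an intensity similarity metric with a
#' multi-resolution strategy: an exhaustive coarse search over rotation
#' angles with FFT cross-correlation for translation, followed by
#' Nelder-Mead refinement of all parameters at increasing resolution.
#' Fully deterministic: the metric uses every overlapping pixel, no random
#' sampling.
#'
#' @param moving image to be aligned (matrix, or RGB array - converted to
#'   luminance for metric evaluation).
#' @param fixed reference image (matrix), typically the SHG frame.
#' @param model "rigid" (default) or "affine". The affine model is refined
#'   from the rigid solution.
#' @param options list: \code{metric} ("ncc", default, or "mi"),
#'   \code{angle_range_deg} half-width of the coarse rotation search
#'   (default 12), \code{angle_step_deg} coarse step (default 1.5),
#'   \code{init_scale} initial isotropic scale of moving relative to fixed
#'   (default 1; use the pixel-size ratio when modalities were acquired at
#'   different magnification).
#' @return a \code{cm_transform} with an \code{optim} attribute carrying the
#'   final metric value and convergence info.
#' @export
register <- function(moving, fixed, model = c("rigid", "affine"),
                     options = list()) {
  model <- match.arg(model)
  if (length(dim(moving)) == 3L) moving <- luminance(moving)
  if (length(dim(fixed)) == 3L) fixed <- luminance(fixed)
  stopifnot(is.matrix(moving), is.matrix(fixed))
  metric <- if (is.null(options$metric)) "ncc" else options$metric
  arange <- if (is.null(options$angle_range_deg)) 12 else options$angle_range_deg
  astep <- if (is.null(options$angle_step_deg)) 1.5 else options$angle_step_deg
  iscale <- if (is.null(options$init_scale)) 1 else options$init_scale

  if (iscale != 1) {
    # pre-scale moving about its center so the search is pure rigid
    pre <- cm_transform("rigid", 0, c(0, 0),
                        center = (dim(moving) - 1) / 2,
                        fixed_shape = dim(moving), moving_shape = dim(moving))
    pre$A <- pre$A * iscale
    moving <- warp_image(moving, pre, "linear", output_shape = dim(moving))
  }

  f <- max(1L, 2L^floor(log2(min(dim(fixed)) / 96)))
  fx_c <- .downsample(fixed, f)
  mv_c <- .downsample(moving, f)
  cen_c <- (dim(mv_c) - 1) / 2
  angles <- seq(-arange, arange, by = astep) * pi / 180
  best <- list(score = -Inf, theta = 0, t = c(0, 0))
  for (th in angles) {
    tf <- cm_transform("rigid", th, c(0, 0), center = cen_c,
                       fixed_shape = dim(fx_c), moving_shape = dim(mv_c))
    rot <- warp_image(mv_c, tf, "linear", output_shape = dim(fx_c))
    sh <- .xcorr_shift(fx_c, rot)
    tf2 <- cm_transform("rigid", th, sh, center = cen_c,
                        fixed_shape = dim(fx_c), moving_shape = dim(mv_c))
    w <- warp_image(mv_c, tf2, "linear", output_shape = dim(fx_c),
                    fill = NA_real_)
    valid <- !is.na(w); w[!valid] <- 0
    sc <- .metric_ncc(fx_c, w, valid)
    if (sc > best$score) best <- list(score = sc, theta = th, t = sh)
  }

  # refine at intermediate then full resolution
  par <- c(best$theta, best$t * f)
  levels <- unique(c(max(1L, f %/% 2L), 1L))
  conv <- NA_integer_; val <- NA_real_
  for (lv in levels) {
    fx <- .downsample(fixed, lv); mv <- .downsample(moving, lv)
    obj <- function(p) -.reg_score(p[1], p[2] / lv, p[3] / lv, mv, fx, metric)
    op <- stats::optim(c(par[1], par[2], par[3]), function(p) obj(p),
                       method = "Nelder-Mead",
                       control = list(maxit = if (lv == 1L) 120 else 200,
                                      reltol = 1e-7,
                                      parscale = c(0.02, 2, 2)))
    par <- op$par; conv <- op$convergence; val <- -op$value
    if (!is.finite(val)) stop("registration metric became non-finite; trace: ",
                              paste(signif(par, 5), collapse = ", "))
  }
  tfm <- cm_transform("rigid", rotation = par[1],
                      translation = par[2:3],
                      center = (dim(moving) - 1) / 2,
                      fixed_shape = dim(fixed), moving_shape = dim(moving))
  if (iscale != 1) tfm$A <- tfm$A * iscale

  if (model == "affine") {
    p0 <- c(as.vector(tfm$A), tfm$translation)
    obj_a <- function(p) {
      tf <- cm_transform("affine", A = matrix(p[1:4], 2, 2),
                         translation = p[5:6],
                         center = (dim(moving) - 1) / 2,
                         fixed_shape = dim(fixed), moving_shape = dim(moving))
      if (abs(det(tf$A)) < 1e-6) return(1)
      w <- warp_image(moving, tf, "linear", output_shape = dim(fixed),
                      fill = NA_real_)
      valid <- !is.na(w); w[!valid] <- 0
      fn <- if (metric == "mi") .metric_mi else .metric_ncc
      -fn(fixed, w, valid)
    }
    op <- stats::optim(p0, obj_a, method = "Nelder-Mead",
                       control = list(maxit = 250, reltol = 1e-8,
                                      parscale = c(rep(0.02, 4), 2, 2)))
    tfm <- cm_transform("affine", A = matrix(op$par[1:4], 2, 2),
                        translation = op$par[5:6],
                        center = (dim(moving) - 1) / 2,
                        fixed_shape = dim(fixed), moving_shape = dim(moving))
    conv <- op$convergence; val <- -op$value
  }
  attr(tfm, "optim") <- list(metric = metric, value = val, convergence = conv)
  tfm
}

#' Serialize a transform to JSON
#' @param tfm a \code{cm_transform}.
#' @param path destination file.
#' @export
write_transform <- function(tfm, path) {
  obj <- list(model = tfm$model, A = tfm$A, translation = tfm$translation,
              center = tfm$center, fixed_shape = tfm$fixed_shape,
              moving_shape = tfm$moving_shape,
              direction = "moving_to_fixed", coordinates = "row_col_0based")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a transform from JSON
#' @param path file written by \code{write_transform}.
#' @export
read_transform <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm_transform(o$model, A = matrix(unlist(o$A), 2, 2),
               translation = unlist(o$translation),
               center = unlist(o$center),
               fixed_shape = if (length(o$fixed_shape)) unlist(o$fixed_shape),
               moving_shape = if (length(o$moving_shape)) unlist(o$moving_shape))
}
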