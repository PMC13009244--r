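# Independent oracles used to validate the package's optimized code paths.
# Each is a direct, brute-force restatement of the quantity's definition,
# deliberately sharing no code with the implementation under test.

# path length: Euclidean norm of every step (equals 1 for axial steps,
# sqrt(2) for diagonal steps on an 8-connected chain)
oracle_path_length <- function(path, pixel_size_um) {
  d <- diff(path)
  sum(sqrt(d[, 1]^2 + d[, 2]^2)) * pixel_size_um
}

# endpoint orientation folded into [0, pi), 0 = column axis
oracle_orientation <- function(path) {
  d <- path[nrow(path), ] - path[1, ]
  a <- atan2(d[1], d[2])
  if (a < 0) a <- a + pi
  if (a >= pi) a <- a - pi
  a
}

oracle_tortuosity <- function(path, pixel_size_um) {
  d <- path[nrow(path), ] - path[1, ]
  oracle_path_length(path, pixel_size_um) /
    (sqrt(sum(d^2)) * pixel_size_um)
}

# queue-based flood fill component labeling
oracle_flood_fill <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8L)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
          c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  nextlab <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    nextlab <- nextlab + 1L
    queue <- matrix(c(i, j), 1, 2)
    lab[i, j] <- nextlab
    while (nrow(queue) > 0L) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc) next
        if (mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- nextlab
          queue <- rbind(queue, q)
        }
      }
    }
  }
  lab
}

# mid-rank Spearman from first principles
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2)
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# all-pairs minimum dot-to-skeleton-pixel distances
oracle_min_dists <- function(dot_table, fiber_table) {
  out <- matrix(Inf, nrow(dot_table), nrow(fiber_table))
  for (i in seq_len(nrow(dot_table))) {
    for (f in seq_len(nrow(fiber_table))) {
      p <- fiber_table$path[[f]]
      out[i, f] <- sqrt(min((p[, 1] - dot_table$centroid_row[i])^2 +
                            (p[, 2] - dot_table$centroid_col[i])^2))
    }
  }
  out
}

# per-pixel grid-cell mean by explicit loops
oracle_cell_mean <- function(map, cell_row, cell_col, cell_size) {
  vals <- c()
  for (r in seq_len(nrow(map))) for (c_ in seq_len(ncol(map))) {
    if ((r - 1) %/% cell_size == cell_row &&
        (c_ - 1) %/% cell_size == cell_col && !is.na(map[r, c_]))
      vals <- c(vals, map[r, c_])
  }
  if (length(vals)) mean(vals) else NA_real_
}

# small convenience: match detected dots to ground truth by nearest centroid
match_dots <- function(truth, detected) {
  stopifnot(nrow(truth) == nrow(detected))
  idx <- sapply(seq_len(nrow(truth)), function(i) {
    which.min((detected$centroid_row - truth$centroid_row[i])^2 +
              (detected$centroid_col - truth$centroid_col[i])^2)
  })
  detected[idx, , drop = FALSE]
}
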