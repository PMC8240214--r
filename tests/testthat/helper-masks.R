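# Builders and independent brute-force oracles used across the suite.
# The oracles deliberately share only the *convention* with the package
# (surface = 6-connectivity boundary voxel centers, world = origin +
# index * spacing), not its code paths: plain voxel loops and an O(n^2)
# all-pairs nearest-point scan.

mask_of <- function(occ, grid, ...) structure_mask(occ, grid, ...)

box_mask <- function(grid, from, to) {
  occ <- array(FALSE, grid$shape)
  occ[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  structure_mask(occ, grid)
}

sphere_mask <- function(grid, center_vox, radius_vox) {
  cs <- list(seq_len(grid$shape[1]), seq_len(grid$shape[2]),
             seq_len(grid$shape[3]))
  d2 <- outer(outer((cs[[1]] - center_vox[1])^2,
                    (cs[[2]] - center_vox[2])^2, `+`),
              (cs[[3]] - center_vox[3])^2, `+`)
  structure_mask(d2 <= radius_vox^2, grid)
}

# 6-connected one-voxel dilation, by explicit shifts (clipped at the edges)
dilate6 <- function(mask) {
  occ <- mask$occupancy
  d <- dim(occ)
  out <- occ
  out[-1, , ] <- out[-1, , ] | occ[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | occ[-1, , ]
  out[, -1, ] <- out[, -1, ] | occ[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | occ[, -1, ]
  out[, , -1] <- out[, , -1] | occ[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | occ[, , -1]
  structure_mask(out, mask$grid)
}

# random smooth blob mask (one or two voxelized ellipsoids); keeps surfaces
# small enough for the O(n^2) oracle
random_blob_mask <- function(grid, allow_empty = FALSE) {
  one_blob <- function() {
    ctr <- stats::runif(3, 2, grid$shape - 1)
    ax <- stats::runif(3, 1, pmax(2, grid$shape / 3))
    cs <- list(seq_len(grid$shape[1]), seq_len(grid$shape[2]),
               seq_len(grid$shape[3]))
    outer(outer(((cs[[1]] - ctr[1]) / ax[1])^2,
                ((cs[[2]] - ctr[2]) / ax[2])^2, `+`),
          ((cs[[3]] - ctr[3]) / ax[3])^2, `+`) <= 1
  }
  occ <- one_blob()
  if (stats::runif(1) < 0.3) occ <- occ | one_blob()
  if (!allow_empty && !any(occ)) {
    occ[ceiling(grid$shape[1] / 2), ceiling(grid$shape[2] / 2),
        ceiling(grid$shape[3] / 2)] <- TRUE
  }
  structure_mask(occ, grid)
}

# --- oracles -------------------------------------------------------------

# boundary voxel centers by explicit per-voxel neighbour checks; iteration
# order (i fastest) matches column-major voxel order
oracle_surface_points <- function(mask) {
  occ <- mask$occupancy
  d <- dim(occ)
  sp <- mask$grid$spacing
  or <- mask$grid$origin
  pts <- vector("list", 0)
  n <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!occ[i, j, k]) next
    on_boundary <-
      i == 1L || !occ[i - 1L, j, k] || i == d[1] || !occ[i + 1L, j, k] ||
      j == 1L || !occ[i, j - 1L, k] || j == d[2] || !occ[i, j + 1L, k] ||
      k == 1L || !occ[i, j, k - 1L] || k == d[3] || !occ[i, j, k + 1L]
    if (on_boundary) {
      n <- n + 1L
      pts[[n]] <- c(or[1] + (i - 1) * sp[1],
                    or[2] + (j - 1) * sp[2],
                    or[3] + (k - 1) * sp[3])
    }
  }
  if (n == 0L) matrix(numeric(0), 0, 3) else do.call(rbind, pts)
}

# all-pairs nearest-point scan; same squared-distance expression as the
# production kernel so agreement can be asserted bit-for-bit
oracle_directed <- function(from_pts, to_pts) {
  apply(from_pts, 1, function(p) {
    dx <- p[1] - to_pts[, 1]
    dy <- p[2] - to_pts[, 2]
    dz <- p[3] - to_pts[, 3]
    sqrt(min(dx * dx + dy * dy + dz * dz))
  })
}

oracle_pooled <- function(a, b) {
  pa <- oracle_surface_points(a)
  pb <- oracle_surface_points(b)
  c(oracle_directed(pa, pb), oracle_directed(pb, pa))
}

oracle_msd <- function(a, b) mean(oracle_pooled(a, b))

# 95th percentile with linear interpolation, written out directly
oracle_hd95 <- function(a, b, p = 0.95) {
  d <- sort(oracle_pooled(a, b))
  n <- length(d)
  h <- 1 + (n - 1) * p
  lo <- floor(h)
  d[lo] + (h - lo) * (d[min(lo + 1, n)] - d[lo])
}

oracle_dice <- function(a, b)
  2 * sum(a$occupancy & b$occupancy) / (sum(a$occupancy) + sum(b$occupancy))

# closed-form Welch statistics for the two-sample comparison
oracle_welch <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# hand-built scored-table row for the statistics tests
table_row <- function(patient, observer, organ, group, status = "OK",
                      dsc = NA_real_, msd_mm = NA_real_, hd95_mm = NA_real_) {
  data.frame(patient = patient, observer = observer, organ = organ,
             group = group, status = status, dsc = dsc, msd_mm = msd_mm,
             hd95_mm = hd95_mm, vol_ref_cc = NA_real_,
             vol_test_cc = NA_real_, stringsAsFactors = FALSE)
}
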