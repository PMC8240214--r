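#' Extract the boundary surface of a mask as world-coordinate points
#'
#' A voxel belongs to the surface when it is occupied and at least one of its
#' six face-adjacent neighbours is background *or* lies outside the volume
#' (so a structure cropped by the scan edge, e.g. a spinal cord reaching the
#' most caudal slice, still has a closed surface). Points are the world mm
#' centers of those voxels, in column-major voxel order.
#'
#' @param mask a [structure_mask()].
#' @return A list of class `surface_points` with `points` (n x 3 matrix, mm)
#'   and `count`; empty mask gives a 0-row matrix.
#' @export
extract_surface <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  occ <- mask$occupancy
  d <- dim(occ)
  # a voxel is interior iff all six face neighbours exist and are occupied;
  # neighbours beyond the volume edge count as background
  interior <- occ
  shift_occ <- function(ax, dir) {
    nb <- array(FALSE, d)
    n <- d[ax]
    if (n > 1L) {
      if (ax == 1L) {
        if (dir > 0) nb[1:(n - 1), , ] <- occ[2:n, , ]
        else nb[2:n, , ] <- occ[1:(n - 1), , ]
      } else if (ax == 2L) {
        if (dir > 0) nb[, 1:(n - 1), ] <- occ[, 2:n, ]
        else nb[, 2:n, ] <- occ[, 1:(n - 1), ]
      } else {
        if (dir > 0) nb[, , 1:(n - 1)] <- occ[, , 2:n]
        else nb[, , 2:n] <- occ[, , 1:(n - 1)]
      }
    }
    nb
  }
  for (ax in 1:3)
    for (dir in c(-1L, 1L))
      interior <- interior & shift_occ(ax, dir)
  boundary <- occ & !interior
  ind <- which(boundary, arr.ind = TRUE)
  pts <- cbind(mask$grid$origin[1] + (ind[, 1] - 1) * mask$grid$spacing[1],
               mask$grid$origin[2] + (ind[, 2] - 1) * mask$grid$spacing[2],
               mask$grid$origin[3] + (ind[, 3] - 1) * mask$grid$spacing[3])
  dimnames(pts) <- NULL
  structure(list(points = pts, count = nrow(pts)), class = "surface_points")
}

#' Nearest-point distances from one surface to another
#'
#' For each point of `from_set`, the Euclidean mm distance to the closest
#' point of `to_set` (the directed component of the surface-distance metrics).
#'
#' @param from_set,to_set `surface_points` from [extract_surface()];
#'   `to_set` must be nonempty.
#' @return Numeric vector of length `from_set$count`.
#' @export
directed_distances <- function(from_set, to_set) {
  stopifnot(inherits(from_set, "surface_points"),
            inherits(to_set, "surface_points"))
  if (to_set$count == 0L)
    stop("cannot compute distances to an empty surface", call. = FALSE)
  if (from_set$count == 0L) return(numeric(0))
  cpp_nn_distances(from_set$points, to_set$points)$ab
}

# both directed distance vectors in one pass
pooled_surface_distances <- function(a, b) {
  sa <- extract_surface(a)
  sb <- extract_surface(b)
  if (sa$count == 0L || sb$count == 0L)
    stop("surface distances are undefined for an empty mask", call. = FALSE)
  cpp_nn_distances(sa$points, sb$points)
}

#' Dice similarity coefficient
#'
#' Volume-overlap ratio `2 |A n B| / (|A| + |B|)` on voxel counts: 1 for
#' perfect overlap, 0 for disjoint masks. Note that DSC is biased with
#' respect to structure volume: at a fixed absolute boundary error, larger
#' structures score higher than small ones, which is why the surface-distance
#' metrics [msd()] and [hd95()] are reported alongside.
#'
#' @param a,b [structure_mask()] objects on the same grid, not both empty.
#' @return DSC in `[0, 1]`; symmetric in its arguments.
#' @export
dice <- function(a, b) {
  assert_same_grid(a, b)
  na <- sum(a$occupancy)
  nb <- sum(b$occupancy)
  if (na + nb == 0L)
    stop("DSC is undefined when both masks are empty", call. = FALSE)
  2 * sum(a$occupancy & b$occupancy) / (na + nb)
}

#' Mean surface distance (mm)
#'
#' Symmetric MSD: the mean of the pooled multiset of nearest-point distances
#' from every boundary point of A to the surface of B and vice versa, in mm.
#' 0 iff the two surfaces coincide. `directed = TRUE` returns the two
#' one-directional means as well, for sensitivity analysis.
#'
#' @param a,b nonempty [structure_mask()] objects on the same grid.
#' @param directed if `TRUE`, return a list with `symmetric`, `a_to_b`,
#'   `b_to_a` means instead of a single number.
#' @return Mean surface distance in mm (or a list, see `directed`).
#' @export
msd <- function(a, b, directed = FALSE) {
  dd <- pooled_surface_distances(a, b)
  if (directed)
    list(symmetric = mean(c(dd$ab, dd$ba)),
         a_to_b = mean(dd$ab), b_to_a = mean(dd$ba))
  else mean(c(dd$ab, dd$ba))
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' The 95th percentile (linear interpolation between order statistics) of the
#' same pooled symmetric distance multiset used by [msd()] — a robust variant
#' of the maximum Hausdorff distance, insensitive to single outlier points.
#'
#' @param a,b nonempty [structure_mask()] objects on the same grid.
#' @param percentile percentile in (0, 100]; default 95.
#' @return Distance in mm; always <= the exact maximum Hausdorff distance.
#' @export
hd95 <- function(a, b, percentile = 95) {
  dd <- pooled_surface_distances(a, b)
  unname(stats::quantile(c(dd$ab, dd$ba), percentile / 100, type = 7))
}

#' Structure volume in cubic centimetres
#'
#' @param mask a [structure_mask()].
#' @return Occupied-voxel count times voxel volume, in cc.
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$occupancy) * prod(mask$grid$spacing) / 1000
}

#' Pairwise agreement between a reference and a test delineation
#'
#' Computes DSC, MSD and HD95 for one (reference, test) pair and maps the
#' degenerate cases to an explicit status instead of imputing penalty values:
#' `NOT_DELINEATED` (test absent), `TEST_EMPTY` / `REF_EMPTY` (one mask
#' delineated but empty: DSC = 0, distances undefined), `BOTH_EMPTY`, and
#' `OK` (all three metrics defined).
#'
#' @param reference [structure_mask()] or `NULL` (absent).
#' @param test [structure_mask()] or `NULL` (absent).
#' @return A list of class `agreement_result` with fields `dsc`, `msd_mm`,
#'   `hd95_mm` (NA where undefined), `volume_ref_cc`, `volume_test_cc`
#'   (NA where absent) and `status`.
#' @export
compare_masks <- function(reference, test) {
  res <- list(dsc = NA_real_, msd_mm = NA_real_, hd95_mm = NA_real_,
              volume_ref_cc = NA_real_, volume_test_cc = NA_real_,
              status = NA_character_)
  if (!is.null(reference)) res$volume_ref_cc <- volume_cc(reference)
  if (!is.null(test)) res$volume_test_cc <- volume_cc(test)
  if (is.null(test)) {
    res$status <- "NOT_DELINEATED"
  } else if (is.null(reference)) {
    stop("cannot score a delineation without a reference mask", call. = FALSE)
  } else {
    assert_same_grid(reference, test)
    ref_empty <- is_empty_mask(reference)
    test_empty <- is_empty_mask(test)
    if (ref_empty && test_empty) {
      res$status <- "BOTH_EMPTY"
    } else if (test_empty) {
      res$status <- "TEST_EMPTY"
      res$dsc <- 0
    } else if (ref_empty) {
      res$status <- "REF_EMPTY"
      res$dsc <- 0
    } else {
      res$status <- "OK"
      res$dsc <- dice(reference, test)
      dd <- pooled_surface_distances(reference, test)
      pooled <- c(dd$ab, dd$ba)
      res$msd_mm <- mean(pooled)
      res$hd95_mm <- unname(stats::quantile(pooled, 0.95, type = 7))
    }
  }
  structure(res, class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement %s: dsc=%.3f msd=%.2f mm hd95=%.2f mm vol ref/test %.2f/%.2f cc>\n",
              x$status, x$dsc, x$msd_mm, x$hd95_mm,
              x$volume_ref_cc, x$volume_test_cc))
  invisible(x)
}
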