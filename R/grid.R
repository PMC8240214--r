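#' @useDynLib oarconcord, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

GROUP_LEVELS <- c("ICG", "OTHER", "REFERENCE")

#' Voxel grid geometry
#'
#' An `image_grid` describes the axis-aligned voxel lattice that all structure
#' masks of one patient share: grid dimensions, anisotropic voxel spacing in
#' millimetres, and the world position of the first voxel center. The world
#' coordinate of 0-based voxel index `(i, j, k)` is
#' `origin + (i * sx, j * sy, k * sz)`. The third axis is treated as the
#' cranio-caudal axis (axial CT slices), with increasing index pointing
#' cranially.
#'
#' @param shape integer vector of length 3 `(nx, ny, nz)`, all entries >= 1.
#' @param spacing numeric vector of length 3, voxel spacing in mm, all > 0.
#' @param origin numeric vector of length 3, world position (mm) of voxel
#'   `(0, 0, 0)`.
#' @return An object of class `image_grid`.
#' @examples
#' grid <- image_grid(c(64, 64, 40), c(1, 1, 3))
#' @export
image_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L))
    stop("`shape` must be three integers >= 1", call. = FALSE)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes in mm", call. = FALSE)
  if (length(origin) != 3L || anyNA(origin))
    stop("`origin` must be three finite world coordinates in mm", call. = FALSE)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
format.image_grid <- function(x, ...) {
  sprintf("<image_grid %dx%dx%d, spacing (%g, %g, %g) mm, origin (%g, %g, %g)>",
          x$shape[1], x$shape[2], x$shape[3],
          x$spacing[1], x$spacing[2], x$spacing[3],
          x$origin[1], x$origin[2], x$origin[3])
}

#' @export
print.image_grid <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Binary structure mask on a voxel grid
#'
#' A `structure_mask` couples a binary occupancy array with its grid geometry
#' and study labels (organ, patient, observer, guideline group). An all-`FALSE`
#' occupancy is legal and means "delineated but empty"; a structure that was
#' never delineated is represented by the *absence* of a mask (`NULL`), not by
#' an empty one.
#'
#' @param occupancy logical (or coercible 0/1) 3D array matching `grid$shape`.
#' @param grid an [image_grid()].
#' @param organ,patient,observer character labels (free text; the simulator
#'   uses lower-case organ names such as `"parotid"`).
#' @param group one of `"ICG"`, `"OTHER"`, `"REFERENCE"`.
#' @return An object of class `structure_mask`.
#' @examples
#' g <- image_grid(c(10, 10, 10))
#' occ <- array(FALSE, c(10, 10, 10)); occ[4:6, 4:6, 4:6] <- TRUE
#' m <- structure_mask(occ, g, organ = "cube")
#' @export
structure_mask <- function(occupancy, grid, organ = "", patient = "",
                           observer = "", group = "REFERENCE") {
  stopifnot(inherits(grid, "image_grid"))
  if (is.numeric(occupancy) || is.integer(occupancy)) {
    bad <- !(occupancy %in% c(0, 1))
    if (any(bad)) stop("occupancy values must be strictly binary", call. = FALSE)
    occupancy <- array(occupancy > 0.5, dim = dim(occupancy))
  }
  if (!is.logical(occupancy) || length(dim(occupancy)) != 3L)
    stop("`occupancy` must be a logical 3D array", call. = FALSE)
  if (!identical(dim(occupancy), as.integer(grid$shape)))
    stop(sprintf("occupancy dimensions (%s) do not match grid shape (%s)",
                 paste(dim(occupancy), collapse = "x"),
                 paste(grid$shape, collapse = "x")), call. = FALSE)
  if (anyNA(occupancy)) stop("occupancy contains NA", call. = FALSE)
  group <- match.arg(group, GROUP_LEVELS)
  structure(list(occupancy = occupancy, grid = grid, organ = organ,
                 patient = patient, observer = observer, group = group),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask organ=%s patient=%s observer=%s group=%s: %d voxels on %s\n",
              x$organ, x$patient, x$observer, x$group,
              sum(x$occupancy), format(x$grid)))
  invisible(x)
}

is_empty_mask <- function(mask) !any(mask$occupancy)

#' Require two masks to live on the same voxel grid
#'
#' All pairwise metrics assume a shared grid; cross-grid comparisons are an
#' error, never silently resampled. Grids match when shapes are equal and
#' spacings agree within 1e-6 mm.
#'
#' @param a,b [structure_mask()] objects.
#' @return Invisibly `TRUE` if the grids match; otherwise an error naming both
#'   grids.
#' @export
assert_same_grid <- function(a, b) {
  stopifnot(inherits(a, "structure_mask"), inherits(b, "structure_mask"))
  ok <- identical(a$grid$shape, b$grid$shape) &&
    all(abs(a$grid$spacing - b$grid$spacing) <= 1e-6)
  if (!ok)
    stop(sprintf("grid mismatch: %s vs %s; resampling is not performed",
                 format(a$grid), format(b$grid)), call. = FALSE)
  invisible(TRUE)
}

# world mm coordinates of the voxel centers along each grid axis
axis_coords <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3])
}
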