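ORGAN_LEVELS <- c("brainstem", "cochlea", "glottic_area", "mandible",
                  "oral_cavity", "parotid", "pcm", "spinal_cord", "smg",
                  "supraglottic_larynx")
SHAPE_LEVELS <- c("ELLIPSOID", "TAPERED_CYLINDER", "THIN_CYLINDER", "ARCH",
                  "SLAB_STACK", "SHELL")

#' Parametric phantom specification for one organ-at-risk stand-in
#'
#' Each head-and-neck OAR is emulated by a simple parametric solid whose size
#' and position are given in world millimetres: ellipsoids for the compact
#' glands (parotid, submandibular gland, cochlea), a tapered cylinder for the
#' brainstem, a thin cylinder cropped at the caudal grid edge for the spinal
#' cord, a horseshoe arch for the mandible, elliptical slab stacks with a
#' lumen carve-out for oral cavity / larynx structures, and a thin curved
#' shell for the pharyngeal constrictor muscles. These are geometric
#' stand-ins sized like the real organs, not anatomical models.
#'
#' @param organ one of `"brainstem"`, `"cochlea"`, `"glottic_area"`,
#'   `"mandible"`, `"oral_cavity"`, `"parotid"`, `"pcm"`, `"spinal_cord"`,
#'   `"smg"`, `"supraglottic_larynx"`.
#' @param shape shape family; defaults to the organ's canonical family.
#' @param size named list of mm size parameters (see
#'   [default_phantom_specs()] for the fields each family uses).
#' @param center world mm position of the shape center.
#' @param edge_crop if `TRUE` the shape may be cut by the caudal grid edge
#'   (spinal cord) instead of being required to fit inside the grid.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(organ, shape = NULL, size = NULL, center = NULL,
                         edge_crop = FALSE) {
  organ <- match.arg(organ, ORGAN_LEVELS)
  def <- default_phantom_specs()[[organ]]
  if (is.null(shape)) shape <- def$shape
  shape <- match.arg(shape, SHAPE_LEVELS)
  if (is.null(size)) size <- def$size
  if (is.null(center)) center <- def$center
  structure(list(organ = organ, shape = shape, size = size,
                 center = as.numeric(center), edge_crop = edge_crop),
            class = "phantom_spec")
}

#' Default phantom specifications for the ten supported organs
#'
#' Sizes are chosen so the digitized volumes are of the same order as typical
#' adult head-and-neck organ volumes (cochlea ~0.1 cc up to oral cavity
#' ~70 cc) and all shapes fit the [default_grid()] field of view.
#'
#' @return Named list of `phantom_spec`-like lists (organ, shape, size,
#'   center, edge_crop).
#' @export
default_phantom_specs <- function() {
  list(
    brainstem = list(organ = "brainstem", shape = "TAPERED_CYLINDER",
                     size = list(r_cranial = 12, r_caudal = 8, length = 45),
                     center = c(64, 72, 112), edge_crop = FALSE),
    cochlea = list(organ = "cochlea", shape = "ELLIPSOID",
                   size = list(semiaxes = c(3, 3, 3)),
                   center = c(40, 64, 120), edge_crop = FALSE),
    glottic_area = list(organ = "glottic_area", shape = "SLAB_STACK",
                        size = list(semiaxes = c(10, 10), height = 18,
                                    lumen_r = 4),
                        center = c(64, 44, 30), edge_crop = FALSE),
    mandible = list(organ = "mandible", shape = "ARCH",
                    size = list(radius = 40, thickness = 5, height = 24,
                                opening_deg = 100),
                    center = c(64, 56, 66), edge_crop = FALSE),
    oral_cavity = list(organ = "oral_cavity", shape = "SLAB_STACK",
                       size = list(semiaxes = c(26, 22), height = 36,
                                   lumen_r = 5),
                       center = c(64, 48, 84), edge_crop = FALSE),
    parotid = list(organ = "parotid", shape = "ELLIPSOID",
                   size = list(semiaxes = c(18, 12, 25)),
                   center = c(32, 64, 84), edge_crop = FALSE),
    pcm = list(organ = "pcm", shape = "SHELL",
               size = list(radius = 18, thickness = 3, height = 30,
                           arc_deg = 180),
               center = c(64, 78, 60), edge_crop = FALSE),
    spinal_cord = list(organ = "spinal_cord", shape = "THIN_CYLINDER",
                       size = list(radius = 5, length = 90),
                       center = c(64, 84, 0), edge_crop = TRUE),
    smg = list(organ = "smg", shape = "ELLIPSOID",
               size = list(semiaxes = c(12, 10, 12)),
               center = c(44, 44, 48), edge_crop = FALSE),
    supraglottic_larynx = list(organ = "supraglottic_larynx",
                               shape = "SLAB_STACK",
                               size = list(semiaxes = c(14, 14), height = 24,
                                           lumen_r = 5),
                               center = c(64, 44, 52), edge_crop = FALSE)
  )
}

#' Default simulation grid
#'
#' 64 x 64 x 48 voxels at (2, 2, 3) mm — a 128 x 128 x 144 mm field of view
#' with CT-like anisotropy (3 mm axial slices).
#'
#' @return An [image_grid()].
#' @export
default_grid <- function() image_grid(c(64, 64, 48), c(2, 2, 3), c(0, 0, 0))

#' Voxelize a phantom specification on a grid
#'
#' Evaluates the parametric solid at every voxel center; purely deterministic
#' given the spec (per-patient anatomical variation enters through
#' `size_scale`, drawn by the cohort simulator).
#'
#' @param spec a [phantom_spec()] (or an entry of [default_phantom_specs()]).
#' @param grid an [image_grid()].
#' @param size_scale multiplicative factor applied to all mm size parameters
#'   (anatomy variation; 1 = nominal).
#' @param labels named list of labels (`patient`, `observer`, `group`) passed
#'   to [structure_mask()].
#' @return A [structure_mask()] for the organ.
#' @export
make_phantom <- function(spec, grid, size_scale = 1, labels = list()) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  cs <- axis_coords(grid)
  ctr <- spec$center
  sz <- lapply(spec$size, function(v) v * size_scale)
  occ <- switch(spec$shape,
    ELLIPSOID = {
      a2 <- ((cs$x - ctr[1]) / sz$semiaxes[1])^2
      b2 <- ((cs$y - ctr[2]) / sz$semiaxes[2])^2
      c2 <- ((cs$z - ctr[3]) / sz$semiaxes[3])^2
      outer(outer(a2, b2, `+`), c2, `+`) <= 1
    },
    TAPERED_CYLINDER = {
      zlo <- ctr[3] - sz$length / 2
      zhi <- ctr[3] + sz$length / 2
      frac <- pmin(pmax((cs$z - zlo) / (zhi - zlo), 0), 1)
      r <- sz$r_caudal + frac * (sz$r_cranial - sz$r_caudal)
      r[cs$z < zlo | cs$z > zhi] <- -1
      r2xy <- outer((cs$x - ctr[1])^2, (cs$y - ctr[2])^2, `+`)
      arr <- array(r2xy, dim = grid$shape)
      arr <= rep(r^2 * (r >= 0) - (r < 0), each = prod(grid$shape[1:2]))
    },
    THIN_CYLINDER = {
      # runs from the caudal grid edge (z = origin) upward for `length` mm
      zhi <- grid$origin[3] + sz$length
      r2xy <- outer((cs$x - ctr[1])^2, (cs$y - ctr[2])^2, `+`)
      inz <- cs$z <= zhi
      arr <- array(r2xy <= sz$radius^2, dim = grid$shape)
      arr & rep(inz, each = prod(grid$shape[1:2]))
    },
    ARCH = {
      dx <- outer(cs$x - ctr[1], rep(1, grid$shape[2]))
      dy <- outer(rep(1, grid$shape[1]), cs$y - ctr[2])
      rad <- sqrt(dx^2 + dy^2)
      ang <- atan2(dy, dx) * 180 / pi  # opening faces +x
      in_ring <- rad >= sz$radius - sz$thickness &
        rad <= sz$radius + sz$thickness &
        abs(ang) >= sz$opening_deg / 2
      inz <- abs(cs$z - ctr[3]) <= sz$height / 2
      array(in_ring, dim = grid$shape) &
        rep(inz, each = prod(grid$shape[1:2]))
    },
    SLAB_STACK = {
      # elliptical cylinder, mildly tapered toward both ends, minus a lumen
      zlo <- ctr[3] - sz$height / 2
      zhi <- ctr[3] + sz$height / 2
      frac <- (cs$z - zlo) / (zhi - zlo)
      taper <- 1 - 0.25 * (2 * frac - 1)^2
      taper[frac < 0 | frac > 1] <- 0
      npl <- prod(grid$shape[1:2])
      e2 <- outer(((cs$x - ctr[1]) / sz$semiaxes[1])^2,
                  ((cs$y - ctr[2]) / sz$semiaxes[2])^2, `+`)
      body <- array(e2, dim = grid$shape) <= rep(taper^2, each = npl)
      if (!is.null(sz$lumen_r) && sz$lumen_r > 0) {
        lum <- outer((cs$x - ctr[1])^2, (cs$y - ctr[2])^2, `+`) <=
          sz$lumen_r^2
        body <- body & !array(lum, dim = grid$shape)
      }
      body
    },
    SHELL = {
      dx <- outer(cs$x - ctr[1], rep(1, grid$shape[2]))
      dy <- outer(rep(1, grid$shape[1]), cs$y - ctr[2])
      rad <- sqrt(dx^2 + dy^2)
      ang <- atan2(dy, dx) * 180 / pi
      in_shell <- abs(rad - sz$radius) <= sz$thickness / 2 &
        abs(ang) <= sz$arc_deg / 2
      inz <- abs(cs$z - ctr[3]) <= sz$height / 2
      array(in_shell, dim = grid$shape) &
        rep(inz, each = prod(grid$shape[1:2]))
    },
    stop("unknown shape family: ", spec$shape)
  )
  if (!spec$edge_crop) {
    edge <- any(occ[1, , ]) || any(occ[grid$shape[1], , ]) ||
      any(occ[, 1, ]) || any(occ[, grid$shape[2], ]) ||
      any(occ[, , 1]) || any(occ[, , grid$shape[3]])
    if (edge)
      stop(sprintf("phantom `%s` does not fit inside the grid", spec$organ),
           call. = FALSE)
  }
  structure_mask(occ, grid, organ = spec$organ,
                 patient = labels$patient %||% "",
                 observer = labels$observer %||% "",
                 group = labels$group %||% "REFERENCE")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
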