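ERROR_MODES <- c("BOUNDARY_JITTER", "EXTENT_CRANIAL", "EXTENT_CAUDAL",
                 "SYSTEMATIC_SHIFT", "SUBSTRUCTURE_INCLUSION",
                 "WRONG_LOCATION", "SURROGATE_STRUCTURE", "OMISSION")

#' Configuration of one contouring-error mode
#'
#' The error taxonomy mirrors what is seen in multi-observer organ-at-risk
#' delineation audits: smooth boundary disagreement (`BOUNDARY_JITTER`),
#' cranio-caudal extent errors of whole axial slices (`EXTENT_CRANIAL`,
#' `EXTENT_CAUDAL`; e.g. a supraglottic larynx contoured 2-3 cm too caudally,
#' or a spinal cord stopped several slices too high), rigid misregistration
#' (`SYSTEMATIC_SHIFT`), inclusion of an adjacent substructure such as teeth
#' in a mandible (`SUBSTRUCTURE_INCLUSION`), gross wrong-location
#' delineations (`WRONG_LOCATION`, e.g. a region not containing the cochlea),
#' contouring a surrounding surrogate such as the spinal canal instead of the
#' cord (`SURROGATE_STRUCTURE`, realized as a uniform dilation), and not
#' contouring the organ at all (`OMISSION`).
#'
#' @param mode one of the modes above.
#' @param magnitude nonnegative size of the error: mm for
#'   `SYSTEMATIC_SHIFT` / `SUBSTRUCTURE_INCLUSION` (blob radius) /
#'   `WRONG_LOCATION` (displacement) / `SURROGATE_STRUCTURE` (dilation
#'   margin); whole axial slices for the `EXTENT` modes. Ignored for
#'   `OMISSION`.
#' @param probability chance in `[0, 1]` that the mode is applied to a given
#'   delineation.
#' @param grow for the `EXTENT` modes: `TRUE` adds slices beyond the current
#'   extent, `FALSE` removes occupied end slices.
#' @return An object of class `error_mode`.
#' @export
error_mode <- function(mode, magnitude = 0, probability = 1, grow = TRUE) {
  mode <- match.arg(mode, ERROR_MODES)
  stopifnot(magnitude >= 0, probability >= 0, probability <= 1)
  structure(list(mode = mode, magnitude = magnitude,
                 probability = probability, grow = isTRUE(grow)),
            class = "error_mode")
}

#' Observer profile: group, delineation habits and error modes
#'
#' The simulator's generative description of one radiation oncologist:
#' guideline group, per-organ probability of delineating the organ at all,
#' per-organ gross-error catalogue, and the magnitude and spatial correlation
#' of everyday boundary disagreement.
#'
#' @param observer identifier.
#' @param group `"ICG"` (uses the international consensus guidelines) or
#'   `"OTHER"`.
#' @param delineation_prob named numeric vector: per-organ probability in
#'   `[0, 1]` that the observer delineates the organ. A single unnamed value
#'   applies to all organs.
#' @param error_modes named list (per organ) of lists of [error_mode()]
#'   objects; organs without an entry get no gross errors.
#' @param jitter_scale_mm standard deviation (mm) of the smooth
#'   signed-distance perturbation applied to every delineated contour.
#' @param jitter_corr_mm spatial correlation length (mm) of that field.
#' @return An object of class `observer_profile`.
#' @export
observer_profile <- function(observer, group = c("ICG", "OTHER"),
                             delineation_prob = 1, error_modes = list(),
                             jitter_scale_mm = 1, jitter_corr_mm = 10) {
  group <- match.arg(group)
  stopifnot(all(delineation_prob >= 0), all(delineation_prob <= 1),
            jitter_scale_mm >= 0, jitter_corr_mm >= 0)
  structure(list(observer = observer, group = group,
                 delineation_prob = delineation_prob,
                 error_modes = error_modes,
                 jitter_scale_mm = jitter_scale_mm,
                 jitter_corr_mm = jitter_corr_mm),
            class = "observer_profile")
}

organ_prob <- function(profile, organ) {
  p <- profile$delineation_prob
  if (!is.null(names(p)) && organ %in% names(p)) unname(p[[organ]])
  else if (is.null(names(p))) unname(p[1])
  else stop("no delineation probability for organ: ", organ, call. = FALSE)
}

# ---- geometry helpers on occupancy arrays -------------------------------

translate_occ <- function(occ, offset_vox) {
  d <- dim(occ)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- offset_vox[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) { src[[ax]] <- 1:(d[ax] - o); dst[[ax]] <- (1 + o):d[ax] }
    else { src[[ax]] <- (1 - o):d[ax]; dst[[ax]] <- 1:(d[ax] + o) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- occ[src[[1]], src[[2]], src[[3]]]
  out
}

# bounding box of occupied voxels, padded and clamped to the grid
occ_bbox <- function(occ, pad_vox) {
  d <- dim(occ)
  ind <- which(occ, arr.ind = TRUE)
  lo <- pmax(apply(ind, 2, min) - pad_vox, 1L)
  hi <- pmin(apply(ind, 2, max) + pad_vox, d)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

# Signed distance (mm) to the mask surface: negative inside, positive
# outside. Center-to-center EDT distances overshoot the surface (which lies
# on the faces between voxels) by about half a voxel, so half the smallest
# spacing is subtracted from both sides; without this, sub-voxel jitter
# scales could never flip any voxel on coarse grids.
signed_distance <- function(occ, spacing) {
  d <- dim(occ)
  h2 <- min(spacing) / 2
  dout <- sqrt(cpp_edt_sq(as.vector(occ), d, spacing))     # 0 inside
  din <- sqrt(cpp_edt_sq(as.vector(!occ), d, spacing))     # 0 outside
  array(ifelse(dout > 0, dout - h2, h2 - din), dim = d)
}

# smooth zero-mean unit-sd Gaussian random field with the given correlation
# length, synthesized spectrally (white noise -> Gaussian low-pass)
smooth_noise_field <- function(dm, spacing, corr_mm) {
  w <- array(stats::rnorm(prod(dm)), dim = dm)
  if (corr_mm <= 0) return(w)
  freqs <- function(n, d) {
    i <- 0:(n - 1)
    i[i > n / 2] <- i[i > n / 2] - n
    i / (n * d)
  }
  k2 <- outer(outer(freqs(dm[1], spacing[1])^2,
                    freqs(dm[2], spacing[2])^2, `+`),
              freqs(dm[3], spacing[3])^2, `+`)
  filt <- exp(-2 * pi^2 * corr_mm^2 * k2)
  f <- Re(stats::fft(stats::fft(w) * filt, inverse = TRUE)) / prod(dm)
  s <- stats::sd(f)
  if (s == 0) array(0, dim = dm) else (f - mean(f)) / s
}

extent_error <- function(occ, n_slices, end = c("caudal", "cranial"),
                         grow = TRUE) {
  end <- match.arg(end)
  n_slices <- as.integer(round(n_slices))
  if (n_slices <= 0L || !any(occ)) return(occ)
  nz <- dim(occ)[3]
  zocc <- which(apply(occ, 3, any))
  zend <- if (end == "caudal") min(zocc) else max(zocc)
  step <- if (end == "caudal") -1L else 1L
  if (grow) {
    template <- occ[, , zend]
    for (s in seq_len(n_slices)) {
      z <- zend + step * s
      if (z < 1L || z > nz) break
      occ[, , z] <- occ[, , z] | template
    }
  } else {
    # removal walks inward from the end slice
    for (s in seq_len(n_slices)) {
      z <- zend - step * (s - 1L)
      if (z < 1L || z > nz) break
      occ[, , z] <- FALSE
    }
  }
  occ
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  n <- sqrt(sum(v^2))
  if (n == 0) c(1, 0, 0) else v / n
}

#' Apply configured contouring errors to a reference mask
#'
#' Modes are applied in a fixed order — OMISSION, WRONG_LOCATION,
#' SURROGATE_STRUCTURE, SYSTEMATIC_SHIFT, EXTENT errors,
#' SUBSTRUCTURE_INCLUSION, BOUNDARY_JITTER — each triggered independently
#' with its configured probability using the current R random stream.
#' Boundary jitter perturbs the signed distance field of the mask by a
#' smooth zero-mean Gaussian random field (sd = `jitter_scale_mm`,
#' correlation length = `jitter_corr_mm`) and re-thresholds at zero; it is
#' computed on a padded bounding-box crop of the structure for speed.
#'
#' @param reference a [structure_mask()].
#' @param configs list of [error_mode()] objects.
#' @param jitter_scale_mm,jitter_corr_mm boundary-jitter field parameters
#'   (mm); a scale of 0 disables jitter.
#' @return A perturbed [structure_mask()], or `NULL` when the OMISSION mode
#'   fires (organ not delineated).
#' @export
perturb <- function(reference, configs = list(), jitter_scale_mm = 0,
                    jitter_corr_mm = 10) {
  stopifnot(inherits(reference, "structure_mask"))
  grid <- reference$grid
  occ <- reference$occupancy
  cfg_of <- function(mode) Filter(function(cf) cf$mode == mode, configs)
  fires <- function(cf) stats::runif(1) < cf$probability

  for (cf in cfg_of("OMISSION")) if (fires(cf)) return(NULL)

  for (cf in cfg_of("WRONG_LOCATION")) if (fires(cf)) {
    u <- random_unit_vector()
    off <- as.integer(round(u * cf$magnitude / grid$spacing))
    occ <- translate_occ(occ, off)
  }

  for (cf in cfg_of("SURROGATE_STRUCTURE")) if (fires(cf) && any(occ)) {
    pad <- as.integer(ceiling(cf$magnitude / grid$spacing)) + 1L
    bb <- occ_bbox(occ, pad)
    sub <- occ[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
               drop = FALSE]
    dist <- sqrt(cpp_edt_sq(as.vector(sub), dim(sub), grid$spacing))
    occ[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <-
      array(dist <= cf$magnitude, dim = dim(sub))
  }

  for (cf in cfg_of("SYSTEMATIC_SHIFT")) if (fires(cf)) {
    u <- random_unit_vector()
    off <- as.integer(round(u * cf$magnitude / grid$spacing))
    occ <- translate_occ(occ, off)
  }

  for (cf in cfg_of("EXTENT_CRANIAL")) if (fires(cf) && any(occ))
    occ <- extent_error(occ, cf$magnitude, "cranial", cf$grow)
  for (cf in cfg_of("EXTENT_CAUDAL")) if (fires(cf) && any(occ))
    occ <- extent_error(occ, cf$magnitude, "caudal", cf$grow)

  for (cf in cfg_of("SUBSTRUCTURE_INCLUSION")) if (fires(cf) && any(occ)) {
    ind <- which(occ, arr.ind = TRUE)
    ctr_vox <- colMeans(ind)
    u <- random_unit_vector()
    # project the structure extent along u and center the blob just outside
    pts <- sweep(sweep(ind, 2, ctr_vox), 2, grid$spacing, `*`)
    reach <- max(pts %*% u)
    ctr_mm <- grid$origin + (ctr_vox - 1) * grid$spacing +
      u * (reach + 0.6 * cf$magnitude)
    cs <- axis_coords(grid)
    blob <- outer(outer((cs$x - ctr_mm[1])^2, (cs$y - ctr_mm[2])^2, `+`),
                  (cs$z - ctr_mm[3])^2, `+`) <= cf$magnitude^2
    occ <- occ | blob
  }

  jit <- cfg_of("BOUNDARY_JITTER")
  scale <- if (length(jit)) {
    on <- vapply(jit, fires, logical(1))
    if (any(on)) max(vapply(jit[on], `[[`, numeric(1), "magnitude"))
    else 0
  } else jitter_scale_mm
  if (scale > 0 && any(occ)) {
    pad <- as.integer(ceiling(4 * scale / grid$spacing)) + 2L
    bb <- occ_bbox(occ, pad)
    sub <- occ[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
               drop = FALSE]
    sdf <- signed_distance(sub, grid$spacing)
    f <- smooth_noise_field(dim(sub), grid$spacing, jitter_corr_mm) * scale
    occ[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <-
      sdf <= f
  }

  structure_mask(occ, grid, organ = reference$organ,
                 patient = reference$patient,
                 observer = reference$observer, group = reference$group)
}

#' Simulate one observer's submission for a set of reference organs
#'
#' Per organ, independently: with probability `1 - delineation_prob` the
#' organ is not delineated (absent); otherwise the reference is passed
#' through [perturb()] with the profile's error catalogue and jitter. Each
#' organ consumes its own deterministic substream of the seed when called via
#' [simulate_cohort()].
#'
#' @param references named list of reference [structure_mask()]s (one per
#'   organ).
#' @param profile an [observer_profile()].
#' @return Named list parallel to `references`; entries are perturbed masks
#'   or `NULL` (not delineated).
#' @export
simulate_observer <- function(references, profile) {
  out <- vector("list", length(references))
  names(out) <- names(references)
  for (organ in names(references)) {
    p <- organ_prob(profile, organ)
    if (stats::runif(1) >= p) next  # not delineated -> NULL
    m <- perturb(references[[organ]],
                 configs = profile$error_modes[[organ]] %||% list(),
                 jitter_scale_mm = profile$jitter_scale_mm,
                 jitter_corr_mm = profile$jitter_corr_mm)
    if (!is.null(m)) {
      m$observer <- profile$observer
      m$group <- profile$group
      out[[organ]] <- m
    }
  }
  out
}
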