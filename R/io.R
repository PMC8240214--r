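#' Read a binary structure mask from a NIfTI-1 volume
#'
#' Voxels with value > 0.5 are occupied (tolerant of lossy/interpolated
#' files). Geometry is taken from the coded qform/sform when present: spacing
#' from the column norms of its 3x3 part, origin from the translation. The
#' 3x3 part must be axis-aligned (identity up to axis permutation and sign);
#' oblique orientations are rejected rather than resampled. Files without a
#' coded transform fall back to `pixdim` with origin 0.
#'
#' @param path path to a `.nii` / `.nii.gz` file holding a 3D volume.
#' @param organ,patient,observer,group labels attached to the returned mask
#'   (see [structure_mask()]).
#' @return A [structure_mask()].
#' @export
read_mask <- function(path, organ = "", patient = "", observer = "",
                      group = "REFERENCE") {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop(sprintf("expected a 3D volume, got %dD: %s", length(d), path),
         call. = FALSE)
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  code <- if (is.null(xf)) 0L else attr(xf, "code")
  if (!is.null(xf) && !is.null(code) && code > 0L) {
    R3 <- unclass(xf)[1:3, 1:3]
    spacing <- sqrt(colSums(R3^2))
    if (any(spacing <= 0)) stop("non-positive spacing in ", path, call. = FALSE)
    # axis-aligned: exactly one non-negligible entry per column
    aligned <- all(apply(abs(R3) / rep(spacing, each = 3), 2,
                         function(col) sum(col > 1e-4) == 1L))
    if (!aligned)
      stop("unsupported oblique (non-axis-aligned) orientation in ", path,
           call. = FALSE)
    origin <- unclass(xf)[1:3, 4]
  } else {
    spacing <- RNifti::pixdim(img)[1:3]
    origin <- c(0, 0, 0)
  }
  grid <- image_grid(d, spacing, origin)
  structure_mask(array(as.vector(img) > 0.5, dim = d), grid,
                 organ = organ, patient = patient, observer = observer,
                 group = group)
}

#' Write a structure mask as a NIfTI-1 volume
#'
#' Occupancy is stored as uint8 0/1; spacing goes into both `pixdim` and an
#' sform (code 2) diagonal matrix carrying the origin, so that
#' `read_mask(write_mask(m, f))` reproduces occupancy exactly and spacing
#' within 1e-6 mm.
#'
#' @param mask a [structure_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  arr <- array(as.integer(mask$occupancy), dim = mask$grid$shape)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- mask$grid$spacing
  m <- diag(c(mask$grid$spacing, 1))
  m[1:3, 4] <- mask$grid$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  ok <- tryCatch({
    RNifti::writeNifti(img, path, datatype = "uint8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write mask to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

MANIFEST_COLS <- c("patient", "observer", "organ", "group", "path", "reference")

#' Read a cohort manifest (JSON or CSV)
#'
#' A manifest maps `(patient, observer, organ, group)` to one mask file each
#' and flags reference entries. JSON form:
#' `{"entries": [{"patient": ..., "observer": ..., "organ": ...,
#' "group": "ICG"|"OTHER"|"REFERENCE", "path": ..., "reference": bool}, ...]}`.
#' The CSV form has the same columns. Invariants checked here: at most one
#' entry per `(patient, observer, organ)`, and exactly one reference entry for
#' every `(patient, organ)` that has observer entries.
#'
#' @param path manifest file; format chosen by extension (`.json` vs `.csv`).
#' @return A data frame with columns
#'   `patient, observer, organ, group, path, reference`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    entries <- obj$entries
    if (is.null(entries)) stop("manifest JSON lacks an `entries` array",
                               call. = FALSE)
  } else {
    entries <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(MANIFEST_COLS, names(entries))
  if (length(missing_cols))
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  entries <- entries[MANIFEST_COLS]
  entries$reference <- as.logical(entries$reference)
  bad_group <- setdiff(unique(entries$group), GROUP_LEVELS)
  if (length(bad_group))
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  validate_manifest(entries)
  entries
}

validate_manifest <- function(entries) {
  key <- paste(entries$patient, entries$observer, entries$organ, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate manifest entry for (patient, observer, organ): ",
         gsub("\r", ", ", key[duplicated(key)][1]), call. = FALSE)
  obs <- entries[!entries$reference, , drop = FALSE]
  ref <- entries[entries$reference, , drop = FALSE]
  po_obs <- unique(paste(obs$patient, obs$organ, sep = "\r"))
  po_ref <- paste(ref$patient, ref$organ, sep = "\r")
  if (anyDuplicated(po_ref))
    stop("more than one reference entry for (patient, organ): ",
         gsub("\r", ", ", po_ref[duplicated(po_ref)][1]), call. = FALSE)
  missing_ref <- setdiff(po_obs, po_ref)
  if (length(missing_ref))
    stop("no reference entry for (patient, organ): ",
         gsub("\r", ", ", missing_ref[1]), call. = FALSE)
  invisible(entries)
}

#' Write a cohort manifest
#'
#' @param entries data frame as returned by [read_manifest()].
#' @param path output path (`.json` or `.csv`).
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(entries, path) {
  entries <- entries[MANIFEST_COLS]
  validate_manifest(entries)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(entries = entries), path, auto_unbox = FALSE,
                         digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(entries, path, row.names = FALSE)
  }
  invisible(path)
}

#' Load a cohort of masks grouped per (patient, organ)
#'
#' Reads every mask referenced by a manifest and bundles them per
#' `(patient, organ)`: one reference mask plus one entry per observer seen
#' anywhere in the manifest, `NULL` where that observer did not delineate the
#' organ ("not delineated"). All masks of a bundle are checked to share the
#' reference's grid.
#'
#' @param manifest path to a manifest file, or a data frame from
#'   [read_manifest()].
#' @param base_dir directory against which relative mask paths are resolved;
#'   defaults to the manifest's directory (or `"."` for data-frame input).
#' @return A list of bundles, each a list with elements `patient`, `organ`,
#'   `reference` ([structure_mask()]), `observers` (named list of masks or
#'   `NULL`), and `groups` (named character vector per observer).
#' @export
load_cohort <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  } else {
    validate_manifest(manifest)
    if (is.null(base_dir)) base_dir <- "."
  }
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base_dir, p))
  obs_rows <- manifest[!manifest$reference, , drop = FALSE]
  observers <- unique(obs_rows$observer)
  groups <- vapply(observers, function(o)
    obs_rows$group[match(o, obs_rows$observer)], character(1))
  names(groups) <- observers

  po <- unique(obs_rows[, c("patient", "organ")])
  po <- po[order(po$patient, po$organ), , drop = FALSE]
  lapply(seq_len(nrow(po)), function(r) {
    pat <- po$patient[r]; org <- po$organ[r]
    ref_row <- manifest[manifest$reference & manifest$patient == pat &
                          manifest$organ == org, , drop = FALSE]
    ref <- read_mask(resolve(ref_row$path[1]), organ = org, patient = pat,
                     observer = ref_row$observer[1], group = "REFERENCE")
    obs <- stats::setNames(vector("list", length(observers)), observers)
    for (o in observers) {
      row <- obs_rows[obs_rows$patient == pat & obs_rows$organ == org &
                        obs_rows$observer == o, , drop = FALSE]
      if (nrow(row)) {
        m <- read_mask(resolve(row$path[1]), organ = org, patient = pat,
                       observer = o, group = row$group[1])
        assert_same_grid(ref, m)
        obs[[o]] <- m
      }
    }
    list(patient = pat, organ = org, reference = ref, observers = obs,
         groups = groups)
  })
}
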