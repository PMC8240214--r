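# deterministic 32-bit sub-seed from a top-level seed plus a path of labels
# (FNV-1a style); splitting per patient/observer/organ keeps draws for one
# observer independent of how many other observers exist
derive_seed <- function(seed, ...) {
  s <- paste(c(as.character(seed), as.character(list(...))), collapse = "/")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(ch))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% .Machine$integer.max)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default two-group observer roster
#'
#' Seven observers using the international consensus guidelines (`ICG`) and
#' seven using other or no guidelines (`OTHER`). The groups differ in (a)
#' boundary-jitter scale — 1.0 mm for ICG vs 2.5 mm for OTHER, both with
#' 10 mm correlation length — and (b) per-organ delineation probabilities,
#' set to the per-group delineation percentages observed in multi-centre
#' head-and-neck audits (e.g. cochlea 59% vs 26%, spinal cord 63% vs 97%,
#' parotid 100% in both). Gross-error probabilities are an order of
#' magnitude rarer than jitter (0.03-0.10 per contour): petrous-bone
#' inclusion and wrong-location errors for the cochlea, teeth inclusion for
#' the mandible, canal-for-cord surrogate and too-high caudal stop for the
#' spinal cord, caudal overshoot for the supraglottic larynx, small
#' systematic shifts elsewhere. These defaults are configuration, not
#' estimates fitted to any particular study.
#'
#' @param n_icg,n_other observers per group.
#' @return List of [observer_profile()]s.
#' @export
default_profiles <- function(n_icg = 7, n_other = 7) {
  delin <- list(
    ICG = c(brainstem = 0.89, cochlea = 0.59, glottic_area = 0.48,
            mandible = 0.96, oral_cavity = 0.70, parotid = 1.00,
            pcm = 0.44, spinal_cord = 0.63, smg = 0.96,
            supraglottic_larynx = 0.41),
    OTHER = c(brainstem = 0.89, cochlea = 0.26, glottic_area = 0.29,
              mandible = 0.83, oral_cavity = 0.66, parotid = 1.00,
              pcm = 0.20, spinal_cord = 0.97, smg = 0.69,
              supraglottic_larynx = 0.26))
  gross <- function(scale_p) list(
    cochlea = list(
      error_mode("SUBSTRUCTURE_INCLUSION", magnitude = 6,
                 probability = 0.05 * scale_p),
      error_mode("WRONG_LOCATION", magnitude = 25,
                 probability = 0.03 * scale_p)),
    mandible = list(
      error_mode("SUBSTRUCTURE_INCLUSION", magnitude = 8,
                 probability = 0.06 * scale_p)),
    spinal_cord = list(
      error_mode("SURROGATE_STRUCTURE", magnitude = 3, probability = 0.05),
      error_mode("EXTENT_CAUDAL", magnitude = 4, probability = 0.06,
                 grow = FALSE)),
    supraglottic_larynx = list(
      error_mode("EXTENT_CAUDAL", magnitude = 7, probability = 0.05 * scale_p,
                 grow = TRUE)),
    brainstem = list(
      error_mode("EXTENT_CAUDAL", magnitude = 2, probability = 0.10 * scale_p,
                 grow = TRUE)),
    parotid = list(
      error_mode("SYSTEMATIC_SHIFT", magnitude = 3,
                 probability = 0.05 * scale_p)))
  mk <- function(i, group) {
    observer_profile(sprintf("%s%02d", if (group == "ICG") "I" else "O", i),
                     group = group,
                     delineation_prob = delin[[group]],
                     error_modes = gross(if (group == "ICG") 1 else 1.5),
                     jitter_scale_mm = if (group == "ICG") 1.0 else 2.5,
                     jitter_corr_mm = 10)
  }
  c(lapply(seq_len(n_icg), mk, group = "ICG"),
    lapply(seq_len(n_other), mk, group = "OTHER"))
}

#' Simulate a multi-observer delineation cohort
#'
#' For every patient, draws a per-organ anatomical size factor (uniform
#' within ±15% of nominal), voxelizes the reference phantoms, then generates
#' every observer's submission with [simulate_observer()]. All randomness is
#' derived from `seed` through per-(patient, observer, organ) substreams, so
#' the dataset is a pure function of `(specs, profiles, seed)` and adding an
#' observer does not change other observers' draws.
#'
#' @param n_patients number of patients (>= 1).
#' @param profiles list of [observer_profile()]s (at least one).
#' @param specs list of phantom specifications (defaults: brainstem, cochlea,
#'   mandible, parotid, smg, spinal_cord from [default_phantom_specs()]).
#' @param grid an [image_grid()]; defaults to [default_grid()].
#' @param seed integer seed.
#' @return An object of class `cohort_dataset`: `patients`, `organs`,
#'   `references[[patient]][[organ]]`, `observations[[patient]][[observer]]
#'   [[organ]]` (mask or `NULL`), `profiles`, `grid`, `seed`.
#' @export
simulate_cohort <- function(n_patients, profiles = default_profiles(),
                            specs = NULL, grid = default_grid(), seed = 1) {
  stopifnot(n_patients >= 1)
  if (!length(profiles)) stop("at least one observer profile is required",
                              call. = FALSE)
  if (is.null(specs))
    specs <- default_phantom_specs()[c("brainstem", "cochlea", "mandible",
                                       "parotid", "smg", "spinal_cord")]
  organs <- vapply(specs, `[[`, character(1), "organ")
  names(specs) <- organs
  patients <- sprintf("P%02d", seq_len(n_patients))
  observers <- vapply(profiles, `[[`, character(1), "observer")
  if (anyDuplicated(observers)) stop("duplicate observer identifiers",
                                     call. = FALSE)
  names(profiles) <- observers

  references <- list()
  observations <- list()
  for (pat in patients) {
    scales <- with_seed(derive_seed(seed, "anatomy", pat),
                        stats::setNames(stats::runif(length(organs), 0.85, 1.15),
                                        organs))
    refs <- lapply(organs, function(org)
      make_phantom(specs[[org]], grid, size_scale = scales[[org]],
                   labels = list(patient = pat, group = "REFERENCE")))
    names(refs) <- organs
    references[[pat]] <- refs
    obs_p <- list()
    for (obs in observers) {
      prof <- profiles[[obs]]
      sub <- stats::setNames(vector("list", length(organs)), organs)
      for (org in organs) {
        sub[org] <- list(with_seed(
          derive_seed(seed, "obs", pat, obs, org),
          simulate_observer(refs[org], prof)[[org]]))
      }
      obs_p[[obs]] <- sub
    }
    observations[[pat]] <- obs_p
  }
  structure(list(patients = patients, organs = unname(organs),
                 references = references, observations = observations,
                 profiles = profiles, grid = grid, seed = seed),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset: %d patients x %d observers x %d organs, seed %d>\n",
              length(x$patients), length(x$profiles), length(x$organs),
              x$seed))
  invisible(x)
}

# bundle view of a cohort_dataset, same shape as load_cohort() output
cohort_bundles <- function(dataset) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  groups <- vapply(dataset$profiles, `[[`, character(1), "group")
  names(groups) <- names(dataset$profiles)
  out <- list()
  for (pat in dataset$patients)
    for (org in dataset$organs) {
      obs <- lapply(dataset$observations[[pat]], `[[`, org)
      out[[length(out) + 1L]] <- list(
        patient = pat, organ = org,
        reference = dataset$references[[pat]][[org]],
        observers = obs, groups = groups)
    }
  out
}

#' Export a simulated cohort to NIfTI masks plus a manifest
#'
#' Writes one `.nii.gz` per delineated mask under `dir/masks/` and a JSON
#' manifest compatible with [load_cohort()].
#'
#' @param dataset a `cohort_dataset` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
export_cohort <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  add <- function(pat, obs, org, group, path, ref)
    rows[[length(rows) + 1L]] <<- data.frame(
      patient = pat, observer = obs, organ = org, group = group,
      path = path, reference = ref, stringsAsFactors = FALSE)
  for (pat in dataset$patients)
    for (org in dataset$organs) {
      p <- file.path("masks", sprintf("%s_%s_ref.nii.gz", pat, org))
      write_mask(dataset$references[[pat]][[org]], file.path(dir, p))
      add(pat, "REF", org, "REFERENCE", p, TRUE)
      for (obs in names(dataset$observations[[pat]])) {
        m <- dataset$observations[[pat]][[obs]][[org]]
        if (is.null(m)) next
        p <- file.path("masks", sprintf("%s_%s_%s.nii.gz", pat, obs, org))
        write_mask(m, file.path(dir, p))
        add(pat, obs, org, m$group, p, FALSE)
      }
    }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.json")
  write_manifest(manifest, path)
  invisible(path)
}
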