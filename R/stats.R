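#' Score every (patient, observer, organ) slot of a cohort
#'
#' Applies [compare_masks()] to each observer slot of each bundle and returns
#' the long-format table all cohort statistics operate on, one row per slot
#' (including `NOT_DELINEATED` slots), deterministically ordered by
#' (patient, observer, organ).
#'
#' @param bundles bundles from [load_cohort()], or a `cohort_dataset` from
#'   [simulate_cohort()].
#' @return Data frame with columns `patient, observer, organ, group, status,
#'   dsc, msd_mm, hd95_mm, vol_ref_cc, vol_test_cc`.
#' @export
build_table <- function(bundles) {
  if (inherits(bundles, "cohort_dataset")) bundles <- cohort_bundles(bundles)
  rows <- list()
  for (b in bundles) {
    if (is.null(b$reference))
      stop("missing reference mask for (", b$patient, ", ", b$organ, ")",
           call. = FALSE)
    for (obs in names(b$observers)) {
      res <- compare_masks(b$reference, b$observers[[obs]])
      rows[[length(rows) + 1L]] <- data.frame(
        patient = b$patient, observer = obs, organ = b$organ,
        group = unname(b$groups[[obs]]), status = res$status,
        dsc = res$dsc, msd_mm = res$msd_mm, hd95_mm = res$hd95_mm,
        vol_ref_cc = res$volume_ref_cc, vol_test_cc = res$volume_test_cc,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$patient, tab$observer, tab$organ), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Per-organ cohort summary: median and range per metric, counts per group
#'
#' Medians and (min, max) ranges are computed over status-`OK` rows only
#' (undefined metrics are excluded, never imputed); delineation counts are
#' computed over all slots. The median of an even-sized sample is the
#' midpoint of the two central order statistics.
#'
#' @param table scored table from [build_table()].
#' @return Data frame, one row per organ: `organ, n_ok`,
#'   `dsc_median/dsc_min/dsc_max`, `msd_median/...`, `hd95_median/...`,
#'   `n_delineated_icg, n_slots_icg, n_delineated_other, n_slots_other`.
#' @export
summarize_per_organ <- function(table) {
  stopifnot(nrow(table) > 0)
  organs <- sort(unique(table$organ))
  stat3 <- function(x) {
    if (!length(x)) c(NA_real_, NA_real_, NA_real_)
    else c(stats::median(x), min(x), max(x))
  }
  rows <- lapply(organs, function(org) {
    sub <- table[table$organ == org, , drop = FALSE]
    ok <- sub[sub$status == "OK", , drop = FALSE]
    counts <- vapply(c("ICG", "OTHER"), function(g) {
      gs <- sub[sub$group == g, , drop = FALSE]
      c(sum(gs$status != "NOT_DELINEATED"), nrow(gs))
    }, numeric(2))
    d <- stat3(ok$dsc); m <- stat3(ok$msd_mm); h <- stat3(ok$hd95_mm)
    data.frame(organ = org, n_ok = nrow(ok),
               dsc_median = d[1], dsc_min = d[2], dsc_max = d[3],
               msd_median = m[1], msd_min = m[2], msd_max = m[3],
               hd95_median = h[1], hd95_min = h[2], hd95_max = h[3],
               n_delineated_icg = counts[1, "ICG"],
               n_slots_icg = counts[2, "ICG"],
               n_delineated_other = counts[1, "OTHER"],
               n_slots_other = counts[2, "OTHER"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Delineation rate for one organ within one observer group
#'
#' Fraction of cohort slots for `(organ, group)` in which the organ was
#' delineated at all; `NOT_DELINEATED` slots count against the rate, empty
#' delineations count for it.
#'
#' @param table scored table from [build_table()].
#' @param organ organ label.
#' @param group `"ICG"` or `"OTHER"`.
#' @return Ratio in `[0, 1]`.
#' @export
delineation_rate <- function(table, organ, group) {
  sub <- table[table$organ == organ & table$group == group, , drop = FALSE]
  if (!nrow(sub))
    stop(sprintf("no slots for organ `%s` in group `%s`", organ, group),
         call. = FALSE)
  mean(sub$status != "NOT_DELINEATED")
}

#' Two-group comparison of an agreement metric
#'
#' Independent two-sided t-test of ICG vs OTHER on one metric, Welch
#' (unequal variance) by default. The unit of analysis is either every
#' delineation (`PER_DELINEATION`, pooling all status-OK rows per group —
#' note these are pseudo-replicated, the same observer contributes many
#' rows) or observers (`PER_OBSERVER`, testing per-observer mean values).
#'
#' @param table scored table from [build_table()].
#' @param metric `"MSD"`, `"DSC"` or `"HD95"`.
#' @param unit `"PER_DELINEATION"` (default) or `"PER_OBSERVER"`.
#' @param test `"welch"` (default) or `"student"` (pooled variance).
#' @return A list of class `group_comparison`: `metric, unit, test,
#'   mean_icg, mean_other, t, df, p, n_icg, n_other`. Swapping the group
#'   labels flips the sign of `t` and leaves `p` unchanged.
#' @export
group_ttest <- function(table, metric = c("MSD", "DSC", "HD95"),
                        unit = c("PER_DELINEATION", "PER_OBSERVER"),
                        test = c("welch", "student")) {
  metric <- match.arg(metric)
  unit <- match.arg(unit)
  test <- match.arg(test)
  col <- c(MSD = "msd_mm", DSC = "dsc", HD95 = "hd95_mm")[[metric]]
  ok <- table[table$status == "OK" & !is.na(table[[col]]), , drop = FALSE]
  vals <- function(g) {
    sub <- ok[ok$group == g, , drop = FALSE]
    if (unit == "PER_OBSERVER")
      unname(tapply(sub[[col]], sub$observer, mean))
    else sub[[col]]
  }
  x <- vals("ICG"); y <- vals("OTHER")
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least two units with defined ", metric,
         call. = FALSE)
  ht <- stats::t.test(x, y, alternative = "two.sided",
                      var.equal = (test == "student"))
  structure(list(metric = metric, unit = unit, test = test,
                 mean_icg = mean(x), mean_other = mean(y),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, n_icg = length(x), n_other = length(y)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<%s %s comparison (%s): ICG mean %.3f (n=%d) vs OTHER %.3f (n=%d), t=%.3f, df=%.1f, p=%.4g>\n",
    x$metric, x$unit, x$test, x$mean_icg, x$n_icg, x$mean_other, x$n_other,
    x$t, x$df, x$p))
  invisible(x)
}
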