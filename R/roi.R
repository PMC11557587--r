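# Beta-PET core: per-scan normalization to the within-brain mean, mask-based
# SUV extraction per (region, coronal slice, hemisphere), and the F3 - F1
# difference table.
#
# "SUV" here is mean-normalized uptake: each scan is divided by its in-brain
# mean, so region values are dimensionless and comparable across subjects
# and sessions without dose or body-weight information.

#' Normalize a volume to its within-brain mean
#'
#' Divides every in-mask voxel by the in-mask mean; out-of-mask voxels are
#' set to 0. After normalization the in-mask mean is 1 (to 1e-10), and the
#' operation is idempotent.
#'
#' @param vol a [volume_image()].
#' @param brain_mask logical 3D array on the same grid.
#' @return normalized `volume_image`.
#' @export
normalize_to_brain_mean <- function(vol, brain_mask) {
  assert_that(inherits(vol, "volume_image"), "vol must be a volume_image")
  assert_that(identical(dim(vol$data), dim(brain_mask)),
              "volume and brain mask grids differ")
  assert_that(any(brain_mask), "brain mask is empty")
  mu <- mean(vol$data[brain_mask])
  assert_that(is.finite(mu) && mu > 0,
              sprintf("in-mask mean is %g; cannot normalize", mu),
              "betapet_normalization_error")
  out <- vol
  d <- vol$data / mu
  d[!brain_mask] <- 0
  out$data <- d
  out
}

#' Extract per-object SUV records from a normalized volume
#'
#' One record per (region, coronal slice, hemisphere) mask object; the SUV is
#' the arithmetic mean of the normalized voxel values inside that object.
#'
#' @param vol a normalized [volume_image()] (see [normalize_to_brain_mean()]).
#' @param masks a [region_mask_set()] on the same grid.
#' @return data.frame with columns `subject_id`, `group`, `session`,
#'   `region`, `slice_index`, `bregma_mm`, `hemisphere`, `suv`.
#' @export
extract_suvs <- function(vol, masks) {
  assert_that(inherits(vol, "volume_image"), "vol must be a volume_image")
  assert_that(inherits(masks, "region_mask_set"), "masks must be a region_mask_set")
  assert_that(identical(dim(vol$data), dim(masks$brain_mask)),
              "volume and mask set grids differ")
  n <- length(masks$objects)
  out <- data.frame(
    subject_id = rep(vol$subject_id, n),
    group = rep(vol$group, n),
    session = rep(vol$session, n),
    region = vapply(masks$objects, function(o) o$region, character(1)),
    slice_index = vapply(masks$objects, function(o) o$slice, integer(1)),
    hemisphere = vapply(masks$objects, function(o) o$hemisphere, character(1)),
    suv = vapply(masks$objects, function(o) mean(vol$data[o$idx]), numeric(1)),
    stringsAsFactors = FALSE)
  out$bregma_mm <- bregma_mm(vol, out$slice_index)
  out[, c("subject_id", "group", "session", "region", "slice_index",
          "bregma_mm", "hemisphere", "suv")]
}

#' Difference two sessions' SUV records into a delta-SUV table
#'
#' Rows are matched one-to-one on (subject, region, slice, hemisphere);
#' `delta_suv = suv_f3 - suv_f1` exactly. Unmatched keys raise an error that
#' lists them.
#'
#' @param f1,f3 SUV record data.frames from [extract_suvs()] for the first
#'   and second session.
#' @return data.frame of class `delta_suv_table` with columns `subject_id`,
#'   `group`, `region`, `slice_index`, `bregma_mm`, `hemisphere`, `suv_f1`,
#'   `suv_f3`, `delta_suv`.
#' @export
compute_delta_suv <- function(f1, f3) {
  key <- function(d) paste(d$subject_id, d$region, d$slice_index, d$hemisphere,
                           sep = "|")
  k1 <- key(f1); k3 <- key(f3)
  assert_that(!anyDuplicated(k1) && !anyDuplicated(k3),
              "duplicate (subject, region, slice, hemisphere) records")
  miss1 <- setdiff(k3, k1); miss3 <- setdiff(k1, k3)
  if (length(miss1) || length(miss3)) {
    abort(sprintf("unmatched records between sessions: %s",
                  paste(utils::head(c(miss1, miss3), 10), collapse = "; ")),
          "betapet_pairing_error")
  }
  m <- match(k1, k3)
  out <- data.frame(subject_id = f1$subject_id, group = f1$group,
                    region = f1$region, slice_index = f1$slice_index,
                    bregma_mm = f1$bregma_mm, hemisphere = f1$hemisphere,
                    suv_f1 = f1$suv, suv_f3 = f3$suv[m],
                    stringsAsFactors = FALSE)
  out$delta_suv <- out$suv_f3 - out$suv_f1
  class(out) <- c("delta_suv_table", "data.frame")
  out
}

#' Delta-SUV table for a whole cohort
#'
#' Runs the full beta-PET core on every subject: normalize both sessions to
#' the in-brain mean, extract per-object SUVs, and difference F3 - F1.
#'
#' @param cohort a `synthetic_cohort` (or any list with `subjects` holding
#'   `f1` / `f3` volume images, `brain_mask`, `mask_set`).
#' @return a `delta_suv_table` covering all subjects.
#' @export
cohort_delta_table <- function(cohort) {
  tabs <- lapply(cohort$subjects, function(s) {
    f1 <- extract_suvs(normalize_to_brain_mean(s$f1, cohort$brain_mask),
                       cohort$mask_set)
    f3 <- extract_suvs(normalize_to_brain_mean(s$f3, cohort$brain_mask),
                       cohort$mask_set)
    compute_delta_suv(f1, f3)
  })
  out <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  class(out) <- c("delta_suv_table", "data.frame")
  out
}

#' Group mean delta-SUV for one region
#'
#' Mean over all of the region's rows for the group, slices and hemispheres
#' pooled unweighted (one value per mask object, as fed to the mixed model).
#' This is the network-map node value. Supply `voxel_counts` to weight
#' objects by voxel count instead.
#'
#' @param table a `delta_suv_table`.
#' @param region region name.
#' @param group group label.
#' @param voxel_counts optional named numeric of per-row voxel counts for
#'   voxel-weighted pooling (default unweighted).
#' @return mean delta-SUV.
#' @export
region_group_mean <- function(table, region, group, voxel_counts = NULL) {
  sel <- table$region == region & table$group == group
  assert_that(any(sel), sprintf("no rows for region %s, group %s", region, group))
  if (is.null(voxel_counts)) {
    mean(table$delta_suv[sel])
  } else {
    stats::weighted.mean(table$delta_suv[sel], voxel_counts[sel])
  }
}

#' Per-subject mean delta-SUV for one region
#'
#' One value per subject: the mean of that subject's rows in the region.
#' This is the classifier feature and the x-axis of the behavior
#' correlations.
#'
#' @param table a `delta_suv_table`.
#' @param region region name.
#' @return data.frame with columns `subject_id`, `group`, `mean_delta_suv`.
#' @export
subject_region_mean <- function(table, region) {
  sel <- table$region == region
  assert_that(any(sel), sprintf("no rows for region %s", region))
  sub <- table[sel, ]
  agg <- stats::aggregate(delta_suv ~ subject_id + group, data = sub, FUN = mean)
  names(agg)[names(agg) == "delta_suv"] <- "mean_delta_suv"
  agg[order(agg$subject_id), c("subject_id", "group", "mean_delta_suv")]
}

#' Per-subject feature table over all regions
#'
#' Wide table: one row per subject, one column per region holding the
#' subject's region-mean delta-SUV. Input to the classifiers.
#'
#' @param table a `delta_suv_table`.
#' @param regions region order (default: first-appearance order in the table).
#' @return data.frame with `subject_id`, `group`, then one numeric column per
#'   region.
#' @export
feature_table <- function(table, regions = unique(table$region)) {
  out <- NULL
  for (r in regions) {
    sm <- subject_region_mean(table, r)
    names(sm)[3] <- r
    out <- if (is.null(out)) sm else merge(out, sm, by = c("subject_id", "group"))
  }
  assert_that(!anyNA(out), "missing features after merge")
  out[order(out$subject_id), ]
}
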