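# Synthetic phantom cohorts and activity traces.
#
# The generator states a simple world with the statistical structure the
# analysis assumes: an ellipsoidal "brain" on a regular grid, box-shaped
# regions inside it (mirrored across the midline, except the prefrontal
# midline structures), a per-(group, region) uptake change between the two
# sessions, and i.i.d. Gaussian voxel noise. Group effects are stated in
# normalized-uptake units: the generator solves for raw region values such
# that after per-scan normalization to the in-brain mean, the planted
# delta-SUV equals the configured effect exactly at zero noise.

DEFAULT_REGIONS <- c("BA", "PLC", "ILC", "DH", "VH", "SB", "LEC", "MEC")

#' Default per-(group, region) uptake effects
#'
#' Session-2 minus session-1 normalized-uptake change planted per region, for
#' a CON-like group (intact contextual-memory network: enhancement in
#' amygdala / prefrontal / lateral-entorhinal nodes) and an LS-like group in
#' which that enhancement is largely absent.
#'
#' @return data.frame with columns `group`, `region`, `effect`.
#' @export
default_group_effects <- function() {
  data.frame(
    group  = rep(c("CON", "LS"), each = 8),
    region = rep(DEFAULT_REGIONS, 2),
    effect = c(0.15,  0.12,  0.11, -0.043, 0.052, 0.016,   0.059,  0.0086,
               0.049, 0.032, 0.046, -0.028, 0.023, -0.0024, -0.012, -0.00075),
    stringsAsFactors = FALSE
  )
}

#' Default region box specifications
#'
#' Boxes defined on a canonical 40 x 60 x 30 grid: inclusive index ranges
#' for x (left copy), y (coronal slices) and z. Bilateral regions are
#' mirrored about the grid's midline; PLC and ILC straddle the midline and
#' are analysed as one object per slice. BA spans 12 coronal slices on the
#' canonical grid; the others span 4-8. For other grid shapes the boxes are
#' rescaled proportionally (half-open interval scaling, which preserves
#' disjointness); grids below roughly 20 voxels per axis are rejected by
#' [phantom_config()].
#'
#' @param grid_shape target grid (x, y, z voxel counts).
#' @return list of per-region specs (name, x/y/z ranges, hemispheres,
#'   baseline uptake).
#' @export
default_region_specs <- function(grid_shape = c(40L, 60L, 30L)) {
  canonical <- list(
    list(name = "PLC", x = c(18, 23), y = c(44, 49), z = c(18, 22),
         hemispheres = "BOTH", baseline = 1.2),
    list(name = "ILC", x = c(18, 23), y = c(44, 49), z = c(13, 17),
         hemispheres = "BOTH", baseline = 1.2),
    list(name = "BA",  x = c(10, 14), y = c(26, 37), z = c(10, 14),
         hemispheres = "LR", baseline = 1.2),
    list(name = "DH",  x = c(15, 18), y = c(24, 31), z = c(18, 22),
         hemispheres = "LR", baseline = 1.2),
    list(name = "VH",  x = c(10, 14), y = c(20, 27), z = c(16, 19),
         hemispheres = "LR", baseline = 1.2),
    list(name = "SB",  x = c(13, 16), y = c(16, 21), z = c(12, 15),
         hemispheres = "LR", baseline = 1.2),
    list(name = "LEC", x = c(8, 11),  y = c(12, 17), z = c(14, 17),
         hemispheres = "LR", baseline = 1.2),
    list(name = "MEC", x = c(13, 16), y = c(12, 17), z = c(8, 11),
         hemispheres = "LR", baseline = 1.2)
  )
  s <- grid_shape / c(40, 60, 30)
  if (all(s == 1)) return(canonical)
  rescale <- function(rng, sc) {
    lo <- floor(sc * (rng[1] - 1)) + 1
    hi <- max(lo, floor(sc * rng[2] - 1e-9))
    c(lo, hi)
  }
  lapply(canonical, function(spec) {
    spec$x <- rescale(spec$x, s[1])
    spec$y <- rescale(spec$y, s[2])
    spec$z <- rescale(spec$z, s[3])
    spec
  })
}

#' Phantom cohort configuration
#'
#' @param grid_shape voxels per axis (x, y, z).
#' @param voxel_size_mm voxel size; default matches the scanner matrix
#'   (0.78 x 0.78 x 0.8 mm).
#' @param n_subjects_per_group named counts; default 9 CON-like / 15 LS-like
#'   usable scan pairs.
#' @param region_specs list of region box specs (see
#'   [default_region_specs()]); must fit inside the brain ellipsoid and not
#'   overlap one another.
#' @param group_effects data.frame (group, region, effect) of planted
#'   session-2 minus session-1 changes in normalized-uptake units.
#' @param brain_baseline baseline uptake outside the named regions.
#' @param noise_sd voxel noise standard deviation (normalized-uptake units).
#' @param smooth_sigma optional isotropic Gaussian blur (voxels) applied to
#'   the noise for spatial realism; 0 disables (default: smoothing is an
#'   upstream preprocessing step, out of scope).
#' @param bregma_index y index of the bregma plane carried as metadata.
#' @param seed RNG seed; the cohort is bit-reproducible from (config, seed).
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(40L, 60L, 30L),
                           voxel_size_mm = c(0.78, 0.78, 0.8),
                           n_subjects_per_group = c(CON = 9L, LS = 15L),
                           region_specs = NULL,
                           group_effects = default_group_effects(),
                           brain_baseline = 1,
                           noise_sd = 0.05,
                           smooth_sigma = 0,
                           bregma_index = 45,
                           seed = 1L) {
  assert_that(length(grid_shape) == 3 && all(grid_shape >= 8),
              "grid_shape must be 3 values >= 8", "betapet_config_error")
  if (is.null(region_specs)) {
    assert_that(all(grid_shape >= c(20, 30, 15)),
                "default region specs need a grid of at least 20 x 30 x 15",
                "betapet_config_error")
    region_specs <- default_region_specs(grid_shape)
  }
  assert_that(all(voxel_size_mm > 0), "voxel sizes must be > 0",
              "betapet_config_error")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0", "betapet_config_error")
  assert_that(all(n_subjects_per_group >= 1) && length(n_subjects_per_group) == 2 &&
                !is.null(names(n_subjects_per_group)),
              "n_subjects_per_group must be two named positive counts",
              "betapet_config_error")
  assert_that(all(c("group", "region", "effect") %in% names(group_effects)),
              "group_effects needs columns group, region, effect",
              "betapet_config_error")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 n_subjects_per_group = n_subjects_per_group,
                 region_specs = region_specs, group_effects = group_effects,
                 brain_baseline = brain_baseline, noise_sd = noise_sd,
                 smooth_sigma = smooth_sigma, bregma_index = bregma_index,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# ellipsoid brain mask, semi-axes 0.46 * grid extent
phantom_brain_mask <- function(grid_shape) {
  ctr <- (grid_shape + 1) / 2
  semi <- 0.46 * grid_shape
  x <- (seq_len(grid_shape[1]) - ctr[1]) / semi[1]
  y <- (seq_len(grid_shape[2]) - ctr[2]) / semi[2]
  z <- (seq_len(grid_shape[3]) - ctr[3]) / semi[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  r2 <= 1
}

# materialize box specs into a region_mask_set (validates containment/overlap)
phantom_mask_set <- function(config) {
  dims <- config$grid_shape
  brain <- phantom_brain_mask(dims)
  mid <- floor(dims[1] / 2)
  objects <- list()
  box_idx <- function(xr, yr, s, zr) {
    which(slice.index(brain, 1) %in% xr[1]:xr[2] &
            slice.index(brain, 2) == s &
            slice.index(brain, 3) %in% zr[1]:zr[2])
  }
  for (spec in config$region_specs) {
    assert_that(all(spec$x >= 1 & spec$x <= dims[1]) &&
                  all(spec$y >= 1 & spec$y <= dims[2]) &&
                  all(spec$z >= 1 & spec$z <= dims[3]),
                sprintf("region %s box exceeds the grid", spec$name),
                "betapet_config_error")
    for (s in spec$y[1]:spec$y[2]) {
      if (identical(spec$hemispheres, "BOTH")) {
        objects[[length(objects) + 1]] <-
          list(region = spec$name, slice = as.integer(s), hemisphere = "BOTH",
               idx = box_idx(spec$x, spec$y, s, spec$z))
      } else {
        xl <- spec$x
        xr <- c(dims[1] + 1 - xl[2], dims[1] + 1 - xl[1])  # mirror about midline
        objects[[length(objects) + 1]] <-
          list(region = spec$name, slice = as.integer(s), hemisphere = "L",
               idx = box_idx(xl, spec$y, s, spec$z))
        objects[[length(objects) + 1]] <-
          list(region = spec$name, slice = as.integer(s), hemisphere = "R",
               idx = box_idx(xr, spec$y, s, spec$z))
      }
    }
  }
  tryCatch(region_mask_set(brain, objects),
           betapet_mask_error = function(e) abort(conditionMessage(e),
                                                  "betapet_config_error"))
}

# separable Gaussian blur of a 3D array (used only when smooth_sigma > 0);
# edge-replicated padding, kernel truncated at 3 sigma
gauss_blur3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv_axis1 <- function(a) {
    d <- dim(a)
    apad <- a[c(rep(1L, r), seq_len(d[1]), rep(d[1], r)), , , drop = FALSE]
    out <- array(0, d)
    for (j in seq_along(k)) {
      out <- out + k[j] * apad[j:(j + d[1] - 1L), , , drop = FALSE]
    }
    out
  }
  x <- conv_axis1(x)
  x <- aperm(conv_axis1(aperm(x, c(2, 3, 1))), c(3, 1, 2))
  x <- aperm(conv_axis1(aperm(x, c(3, 1, 2))), c(2, 3, 1))
  x
}

#' Generate a phantom PET cohort
#'
#' For every subject, two aligned volumes are produced: a session-1 scan with
#' baseline uptake and a session-2 scan in which each region's uptake is
#' shifted so that the mean-normalized delta-SUV equals the configured
#' per-(group, region) effect exactly (at zero noise). Independent Gaussian
#' voxel noise is added to each scan; voxels outside the brain are zero.
#'
#' @param config a [phantom_config()].
#' @return object of class `synthetic_cohort`: list with `subjects` (each
#'   holding `subject_id`, `group`, `f1`, `f3` volume images), `brain_mask`,
#'   `mask_set`, and the generating `config`.
#' @export
make_phantom_cohort <- function(config) {
  assert_that(inherits(config, "phantom_config"), "config must be a phantom_config")
  masks <- phantom_mask_set(config)
  dims <- config$grid_shape
  brain <- masks$brain_mask
  M <- sum(brain)

  # session-1 raw baseline field
  base <- array(0, dim = dims)
  base[brain] <- config$brain_baseline
  region_idx <- list()
  region_base <- numeric(0)
  for (spec in config$region_specs) {
    idx <- unlist(lapply(masks$objects,
                         function(o) if (o$region == spec$name) o$idx else NULL))
    region_idx[[spec$name]] <- idx
    region_base[spec$name] <- spec$baseline %||% config$brain_baseline
    base[idx] <- region_base[spec$name]
  }
  mu1 <- mean(base[brain])

  # session-2 raw field per group: solve for the normalization-compensated
  # region values v_r = t_r * mu3 with t_r the target normalized value
  # b_r / mu1 + e_r, and mu3 the implied in-brain mean.
  f3_field <- function(group) {
    eff <- config$group_effects
    e <- stats::setNames(rep(0, length(region_idx)), names(region_idx))
    rows <- eff[eff$group == group, , drop = FALSE]
    e[rows$region[rows$region %in% names(e)]] <-
      rows$effect[rows$region %in% names(e)]
    if (all(e == 0)) return(base)  # bit-identical sessions when nothing is planted
    m <- vapply(region_idx, length, integer(1))
    t_r <- region_base[names(region_idx)] / mu1 + e[names(region_idx)]
    non_region_sum <- M * mu1 - sum(m * region_base[names(region_idx)])
    denom <- M - sum(m * t_r)
    assert_that(denom > 0, "planted effects too large for this brain volume",
                "betapet_config_error")
    mu3 <- non_region_sum / denom
    out <- base
    for (r in names(region_idx)) out[region_idx[[r]]] <- t_r[[r]] * mu3
    out
  }

  groups <- names(config$n_subjects_per_group)
  fields3 <- stats::setNames(lapply(groups, f3_field), groups)

  set.seed(config$seed)
  subjects <- list()
  for (g in groups) {
    for (i in seq_len(config$n_subjects_per_group[[g]])) {
      sid <- sprintf("%s%02d", g, i)
      mk <- function(field, session) {
        vox <- field
        if (config$noise_sd > 0) {
          eps <- array(stats::rnorm(prod(dims), 0, config$noise_sd), dim = dims)
          if (config$smooth_sigma > 0) eps <- gauss_blur3(eps, config$smooth_sigma)
          vox <- vox + eps
        }
        vox[!brain] <- 0
        volume_image(vox, config$voxel_size_mm, subject_id = sid, group = g,
                     session = session, bregma_index = config$bregma_index)
      }
      subjects[[sid]] <- list(subject_id = sid, group = g,
                              f1 = mk(base, "F1"), f3 = mk(fields3[[g]], "F3"))
    }
  }
  structure(list(subjects = subjects, brain_mask = brain, mask_set = masks,
                 config = config, seed = config$seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  groups <- table(vapply(x$subjects, function(s) s$group, character(1)))
  cat(sprintf("<synthetic_cohort  %s subjects (%s), grid %s, seed %d>\n",
              length(x$subjects),
              paste(sprintf("%s=%d", names(groups), groups), collapse = ", "),
              paste(x$config$grid_shape, collapse = "x"), x$seed))
  invisible(x)
}

#' Activity trace configuration
#'
#' States the world of a conditioning-chamber session: frame-wise activity
#' scores at a fixed frame rate, freezing bouts during which the score is 0,
#' and movement frames with scores uniform on (threshold, activity_max].
#' Per-group bout rate and bout-duration distribution control the freezing
#' level; `bout_rate_for_target()` converts a target freezing percentage.
#'
#' @param frame_rate frames per second (default 30; video tracking default).
#' @param session_length_s session duration in seconds (default 480, the
#'   8-min contextual-memory test).
#' @param threshold activity score separating freezing from movement in the
#'   generated world (downstream scoring uses its own configured threshold).
#' @param activity_max upper bound of movement activity scores.
#' @param groups named list; per group: `n` traces, `bout_rate` (bouts per
#'   minute), `dur_mean` and `dur_shape` (gamma bout-duration distribution,
#'   seconds). Defaults target ~73% freezing for the CON-like and ~45% for
#'   the LS-like group with 6-s mean bouts.
#' @param seed RNG seed.
#' @return object of class `trace_config`.
#' @export
trace_config <- function(frame_rate = 30, session_length_s = 480,
                         threshold = 0.05, activity_max = 1,
                         groups = list(
                           CON = list(n = 10, bout_rate = 7.3, dur_mean = 6,
                                      dur_shape = 9),
                           LS = list(n = 18, bout_rate = 4.5, dur_mean = 6,
                                     dur_shape = 9)),
                         seed = 1L) {
  assert_that(frame_rate > 0, "frame_rate must be > 0", "betapet_config_error")
  assert_that(session_length_s > 0, "session_length_s must be > 0",
              "betapet_config_error")
  assert_that(threshold >= 0 && activity_max > threshold,
              "need 0 <= threshold < activity_max", "betapet_config_error")
  for (g in groups) {
    assert_that(g$bout_rate >= 0 && (g$bout_rate == 0 || g$dur_mean > 0),
                "bout_rate must be >= 0 and dur_mean > 0", "betapet_config_error")
  }
  structure(list(frame_rate = frame_rate, session_length_s = session_length_s,
                 threshold = threshold, activity_max = activity_max,
                 groups = groups, seed = as.integer(seed)),
            class = "trace_config")
}

#' Bout rate implied by a target freezing percentage
#' @param target_pct desired mean percent freezing over the session
#' @param dur_mean_s mean bout duration in seconds
#' @return bouts per minute
#' @export
bout_rate_for_target <- function(target_pct, dur_mean_s) {
  target_pct / 100 * 60 / dur_mean_s
}

# place n non-overlapping frame-quantized bouts; returns data.frame of frame
# spans. Gap frames distributed randomly (>= 2 frames between bouts).
place_bouts <- function(n_frames, dur_frames) {
  n <- length(dur_frames)
  if (n == 0) return(data.frame(start_frame = integer(0), n_frames = integer(0)))
  min_gap <- 2L
  free <- n_frames - sum(dur_frames) - min_gap * (n + 1L)
  assert_that(free >= 0,
              "bout_rate too high: bouts cannot be placed without overlap",
              "betapet_generation_error")
  w <- stats::rexp(n + 1L)
  extra <- floor(free * w / sum(w))
  gaps <- min_gap + extra
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + dur_frames[i]
  }
  data.frame(start_frame = starts, n_frames = dur_frames)
}

#' Generate synthetic activity traces
#'
#' Bout count per trace is deterministic (`round(bout_rate * minutes)`);
#' durations are gamma-distributed, truncated below at 2 s, quantized to the
#' frame grid and placed uniformly at random without overlap. The
#' ground-truth bout list (frame-quantized) is attached to each trace for
#' oracle testing.
#'
#' @param config a [trace_config()].
#' @param session session label stamped on each trace (e.g. `"F3"`).
#' @return list of `activity_trace` objects; each is a list with
#'   `subject_id`, `group`, `session`, `time_s`, `activity_score`,
#'   `frame_rate`, and `truth_bouts` (data.frame `start_s`, `duration_s`).
#' @export
make_activity_traces <- function(config, session = "F3") {
  assert_that(inherits(config, "trace_config"), "config must be a trace_config")
  fr <- config$frame_rate
  n_frames <- round(config$session_length_s * fr)
  set.seed(config$seed)
  traces <- list()
  for (g in names(config$groups)) {
    spec <- config$groups[[g]]
    for (i in seq_len(spec$n)) {
      n_bouts <- round(spec$bout_rate * config$session_length_s / 60)
      if (n_bouts > 0) {
        shape <- spec$dur_shape %||% 9
        dur <- stats::rgamma(n_bouts, shape = shape, rate = shape / spec$dur_mean)
        dur <- pmax(dur, 2)
        dur_frames <- pmax(round(dur * fr), ceiling(2 * fr))
        spans <- place_bouts(n_frames, dur_frames)
      } else {
        spans <- data.frame(start_frame = integer(0), n_frames = integer(0))
      }
      score <- stats::runif(n_frames, config$threshold, config$activity_max)
      inactive <- rep(FALSE, n_frames)
      for (b in seq_len(nrow(spans))) {
        sel <- (spans$start_frame[b] + 1L):(spans$start_frame[b] + spans$n_frames[b])
        inactive[sel] <- TRUE
      }
      score[inactive] <- 0
      traces[[length(traces) + 1]] <- structure(
        list(subject_id = sprintf("%s%02d", g, i), group = g, session = session,
             time_s = (seq_len(n_frames) - 1) / fr,
             activity_score = score, frame_rate = fr,
             truth_bouts = data.frame(start_s = spans$start_frame / fr,
                                      duration_s = spans$n_frames / fr)),
        class = "activity_trace")
    }
  }
  traces
}

#' Write a cohort + traces fixture bundle to disk
#'
#' Volumes and masks go out as NIfTI, traces and the subject table as CSV,
#' and a JSON manifest records every file with its MD5 checksum, so two runs
#' from the same config and seed are checksum-identical.
#'
#' @param cohort a `synthetic_cohort`.
#' @param traces list of `activity_trace` objects (may be empty).
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
write_fixture_bundle <- function(cohort, traces, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(out_dir),
              sprintf("cannot create output directory '%s'", out_dir),
              "betapet_io_error")
  vx <- cohort$config$voxel_size_mm
  files <- character(0)
  wn <- function(arr, name) {
    p <- file.path(out_dir, name)
    write_nifti(arr, p, vx)
    files[[length(files) + 1]] <<- p
    p
  }
  lab <- mask_set_to_labels(cohort$mask_set)
  wn(cohort$brain_mask, "brain_mask.nii")
  wn(lab$labels, "region_labels.nii")
  utils::write.csv(
    data.frame(region_id = unname(lab$region_ids), region = names(lab$region_ids)),
    file.path(out_dir, "region_ids.csv"), row.names = FALSE)
  files <- c(files, file.path(out_dir, "region_ids.csv"))

  subj_rows <- list()
  for (s in cohort$subjects) {
    f1 <- wn(s$f1$data, sprintf("%s_F1.nii", s$subject_id))
    f3 <- wn(s$f3$data, sprintf("%s_F3.nii", s$subject_id))
    subj_rows[[s$subject_id]] <- data.frame(
      subject_id = s$subject_id, group = s$group,
      f1_path = basename(f1), f3_path = basename(f3),
      trace_path = NA_character_, stringsAsFactors = FALSE)
  }
  for (tr in traces) {
    p <- file.path(out_dir, sprintf("%s_%s_trace.csv", tr$subject_id, tr$session))
    utils::write.csv(data.frame(frame_index = seq_along(tr$time_s) - 1L,
                                time_s = tr$time_s,
                                activity_score = tr$activity_score),
                     p, row.names = FALSE)
    files <- c(files, p)
    if (tr$subject_id %in% names(subj_rows)) {
      subj_rows[[tr$subject_id]]$trace_path <- basename(p)
    }
  }
  subj_tab <- do.call(rbind, subj_rows)
  utils::write.csv(subj_tab, file.path(out_dir, "subjects.csv"), row.names = FALSE)
  files <- c(files, file.path(out_dir, "subjects.csv"))

  manifest <- list(
    seed = cohort$seed,
    grid_shape = cohort$config$grid_shape,
    voxel_size_mm = vx,
    n_subjects = length(cohort$subjects),
    files = data.frame(file = basename(files),
                       md5 = vapply(files, file_md5, character(1)),
                       row.names = NULL))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
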