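# Ordinal-trends canonical-variates analysis on two-condition scan sets.
#
# Concrete, documented variant (the published approach is a closed-source
# script): PCA of the voxel- and subject-centered scan matrix; candidate PC
# subsets are the singletons and pairs among the leading max_pcs components;
# within a subset the combination weights are the least-squares fit of the
# condition indicator on the subset expressions (equivalently, the
# combination maximizing the subject-wise F1 -> F3 expression trend); each
# candidate's unit-norm pattern is scored by AIC = m log(RSS/m) + 2k, where
# RSS comes from regressing the pattern expression on the condition
# indicator (subject intercepts vanish under subject centering), m is the
# scan count and k the subset size. The lowest AIC wins, and the pattern is
# oriented so the majority of subjects increase from F1 to F3.

#' Build a scan matrix from a cohort
#'
#' Each scan is normalized to its in-brain mean (consistently with the ROI
#' pipeline), flattened over the brain mask, and stacked subject-major with
#' condition order F1 then F3. The per-voxel grand mean is removed and
#' stored, so the original data are recoverable exactly.
#'
#' @param cohort a `synthetic_cohort`-style list (`subjects` with `f1`/`f3`
#'   volume images, `brain_mask`).
#' @param groups optional subset of group labels to include (e.g. `"CON"`
#'   for fitting; the held-out group is projected later).
#' @return object of class `scan_matrix`: centered matrix `X` (scans x
#'   voxels), `voxel_mean`, row metadata (`subject_id`, `condition`,
#'   `group`), `mask_idx`, `grid_dim`, `voxel_size_mm`.
#' @export
build_scan_matrix <- function(cohort, groups = NULL) {
  subs <- cohort$subjects
  if (!is.null(groups)) {
    subs <- Filter(function(s) s$group %in% groups, subs)
  }
  assert_that(length(subs) >= 1, "no subjects selected")
  for (s in subs) {
    assert_that(!is.null(s$f1) && !is.null(s$f3),
                sprintf("subject %s is missing a condition", s$subject_id))
  }
  mask <- cohort$brain_mask
  mask_idx <- which(mask)
  rows <- list(); sid <- character(0); cond <- character(0); grp <- character(0)
  for (s in subs) {
    for (session in c("f1", "f3")) {
      v <- normalize_to_brain_mean(s[[session]], mask)
      rows[[length(rows) + 1]] <- v$data[mask_idx]
      sid <- c(sid, s$subject_id)
      cond <- c(cond, toupper(session))
      grp <- c(grp, s$group)
    }
  }
  X <- do.call(rbind, rows)
  voxel_mean <- colMeans(X)
  Xc <- sweep(X, 2, voxel_mean)
  structure(list(X = Xc, voxel_mean = voxel_mean, subject_id = sid,
                 condition = cond, group = grp, mask_idx = mask_idx,
                 grid_dim = dim(mask), voxel_size_mm =
                   subs[[1]]$f1$voxel_size_mm),
            class = "scan_matrix")
}

#' Construct a scan matrix from an explicit data matrix
#'
#' Lower-level companion to [build_scan_matrix()] for data that are already
#' flattened (or not voxel data at all): rows are scans, columns variables.
#' The per-column grand mean is removed and stored.
#'
#' @param X numeric matrix, scans x variables (two rows per subject).
#' @param subject_id,condition,group per-row metadata; `condition` must be
#'   `"F1"` / `"F3"`.
#' @param voxel_size_mm carried through to any volume outputs.
#' @return a `scan_matrix`
#' @export
scan_matrix <- function(X, subject_id, condition, group = rep(NA_character_,
                                                              nrow(X)),
                        voxel_size_mm = c(1, 1, 1)) {
  assert_that(is.matrix(X) && nrow(X) == length(subject_id) &&
                nrow(X) == length(condition),
              "X rows and metadata lengths must agree")
  assert_that(all(condition %in% c("F1", "F3")), "condition must be F1 or F3")
  cnt <- table(subject_id)
  assert_that(all(cnt == 2), "each subject needs exactly two rows (F1 and F3)")
  voxel_mean <- colMeans(X)
  structure(list(X = sweep(X, 2, voxel_mean), voxel_mean = voxel_mean,
                 subject_id = as.character(subject_id),
                 condition = as.character(condition),
                 group = as.character(group),
                 mask_idx = seq_len(ncol(X)),
                 grid_dim = c(ncol(X), 1L, 1L),
                 voxel_size_mm = voxel_size_mm),
            class = "scan_matrix")
}

#' @export
print.scan_matrix <- function(x, ...) {
  cat(sprintf("<scan_matrix  %d scans (%d subjects) x %d voxels>\n",
              nrow(x$X), length(unique(x$subject_id)), ncol(x$X)))
  invisible(x)
}

# remove each subject's mean scan (isolates within-subject condition change)
subject_center <- function(X, subject_id) {
  for (s in unique(subject_id)) {
    r <- subject_id == s
    X[r, ] <- sweep(X[r, , drop = FALSE], 2, colMeans(X[r, , drop = FALSE]))
  }
  X
}

# PCA of a wide matrix via the scan-space Gram matrix
gram_pca <- function(Y, k_max) {
  G <- tcrossprod(Y)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  keep <- which(e$values > tol)
  assert_that(length(keep) >= 1, "scan matrix has no usable components",
              "betapet_fit_error")
  keep <- keep[seq_len(min(length(keep), k_max))]
  d <- sqrt(e$values[keep])
  V <- crossprod(Y, e$vectors[, keep, drop = FALSE]) %*% diag(1 / d,
                                                              length(keep))
  list(V = V, d = d, eigenvalues = e$values[keep])
}

#' Fit the ordinal-trends model
#'
#' @param sm a [build_scan_matrix()] result (typically the group expected to
#'   carry the trend, e.g. CON-like subjects only).
#' @param max_pcs number of leading PCs eligible for selection (default 5).
#' @return object of class `ort_model`: PC basis (`pcs`, `eigenvalues`),
#'   `selected` PC indices, unit-norm voxel `pattern` (positive weight =
#'   uptake increases F1 to F3 for the majority trend), `aic` table,
#'   `voxel_mean`, grid metadata, and the fitted per-scan expressions.
#' @export
fit_ort <- function(sm, max_pcs = 5) {
  assert_that(inherits(sm, "scan_matrix"), "sm must be a scan_matrix")
  n_sub <- length(unique(sm$subject_id))
  assert_that(n_sub >= 3, "ordinal-trends fit needs at least 3 subjects")
  Y <- subject_center(sm$X, sm$subject_id)
  pca <- gram_pca(Y, max_pcs)
  K <- ncol(pca$V)
  dvec <- ifelse(sm$condition == "F3", 0.5, -0.5)
  subsets <- c(lapply(seq_len(K), identity),
               if (K >= 2) utils::combn(K, 2, simplify = FALSE))
  m <- nrow(Y)
  aic_rows <- list()
  best <- NULL
  for (S in subsets) {
    E <- Y %*% pca$V[, S, drop = FALSE]
    XtX <- crossprod(E)
    if (rcond(XtX) < 1e-12) next
    w <- solve(XtX, crossprod(E, dvec))
    pat <- pca$V[, S, drop = FALSE] %*% w
    nrm <- sqrt(sum(pat^2))
    if (nrm == 0) next
    pat <- pat / nrm
    e_pat <- drop(Y %*% pat)
    beta <- sum(e_pat * dvec) / sum(dvec^2)
    rss <- sum((e_pat - beta * dvec)^2)
    aic <- m * log(rss / m) + 2 * length(S)
    aic_rows[[length(aic_rows) + 1]] <-
      data.frame(subset = paste(S, collapse = "+"), k = length(S), aic = aic)
    if (is.null(best) || aic < best$aic) {
      best <- list(S = S, pattern = drop(pat), aic = aic)
    }
  }
  assert_that(!is.null(best), "no candidate PC subset was fittable",
              "betapet_fit_error")
  # orient: majority of subjects should increase F1 -> F3
  e_full <- drop(sm$X %*% best$pattern)
  inc <- subject_deltas(e_full, sm$subject_id, sm$condition)
  if (sum(inc > 0) < length(inc) / 2) {
    best$pattern <- -best$pattern
    e_full <- -e_full
  }
  structure(list(pcs = pca$V, eigenvalues = pca$eigenvalues,
                 selected = best$S, pattern = best$pattern,
                 aic = do.call(rbind, aic_rows), best_aic = best$aic,
                 voxel_mean = sm$voxel_mean, mask_idx = sm$mask_idx,
                 grid_dim = sm$grid_dim, voxel_size_mm = sm$voxel_size_mm,
                 expressions = data.frame(subject_id = sm$subject_id,
                                          condition = sm$condition,
                                          group = sm$group,
                                          expression = e_full)),
            class = "ort_model")
}

#' @export
print.ort_model <- function(x, ...) {
  cat(sprintf("<ort_model  PCs {%s} of %d, AIC = %.2f, %d voxels>\n",
              paste(x$selected, collapse = ","), ncol(x$pcs), x$best_aic,
              length(x$pattern)))
  invisible(x)
}

# per-subject expression(F3) - expression(F1)
subject_deltas <- function(expr, subject_id, condition) {
  sids <- unique(subject_id)
  vapply(sids, function(s) {
    expr[subject_id == s & condition == "F3"] -
      expr[subject_id == s & condition == "F1"]
  }, numeric(1))
}

#' Nodal expression of a fitted pattern
#'
#' Projects each scan of the fitted set onto the pattern and z-scores the
#' expressions across all scans.
#'
#' @param model an `ort_model`.
#' @return data.frame of class `nodal_expression` with one row per subject:
#'   `subject_id`, `group`, `z_f1`, `z_f3`, `delta` (= z_f3 - z_f1).
#' @export
nodal_expression <- function(model) {
  ex <- model$expressions
  z <- as.numeric(scale(ex$expression))
  wide <- data.frame(
    subject_id = unique(ex$subject_id),
    group = ex$group[match(unique(ex$subject_id), ex$subject_id)],
    z_f1 = z[ex$condition == "F1"][match(unique(ex$subject_id),
                                         ex$subject_id[ex$condition == "F1"])],
    z_f3 = z[ex$condition == "F3"][match(unique(ex$subject_id),
                                         ex$subject_id[ex$condition == "F3"])])
  wide$delta <- wide$z_f3 - wide$z_f1
  class(wide) <- c("nodal_expression", "data.frame")
  wide
}

#' Ordinal statistic: number of subjects whose expression increases
#'
#' @param ne a [nodal_expression()] result (or any data.frame with `z_f1`,
#'   `z_f3`).
#' @return integer count of subjects with `z_f3 > z_f1`.
#' @export
ordinal_statistic <- function(ne) {
  assert_that(all(c("z_f1", "z_f3") %in% names(ne)),
              "need z_f1 and z_f3 columns")
  sum(ne$z_f3 > ne$z_f1)
}

#' Permutation test for the ordinal trend
#'
#' Null distribution by within-subject condition-label flips: per iteration
#' each subject's F1/F3 labels are swapped independently with probability
#' 1/2, the full model fit and ordinal statistic are recomputed, and the
#' add-one p-value `(1 + #{perm >= observed}) / (1 + n_iter)` is returned
#' (never exactly 0; floor `1/(n_iter + 1)`).
#'
#' @param sm a `scan_matrix`.
#' @param n_iter permutation iterations (default 500).
#' @param max_pcs passed to [fit_ort()].
#' @param seed RNG seed.
#' @return list of class `ort_permutation`: `p`, `observed`,
#'   `perm_statistics`, `n_iter`, `seed`.
#' @export
permutation_test <- function(sm, n_iter = 500, max_pcs = 5, seed = 1L) {
  assert_that(n_iter >= 1, "n_iter must be >= 1")
  observed <- ordinal_statistic(nodal_expression(fit_ort(sm, max_pcs)))
  sids <- unique(sm$subject_id)
  set.seed(seed)
  perm_stats <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    flip <- sids[stats::runif(length(sids)) < 0.5]
    smp <- sm
    fl <- smp$subject_id %in% flip
    smp$condition[fl] <- ifelse(smp$condition[fl] == "F1", "F3", "F1")
    perm_stats[it] <- ordinal_statistic(nodal_expression(fit_ort(smp, max_pcs)))
  }
  p <- (1 + sum(perm_stats >= observed)) / (1 + n_iter)
  structure(list(p = p, observed = observed, perm_statistics = perm_stats,
                 n_iter = n_iter, seed = seed),
            class = "ort_permutation")
}

#' @export
print.ort_permutation <- function(x, ...) {
  cat(sprintf("ordinal trend: %d subjects increase, permutation p = %.4g (%d iterations)\n",
              x$observed, x$p, x$n_iter))
  invisible(x)
}

#' Bootstrap voxel reliability of the pattern
#'
#' Subjects are resampled with replacement (both scans travel together), the
#' pattern is refit per replicate and sign-aligned to the observed pattern,
#' and each voxel's one-tailed p is the fraction of replicates whose weight
#' crosses zero against the observed sign. The significance mask thresholds
#' at p < 0.05.
#'
#' @param sm a `scan_matrix`.
#' @param n_boot bootstrap replicates (default 500).
#' @param max_pcs passed to [fit_ort()].
#' @param seed RNG seed.
#' @return list of class `ort_inference`: observed `model`, `p_map` (per
#'   mask voxel), `sig_mask` (logical), `n_boot`, `seed`.
#' @export
bootstrap_voxel_pmap <- function(sm, n_boot = 500, max_pcs = 5, seed = 1L) {
  assert_that(n_boot >= 1, "n_boot must be >= 1")
  model <- fit_ort(sm, max_pcs)
  sids <- unique(sm$subject_id)
  obs_sign <- ifelse(model$pattern >= 0, 1, -1)
  cross <- numeric(length(model$pattern))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    pick <- sample(sids, length(sids), replace = TRUE)
    rows <- unlist(lapply(seq_along(pick),
                          function(i) which(sm$subject_id == pick[i])))
    smb <- sm
    smb$X <- sm$X[rows, , drop = FALSE]
    smb$subject_id <- sprintf("rep%02d_%s", rep(seq_along(pick), each = 2),
                              sm$subject_id[rows])
    smb$condition <- sm$condition[rows]
    smb$group <- sm$group[rows]
    mb <- tryCatch(fit_ort(smb, max_pcs), betapet_fit_error = function(e) NULL)
    if (is.null(mb)) next
    pat <- mb$pattern
    if (sum(pat * model$pattern) < 0) pat <- -pat
    cross <- cross + (obs_sign * pat <= 0)
  }
  p_map <- cross / n_boot
  structure(list(model = model, p_map = p_map, sig_mask = p_map < 0.05,
                 n_boot = n_boot, seed = seed),
            class = "ort_inference")
}

#' Map per-voxel values back into a 3D volume
#'
#' @param model an `ort_model` (or `ort_inference$model`).
#' @param values per-mask-voxel vector (e.g. the pattern or a p-map);
#'   defaults to the signed pattern.
#' @return 3D array on the template grid (0 outside the brain mask).
#' @export
ort_map_volume <- function(model, values = model$pattern) {
  assert_that(length(values) == length(model$mask_idx),
              "values length must equal mask voxel count")
  vol <- array(0, dim = model$grid_dim)
  vol[model$mask_idx] <- values
  vol
}

#' Project held-out scans onto a fitted pattern
#'
#' Every scan (fitted and held-out groups alike) is normalized, centered
#' with the model's stored voxel means, and projected onto the pattern;
#' expressions are z-scored across all projected scans so group values are
#' comparable, and the per-subject change z(F3) - z(F1) is returned.
#'
#' @param model an `ort_model` (fitted, e.g., on CON-like subjects).
#' @param cohort cohort whose subjects to project (can include the held-out
#'   group).
#' @return a `nodal_expression` data.frame over the projected subjects.
#' @export
nodal_expression_delta <- function(model, cohort) {
  mask <- array(FALSE, dim = model$grid_dim)
  mask[model$mask_idx] <- TRUE
  sid <- character(0); cond <- character(0); grp <- character(0)
  expr <- numeric(0)
  for (s in cohort$subjects) {
    for (session in c("f1", "f3")) {
      v <- normalize_to_brain_mean(s[[session]], mask)
      x <- v$data[model$mask_idx] - model$voxel_mean
      expr <- c(expr, sum(x * model$pattern))
      sid <- c(sid, s$subject_id)
      cond <- c(cond, toupper(session))
      grp <- c(grp, s$group)
    }
  }
  sd_e <- stats::sd(expr)
  z <- if (sd_e > 0) (expr - mean(expr)) / sd_e else expr - mean(expr)
  sids <- unique(sid)
  wide <- data.frame(
    subject_id = sids,
    group = grp[match(sids, sid)],
    z_f1 = z[cond == "F1"][match(sids, sid[cond == "F1"])],
    z_f3 = z[cond == "F3"][match(sids, sid[cond == "F3"])])
  wide$delta <- wide$z_f3 - wide$z_f1
  class(wide) <- c("nodal_expression", "data.frame")
  wide
}
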