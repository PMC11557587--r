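test_that("build_scan_matrix stacks, centers and round-trips", {
  co <- small_phantom(noise_sd = 0.02, seed = 9, n = c(CON = 2L, LS = 2L))
  sm <- build_scan_matrix(co)
  expect_equal(nrow(sm$X), 8)  # 2 scans per subject
  expect_equal(ncol(sm$X), sum(co$brain_mask))
  expect_lt(max(abs(colMeans(sm$X))), 1e-10)
  # un-centering reproduces the normalized scans
  v <- normalize_to_brain_mean(co$subjects$CON01$f1, co$brain_mask)
  expect_equal(sm$X[1, ] + sm$voxel_mean, v$data[sm$mask_idx],
               tolerance = 1e-12)
  # group filter
  sm_con <- build_scan_matrix(co, groups = "CON")
  expect_equal(nrow(sm_con$X), 4)
  # missing condition is an input error
  broken <- co
  broken$subjects$CON01$f3 <- NULL
  expect_error(build_scan_matrix(broken), "missing a condition")
})

test_that("PCs match a dense eigendecomposition oracle up to sign", {
  set.seed(12)
  sim <- ort_sim(4, 0.5, 0.3, 77, n_vox = 50)
  Y <- betapet:::subject_center(sim$sm$X, sim$sm$subject_id)
  pca <- betapet:::gram_pca(Y, 4)
  ev <- eigen(crossprod(Y), symmetric = TRUE)
  for (j in seq_len(ncol(pca$V))) {
    v_o <- ev$vectors[, j]
    expect_equal(abs(sum(pca$V[, j] * v_o)), 1, tolerance = 1e-8)
    expect_equal(pca$d[j]^2, ev$values[j], tolerance = 1e-8)
  }
})

test_that("fit_ort recovers a strongly planted pattern", {
  # pattern-estimate noise norm ~ noise * sqrt(2 V / n) / effect; at
  # (n = 12, V = 150, noise = 0.05) the expected correlation is ~0.97
  sim <- ort_sim(12, 1, 0.05, 101)
  model <- fit_ort(sim$sm)
  expect_gte(abs(sum(model$pattern * sim$w)), 0.95)
  expect_equal(sqrt(sum(model$pattern^2)), 1, tolerance = 1e-10)
  ne <- nodal_expression(model)
  expect_equal(ordinal_statistic(ne), 12)
  # z-scored expressions have mean 0, sd 1 across scans
  z <- c(ne$z_f1, ne$z_f3)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
})

test_that("symmetric noise yields a near-binomial split of increases", {
  inc <- integer(40)
  for (i in 1:40) {
    sim <- ort_sim(8, 0, 0.3, 500 + i, n_vox = 80)
    ne <- nodal_expression(fit_ort(sim$sm))
    inc[i] <- ordinal_statistic(ne)
  }
  # orientation forces >= half; the excess above half stays modest
  expect_true(all(inc >= 4))
  expect_lt(mean(inc), 7.2)
})

test_that("ordinal_statistic counts increasing subjects", {
  ne <- data.frame(z_f1 = c(0, 1, 2), z_f3 = c(1, 0, 3))
  expect_equal(ordinal_statistic(ne), 2)
  ne$z_f3 <- ne$z_f1 - 1
  expect_equal(ordinal_statistic(ne), 0)
  set.seed(13)
  ne <- data.frame(z_f1 = rnorm(20), z_f3 = rnorm(20))
  expect_equal(ordinal_statistic(ne), sum(ne$z_f3 > ne$z_f1))
})

test_that("permutation p has the add-one floor and is seed-reproducible", {
  sim <- ort_sim(12, 1, 0.1, 201)
  p1 <- permutation_test(sim$sm, n_iter = 49, seed = 3)
  p2 <- permutation_test(sim$sm, n_iter = 49, seed = 3)
  expect_identical(p1$perm_statistics, p2$perm_statistics)
  expect_gte(p1$p, 1 / 50)
  expect_equal(p1$observed, 12)
  expect_error(permutation_test(sim$sm, n_iter = 0), "n_iter")
})

test_that("bootstrap voxel p-map separates loaded from null voxels", {
  # pattern supported on the first 30 voxels only
  set.seed(14)
  n_sub <- 12; n_vox <- 120
  w <- c(rep(1 / sqrt(30), 30), rep(0, 90))
  X <- matrix(rnorm(2 * n_sub * n_vox, 0, 0.08), 2 * n_sub, n_vox)
  cond <- rep(c("F1", "F3"), n_sub)
  X[cond == "F3", ] <- X[cond == "F3", ] +
    matrix(1.5 * w, n_sub, n_vox, byrow = TRUE)
  sm <- scan_matrix(X, rep(sprintf("S%02d", 1:n_sub), each = 2), cond)
  inf <- bootstrap_voxel_pmap(sm, n_boot = 150, seed = 4)
  expect_gte(mean(inf$sig_mask[1:30]), 0.9)
  expect_lte(mean(inf$sig_mask[31:120]), 0.1)
  expect_true(all(inf$p_map >= 0 & inf$p_map <= 1))
})

test_that("nodal_expression_delta projects held-out groups consistently", {
  co <- small_phantom(noise_sd = 0.03, seed = 23, n = c(CON = 5L, LS = 5L))
  sm <- build_scan_matrix(co, groups = "CON")
  model <- fit_ort(sm)
  ne <- nodal_expression_delta(model, co)
  expect_setequal(ne$subject_id,
                  vapply(co$subjects, `[[`, character(1), "subject_id"))
  # CON-like group carries the larger planted F3 enhancement
  expect_gt(mean(ne$delta[ne$group == "CON"]),
            mean(ne$delta[ne$group == "LS"]))
  # adding c * pattern to every F3 scan shifts all deltas equally
  co2 <- co
  shift <- array(0, dim = dim(co$brain_mask))
  shift[model$mask_idx] <- 0.005 * model$pattern
  for (nm in names(co2$subjects)) {
    f3 <- co2$subjects[[nm]]$f3
    mu <- mean(f3$data[co$brain_mask])
    f3$data <- f3$data + shift * mu  # pre-normalization scale
    co2$subjects[[nm]]$f3 <- f3
  }
  # raw expression deltas shift by a constant; after z-scoring that is an
  # affine map, so the new deltas regress on the old with R^2 ~ 1, positive
  # slope and positive intercept
  ne2 <- nodal_expression_delta(model, co2)
  fit <- stats::lm(ne2$delta ~ ne$delta)
  expect_gt(suppressWarnings(summary(fit))$r.squared, 0.999)
  expect_gt(stats::coef(fit)[2], 0)
  expect_gt(stats::coef(fit)[1], 0)
})

test_that("F3 changes orthogonal to the pattern give zero expression delta", {
  sim <- ort_sim(6, 1, 0.05, 301, n_vox = 60)
  model <- fit_ort(sim$sm)
  model2 <- model
  arr_dim <- c(60, 1, 1)
  model2$grid_dim <- arr_dim
  model2$mask_idx <- 1:60
  model2$voxel_mean <- rep(0, 60)
  # orthonormal basis of span{constant, pattern}; orth noise lives in the
  # complement, so it moves neither the scan mean nor the projection
  u1 <- rep(1, 60) / sqrt(60)
  u2 <- model$pattern - sum(model$pattern * u1) * u1
  u2 <- u2 / sqrt(sum(u2^2))
  proj_out <- function(v) v - sum(v * u1) * u1 - sum(v * u2) * u2
  co <- list(subjects = list())
  set.seed(15)
  for (i in 1:3) {
    f1_vec <- 5 + 0.1 * i * model$pattern
    orth <- proj_out(rnorm(60, 0, 0.05))
    f3_vec <- f1_vec + orth
    mk <- function(x, session) {
      volume_image(array(x, arr_dim), c(1, 1, 1),
                   subject_id = sprintf("O%d", i), group = "ORTH",
                   session = session)
    }
    co$subjects[[i]] <- list(subject_id = sprintf("O%d", i), group = "ORTH",
                             f1 = mk(f1_vec, "F1"), f3 = mk(f3_vec, "F3"))
  }
  co$brain_mask <- array(TRUE, dim = arr_dim)
  ne <- nodal_expression_delta(model2, co)
  # each F3 differs from its F1 only orthogonally to the pattern (and with
  # zero voxel mean, so normalization cancels): delta is 0 to within the
  # residual pattern-mean coupling of the projection
  expect_lt(max(abs(ne$delta)), 1e-6)
})

test_that("ort_map_volume places values on the template grid", {
  co <- small_phantom(noise_sd = 0.02, seed = 9, n = c(CON = 4L, LS = 4L))
  sm <- build_scan_matrix(co, groups = "CON")
  model <- fit_ort(sm)
  vol <- ort_map_volume(model)
  expect_equal(dim(vol), dim(co$brain_mask))
  expect_equal(vol[model$mask_idx], model$pattern)
  expect_true(all(vol[!co$brain_mask] == 0))
  expect_error(ort_map_volume(model, 1:3), "length")
})
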