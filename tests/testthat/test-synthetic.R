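test_that("zero-noise, zero-effect cohort has identical F1/F3 volumes", {
  eff <- default_group_effects()
  eff$effect <- 0
  co <- make_phantom_cohort(phantom_config(
    grid_shape = c(24, 36, 18), n_subjects_per_group = c(CON = 2, LS = 2),
    group_effects = eff, noise_sd = 0, seed = 1))
  for (s in co$subjects) {
    expect_identical(s$f1$data, s$f3$data)
  }
})

test_that("zero-noise planted effect is exact through the roi pipeline", {
  co <- small_phantom(noise_sd = 0, seed = 5, n = c(CON = 2L, LS = 2L))
  tab <- cohort_delta_table(co)
  eff <- default_group_effects()
  for (i in seq_len(nrow(eff))) {
    expect_equal(region_group_mean(tab, eff$region[i], eff$group[i]),
                 eff$effect[i], tolerance = 1e-12)
  }
})

test_that("noisy region-mean delta stays within the standard-error bound", {
  co <- small_phantom(noise_sd = 0.05, seed = 21, n = c(CON = 10L, LS = 10L))
  tab <- cohort_delta_table(co)
  eff <- default_group_effects()
  masks <- co$mask_set
  for (i in seq_len(nrow(eff))) {
    m <- sum(vapply(masks$objects,
                    function(o) if (o$region == eff$region[i]) length(o$idx)
                    else 0L, numeric(1)))
    n_sub <- sum(vapply(co$subjects, function(s) s$group == eff$group[i],
                        logical(1)))
    # delta of two noisy scans: var = 2 sd^2 / m per subject
    bound <- 3 * 0.05 * sqrt(2 / (m * n_sub))
    got <- region_group_mean(tab, eff$region[i], eff$group[i])
    expect_lt(abs(got - eff$effect[i]), bound + 1e-12)
  }
})

test_that("cohort generation is deterministic and validates configs", {
  a <- small_phantom(noise_sd = 0.05, seed = 31)
  b <- make_phantom_cohort(phantom_config(
    grid_shape = c(24L, 36L, 18L), n_subjects_per_group = c(CON = 4L, LS = 4L),
    noise_sd = 0.05, seed = 31))
  expect_identical(a$subjects$CON01$f1$data, b$subjects$CON01$f1$data)
  expect_identical(a$subjects$LS03$f3$data, b$subjects$LS03$f3$data)

  expect_error(phantom_config(noise_sd = -1), class = "betapet_config_error")
  expect_error(phantom_config(grid_shape = c(0, 10, 10)),
               class = "betapet_config_error")
  # overlapping regions rejected
  specs <- list(
    list(name = "A", x = c(10, 14), y = c(20, 25), z = c(8, 12),
         hemispheres = "BOTH", baseline = 1),
    list(name = "B", x = c(12, 16), y = c(22, 27), z = c(10, 14),
         hemispheres = "BOTH", baseline = 1))
  expect_error(make_phantom_cohort(phantom_config(region_specs = specs)),
               class = "betapet_config_error")
})

test_that("region masks are disjoint, in-brain, with expected object counts", {
  co <- small_phantom(noise_sd = 0, seed = 5, n = c(CON = 2L, LS = 2L))
  masks <- co$mask_set
  all_idx <- unlist(lapply(masks$objects, `[[`, "idx"))
  expect_false(anyDuplicated(all_idx) > 0)
  expect_true(all(all_idx %in% which(masks$brain_mask)))
  regs <- vapply(masks$objects, `[[`, character(1), "region")
  hemis <- vapply(masks$objects, `[[`, character(1), "hemisphere")
  # midline prefrontal regions are single objects per slice
  expect_true(all(hemis[regs %in% c("PLC", "ILC")] == "BOTH"))
  # bilateral regions come in L/R pairs per slice
  ba <- masks$objects[regs == "BA"]
  slices <- vapply(ba, `[[`, integer(1), "slice")
  expect_true(all(table(slices) == 2))
})

test_that("canonical grid keeps 12 BA slices and scaling preserves structure", {
  specs <- default_region_specs()
  ba <- Filter(function(s) s$name == "BA", specs)[[1]]
  expect_equal(diff(ba$y) + 1, 12)
  scaled <- default_region_specs(c(24, 36, 18))
  expect_equal(length(scaled), length(specs))
  for (s in scaled) {
    expect_true(all(s$x >= 1) && all(s$y >= 1) && all(s$z >= 1))
  }
})

test_that("trace generator plants recoverable structure", {
  # no bouts -> no frames below threshold
  tc0 <- trace_config(groups = list(CON = list(n = 2, bout_rate = 0,
                                               dur_mean = 6, dur_shape = 9)),
                      seed = 2)
  for (tr in make_activity_traces(tc0)) {
    expect_true(all(tr$activity_score > 0.05))
    pct <- epoch_percent_freezing(score_inactivity(tr, freezing_config(0.05)),
                                  tr$frame_rate)
    expect_true(all(pct == 0))
  }
  # bouts never overlap, total bout time below session length, and
  # detect_bouts recovers the planted list exactly
  tc <- trace_config(seed = 8)
  trs <- make_activity_traces(tc)
  for (tr in trs[c(1, 15, 28)]) {
    tb <- tr$truth_bouts
    ends <- tb$start_s + tb$duration_s
    expect_true(all(tb$start_s[-1] > ends[-nrow(tb)]))
    expect_lte(sum(tb$duration_s), tc$session_length_s)
    got <- detect_bouts(score_inactivity(tr, freezing_config(0.04)),
                        tr$frame_rate)
    expect_equal(got, tb, ignore_attr = TRUE)
  }
})

test_that("single planted bout is recovered at its exact length", {
  tc <- trace_config(groups = list(CON = list(n = 1, bout_rate = 1 / 8,
                                              dur_mean = 5, dur_shape = 1e8)),
                     seed = 3)
  tr <- make_activity_traces(tc)[[1]]
  bouts <- detect_bouts(score_inactivity(tr, freezing_config(0.04)),
                        tr$frame_rate)
  expect_equal(nrow(bouts), 1)
  expect_equal(bouts$duration_s, 5, tolerance = 1 / tr$frame_rate)
})

test_that("group freezing means land near their targets at n = 10", {
  tc <- trace_config(groups = list(
    CON = list(n = 10, bout_rate = bout_rate_for_target(73.11, 6),
               dur_mean = 6, dur_shape = 9),
    LS = list(n = 10, bout_rate = bout_rate_for_target(45.44, 6),
              dur_mean = 6, dur_shape = 9)), seed = 12)
  trs <- make_activity_traces(tc)
  wm <- vapply(trs, function(tr) {
    window_mean(epoch_percent_freezing(
      score_inactivity(tr, freezing_config(0.04)), tr$frame_rate),
      c(180, 480), 10)
  }, numeric(1))
  grp <- vapply(trs, `[[`, character(1), "group")
  expect_lt(abs(mean(wm[grp == "CON"]) - 73.11), 5)
  expect_lt(abs(mean(wm[grp == "LS"]) - 45.44), 5)
})

test_that("impossible bout load raises a generation error", {
  tc <- trace_config(session_length_s = 60,
                     groups = list(CON = list(n = 1, bout_rate = 30,
                                              dur_mean = 10, dur_shape = 50)),
                     seed = 1)
  expect_error(make_activity_traces(tc), class = "betapet_generation_error")
})

test_that("fixture bundle round-trips bit-exactly with stable checksums", {
  co <- small_phantom(noise_sd = 0.02, seed = 17, n = c(CON = 2L, LS = 2L))
  tc <- trace_config(groups = list(CON = list(n = 2, bout_rate = 5,
                                              dur_mean = 5, dur_shape = 9),
                                   LS = list(n = 2, bout_rate = 3,
                                             dur_mean = 5, dur_shape = 9)),
                     seed = 4)
  traces <- make_activity_traces(tc)
  d1 <- withr::local_tempdir()
  m1 <- write_fixture_bundle(co, traces, d1)
  # one F1 and one F3 file per subject
  expect_equal(sum(grepl("_F1\\.nii$", m1$files$file)), 4)
  expect_equal(sum(grepl("_F3\\.nii$", m1$files$file)), 4)
  # round-trip voxel identity
  back <- read_fixture_bundle(d1)
  expect_identical(back$cohort$subjects$CON01$f1$data,
                   co$subjects$CON01$f1$data)
  expect_identical(back$cohort$subjects$LS02$f3$data,
                   co$subjects$LS02$f3$data)
  expect_equal(sum(back$cohort$brain_mask), sum(co$brain_mask))
  # same seed -> identical checksums
  d2 <- withr::local_tempdir()
  m2 <- write_fixture_bundle(co, traces, d2)
  expect_identical(m1$files$md5, m2$files$md5)
})
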