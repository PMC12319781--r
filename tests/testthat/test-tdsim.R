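# Virtual instrument: timing arithmetic, IRF model, DTOF synthesis, scenes
# and task paradigms.

test_that("multiplexing arithmetic reproduces the instrument rates", {
  r <- sampling_rates(multiplex_schedule())
  expect_equal(r$histogram_hz, 285.7, tolerance = 0.1 / 285.7)
  expect_equal(r$spectroscopic_hz, 142.9, tolerance = 0.1 / 142.9)
  expect_equal(r$system_hz, 3.76, tolerance = 0.01 / 3.76)
  expect_equal(r$single_source_hz, 7.52, tolerance = 0.01 / 7.52)
  r1 <- sampling_rates(multiplex_schedule(1, 1, 1))
  expect_equal(unlist(r1)[c(1, 3, 4)], c(histogram_hz = 1000,
                                         system_hz = 1000,
                                         single_source_hz = 1000))
})

test_that("the IRF model realizes the configured widths and tail constants", {
  tg <- time_grid(10, 800)
  for (i in 1:2) {
    wl <- c(690, 905)[i]
    y <- irf_curve(irf_model(), wl, tg)
    w <- irf_width_metrics(y, 10)
    expect_equal(w$fwhm_ps, c(240, 270)[i], tolerance = 2 * 10 / 240)
    expect_equal(w$tail_tau_ps, c(292, 265)[i], tolerance = 0.03)
    expect_true(w$fw1_ps >= w$fw10_ps && w$fw10_ps >= w$fwhm_ps)
    expect_equal(sum(y) * tg$bin_width_ps, 1, tolerance = 1e-6)
  }
  # drift widens the IRF monotonically from cold start
  f <- vapply(c(0, 1800, 7200), function(ts)
    irf_width_metrics(irf_curve(irf_model(), 690, tg, ts), 10)$fwhm_ps,
    numeric(1))
  expect_true(all(diff(f) > 0))
  expect_lt(abs(f[3] - 285) / 285, 0.05)   # ~ +45 ps after 2 h
})

test_that("DTOF synthesis obeys moment additivity under convolution", {
  tg <- time_grid(25, 400)
  ik <- fixture_irf(690, tg)
  props <- optical_properties(0.01, 1.0, 1.41)
  d <- simulate_dtof(scene(props), list(sds_mm = 26.5, wavelength_nm = 690),
                     ik, tg, 1e6, noise = FALSE)
  m <- dtof_moments(d)
  t <- time_centers(tg)
  tp <- tpsf_semi_infinite(props, 26.5, tg)
  mt <- brute_moments(tp, t)
  mi <- brute_moments(ik, t)
  expect_lt(abs(m$m1_ps - (mt$m1 + mi$m1)), tg$bin_width_ps)
  expect_lt(abs(m$V_ps2 - (mt$V + mi$V)), 2 * tg$bin_width_ps^2)
  expect_equal(m$N, 1e6, tolerance = 1e-9)
})

test_that("a delta IRF reproduces the binned TPSF", {
  tg <- time_grid(25, 400)
  delta <- c(1 / tg$bin_width_ps, rep(0, tg$n_bins - 1))
  props <- optical_properties(0.01, 1.0, 1.41)
  d <- simulate_dtof(scene(props), list(sds_mm = 20, wavelength_nm = 690),
                     delta, tg, 1e6, noise = FALSE)
  tp <- tpsf_semi_infinite(props, 20, tg)
  expect_gt(cor(d$counts, tp), 1 - 1e-9)
})

test_that("shot noise is Poisson: variance of totals tracks the mean", {
  tg <- time_grid(50, 100)
  ik <- irf_curve(irf_model(), 905, tg)
  props <- optical_properties(0.01, 1.0, 1.33)
  sc <- scene(props)
  set.seed(11)
  totals <- vapply(seq_len(200), function(k)
    sum(simulate_dtof(sc, list(sds_mm = 20, wavelength_nm = 905), ik, tg,
                      1e5, noise = TRUE)$counts), numeric(1))
  expect_lt(abs(var(totals) / mean(totals) - 1), 0.3)
  expect_lt(abs(mean(totals) / 1e5 - 1), 0.01)
})

test_that("DTOF synthesis is deterministic given the seed", {
  tg <- time_grid(50, 100)
  ik <- irf_curve(irf_model(), 905, tg)
  sc <- scene(optical_properties(0.01, 1.0, 1.33), seed = 4)
  ch <- list(sds_mm = 20, wavelength_nm = 905)
  d1 <- simulate_dtof(sc, ch, ik, tg, 1e5, seed = 42)
  d2 <- simulate_dtof(sc, ch, ik, tg, 1e5, seed = 42)
  expect_identical(d1$counts, d2$counts)
  expect_equal(d1$seed, 42)
  expect_error(simulate_dtof(sc, ch, ik, tg, target_counts = 0),
               "target_counts")
})

test_that("depth scans: contrast decays with depth and vanishes for a null inclusion", {
  tg <- time_grid(50, 200)
  im <- irf_model()
  ch <- list(sds_mm = 26.5, wavelength_nm = 905)
  props <- optical_properties(0.01, 1.0, 1.33)
  scan <- neuropt_scan(props, ch, im, tg, depths_mm = c(8, 20, 36),
                       volume_mm3 = 100, n_reference = 10, n_per_depth = 4,
                       seed = 5)
  cr <- vapply(scan$scans, function(ds)
    mean(vapply(ds, function(d) sum(d$counts), numeric(1))) / 1e6 - 1,
    numeric(1))
  expect_lt(abs(cr[3]), abs(cr[1]))
  expect_lt(cr[1], 0)    # absorbing inclusion removes photons
  scan0 <- neuropt_scan(props, ch, im, tg, depths_mm = c(8, 20),
                        volume_mm3 = 0, n_reference = 10, n_per_depth = 4,
                        seed = 5)
  cr0 <- vapply(scan0$scans, function(ds)
    mean(vapply(ds, function(d) sum(d$counts), numeric(1))) / 1e6 - 1,
    numeric(1))
  expect_lt(max(abs(cr0)), 0.005)
  expect_error(neuropt_scan(props, ch, im, tg, depths_mm = -3), "depth")
})

test_that("inclusion contrast is first-order linear in the perturbation", {
  tg <- time_grid(50, 200)
  ik <- irf_curve(irf_model(), 905, tg)
  props <- optical_properties(0.01, 1.0, 1.33)
  ch <- list(sds_mm = 26.5, wavelength_nm = 905)
  cr_at <- function(dmua) {
    sc <- scene(props, inclusion = list(position_mm = c(13.25, 0, 16),
                                        volume_mm3 = 100, delta_mua = dmua))
    sum(simulate_dtof(sc, ch, ik, tg, 1e6, noise = FALSE)$counts) / 1e6 - 1
  }
  expect_equal(cr_at(0.02) / cr_at(0.01), 2, tolerance = 0.02)
})

test_that("paradigm presets reproduce the printed block structures", {
  bh <- paradigm_breath_hold()
  expect_equal(sum(bh$condition == "hold"), 6)
  expect_equal(sum(bh$condition == "paced"), 6)
  expect_true(all(bh$duration_s[bh$condition == "hold"] == 20))
  expect_true(all(bh$duration_s[bh$condition == "paced"] == 30))
  expect_equal(attr(bh, "breath_cycle_s"), 6)

  au <- paradigm_auditory()
  expect_equal(sum(au$condition == "story"), 8)
  expect_equal(sum(au$condition == "noise"), 7)
  expect_true(all(au$duration_s == 20))
  expect_equal(min(au$onset_s), 10)

  ft <- paradigm_finger_tapping()
  expect_equal(sum(ft$condition == "left"), 10)
  expect_equal(sum(ft$condition == "right"), 10)
  expect_true(all(abs(ft$duration_s - 17.3) < 1e-9))
  tr <- attr(ft, "trials")
  expect_equal(nrow(tr), 20 * 13)
  expect_true(all(tr$duration_s == 0.75))
  expect_equal(unname(diff(tr$onset_s[1:2])), 1.25)  # 0.75 s + 0.50 s ITI
})

test_that("overlapping paradigm blocks are rejected", {
  bad <- data.frame(onset_s = c(0, 10), duration_s = c(15, 10),
                    condition = "a")
  expect_error(task_session(bad), "overlapping")
})

test_that("the MEDPHOT phantom grid spans 4 x 3 conditions", {
  g <- medphot_phantom_grid()
  expect_equal(nrow(g), 12)
  expect_equal(length(unique(g$musp)), 4)
  expect_equal(length(unique(g$mua)), 3)
  expect_equal(anyDuplicated(g$phantom), 0)
})

test_that("task sessions are reproducible and a null session has near-zero t-stats", {
  s1 <- task_session(paradigm_finger_tapping(),
                     responses = response_spec(c("left", "right"),
                                               c("right_motor", "left_motor"),
                                               dhbo_uM = c(0, 0)),
                     seed = 8)
  s2 <- task_session(paradigm_finger_tapping(),
                     responses = response_spec(c("left", "right"),
                                               c("right_motor", "left_motor"),
                                               dhbo_uM = c(0, 0)),
                     seed = 8)
  expect_identical(s1$features, s2$features)
  expect_equal(s1$truth$seed, 8)

  des <- build_design(s1$events, length(s1$t_s), s1$sampling_hz)
  hr <- hemo_pipeline(s1)
  g <- fit_glm(hr$dhbo, des, contrasts = list(lr = c(left = 1, right = -1)))
  tt <- g$contrasts$lr$t
  expect_lt(abs(mean(tt)), 1)
  expect_lt(mean(abs(tt) > 3), 0.2)
})
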