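# Hemodynamic pipeline: sensitivities, chromophore solves, conditioning
# stages, heart rate.

test_that("the extinction matrix is well conditioned and invertible", {
  E <- extinction_matrix()
  expect_equal(dim(E), c(2, 2))
  expect_gt(abs(det(unclass(E))), 0)
  expect_lt(attr(E, "condition_number"), 50)
  # HbR dominates at 690 nm, HbO at 905 nm
  expect_gt(E["690", "hbr"], E["690", "hbo"])
  expect_gt(E["905", "hbo"], E["905", "hbr"])
})

test_that("layered sensitivities match the layered finite-difference forward", {
  props <- optical_properties(0.01, 1.0, 1.4)
  tg <- time_grid(10, 512)
  ls <- layer_sensitivities(medium_two_layer(props, props, 12), 26.5, tg)
  delta <- 2e-4
  feat <- function(f) fd_layered_features(f, 1.0, 1.4, 26.5, tg)
  f0 <- feat(function(z) rep(0.01, length(z)))
  for (layer in c("deep", "superficial")) {
    inlayer <- if (layer == "deep") function(z) z >= 12 else function(z) z < 12
    fp <- feat(function(z) 0.01 + delta * inlayer(z))
    fm <- feat(function(z) 0.01 - delta * inlayer(z))
    fd <- c((fp["N"] - fm["N"]) / f0["N"], fp["m1"] - fm["m1"],
            fp["V"] - fm["V"]) / (2 * delta)
    expect_lt(max(abs(ls$S[, layer] / fd - 1)), 0.05)
  }
})

test_that("variance weights the deep layer more than intensity does", {
  props <- optical_properties(0.01, 1.0, 1.4)
  ls <- layer_sensitivities(medium_two_layer(props, props, 12), 26.5,
                            time_grid(20, 256))
  ratio <- function(row) abs(ls$S[row, "deep"] / ls$S[row, "superficial"])
  expect_gt(ratio("variance"), ratio("intensity"))
  expect_gt(ratio("meantime"), ratio("intensity"))
})

test_that("an empty deep layer yields zero deep sensitivities and a thick layer errors", {
  props <- optical_properties(0.01, 1.0, 1.4)
  g <- voxel_grid(3, xlim = c(-15, 35), ylim = c(-15, 15), zlim = c(0, 12))
  ls <- layer_sensitivities(medium_two_layer(props, props, 12), 20,
                            time_grid(20, 128), grid = g)
  expect_equal(unname(ls$S[, "deep"]), c(0, 0, 0))
  expect_error(
    layer_sensitivities(medium_two_layer(props, props, 60), 20,
                        time_grid(20, 128)),
    "thicker")
})

test_that("moments_to_dmua round-trips exactly and propagates noise unbiasedly", {
  props <- optical_properties(0.01, 1.0, 1.4)
  S <- layer_sensitivities(medium_two_layer(props, props, 12), 26.5,
                           time_grid(20, 256))$S
  x <- c(superficial = 3e-4, deep = -2e-4)
  dm <- matrix(as.numeric(S %*% x), nrow = 5, ncol = 3, byrow = TRUE)
  sol <- moments_to_dmua(dm, S)
  expect_equal(unname(sol[1, ]), unname(x), tolerance = 1e-10)
  expect_equal(unname(moments_to_dmua(matrix(0, 2, 3), S)),
               matrix(0, 2, 2), ignore_attr = TRUE)

  # Monte-Carlo: noisy features recover the truth without bias
  bm <- list(V = 2.6e5, m4c = 4e11)
  fsd <- feature_noise_sd(bm, 1e5)
  set.seed(31)
  est <- t(vapply(1:100, function(k) {
    noisy <- matrix(as.numeric(S %*% x) + rnorm(3, 0, fsd), 1)
    moments_to_dmua(noisy, S, feature_sd = fsd)[1, ]
  }, numeric(2)))
  se <- apply(est, 2, sd) / sqrt(100)
  expect_lt(abs(mean(est[, 1]) - x[1]), 4 * se[1])
  expect_lt(abs(mean(est[, 2]) - x[2]), 4 * se[2])
  expect_error(moments_to_dmua(matrix(0, 2, 3), matrix(1, 3, 2)),
               "rank-deficient")
})

test_that("the modified Beer-Lambert solve round-trips chromophores", {
  E <- extinction_matrix()
  expect_equal(unlist(mbll_delta(0, 0)), c(dhbo_uM = 0, dhbr_uM = 0))
  hb_true <- c(1, -0.25)
  dmua <- unclass(E) %*% hb_true
  out <- mbll_delta(dmua[1], dmua[2], E)
  expect_equal(c(out$dhbo_uM, out$dhbr_uM), hb_true, tolerance = 1e-12)
  out2 <- mbll_delta(2 * dmua[1], 2 * dmua[2], E)
  expect_equal(c(out2$dhbo_uM, out2$dhbr_uM), 2 * hb_true, tolerance = 1e-12)
  expect_error(mbll_delta(1e-4, 1e-4, matrix(c(1, 1, 1, 1), 2)), "singular")
})

test_that("absolute hemoglobin recovers a homogeneous head within 10%", {
  E <- extinction_matrix()
  hb_true <- c(hbo = 55, hbr = 22)
  mua_true <- as.numeric(unclass(E) %*% hb_true)      # 690 then 905
  tg <- time_grid(25, 400)
  im <- irf_model()
  fits <- do.call(rbind, lapply(1:3, function(chn) {
    do.call(rbind, lapply(1:2, function(i) {
      wl <- c(690, 905)[i]
      props <- optical_properties(mua_true[i], 1.1, 1.4)
      d <- simulate_dtof(scene(props), list(sds_mm = 26.5, wavelength_nm = wl),
                         irf_curve(im, wl, tg), tg, 1e6, noise = TRUE,
                         seed = 50 + 10 * chn + i)
      f <- fit_optical_properties(d, irf_curve(im, wl, tg), 26.5, 1.4)
      data.frame(channel = paste0("ch", chn), wavelength_nm = wl,
                 mua = f$mua, sds_mm = 26.5)
    }))
  }))
  res <- absolute_hb(fits, E)
  expect_lt(abs(res$hbo_uM / hb_true["hbo"] - 1), 0.1)
  expect_lt(abs(res$hbr_uM / hb_true["hbr"] - 1), 0.1)

  # identical channels: median equals the single-channel value
  one <- fits[fits$channel == "ch1", ]
  dup <- rbind(one, transform(one, channel = "ch9"))
  r1 <- absolute_hb(one, E)
  r2 <- absolute_hb(dup, E)
  expect_equal(r1$hbo_uM, r2$hbo_uM)
  expect_error(absolute_hb(fits[fits$wavelength_nm == 690, ], E),
               "qualifying")
})

test_that("absolute HbO rises during simulated breath holds and HbR falls", {
  E <- extinction_matrix()
  base_hb <- c(60, 20)
  hold_hb <- c(64, 18.6)                      # hypercapnic excursion
  tg <- time_grid(25, 400)
  im <- irf_model()
  measure <- function(hb, seed) {
    mua <- as.numeric(unclass(E) %*% hb)
    fits <- do.call(rbind, lapply(1:2, function(i) {
      wl <- c(690, 905)[i]
      d <- simulate_dtof(scene(optical_properties(mua[i], 1.1, 1.4)),
                         list(sds_mm = 26.5, wavelength_nm = wl),
                         irf_curve(im, wl, tg), tg, 3e6, noise = TRUE,
                         seed = seed + i)
      data.frame(channel = "c1", wavelength_nm = wl,
                 mua = fit_optical_properties(d, irf_curve(im, wl, tg), 26.5,
                                              1.4)$mua,
                 sds_mm = 26.5)
    }))
    absolute_hb(fits, E)
  }
  # ramp through a hold block: baseline, mid-hold, end-hold, recovery
  frac <- c(0, 0.5, 1, 0.2)
  hbo <- hbr <- numeric(length(frac))
  for (k in seq_along(frac)) {
    hb <- base_hb + frac[k] * (hold_hb - base_hb)
    m <- measure(hb, 700 + 10 * k)
    hbo[k] <- m$hbo_uM; hbr[k] <- m$hbr_uM
  }
  expect_gt(hbo[3], hbo[1])          # gradual HbO increase during the hold
  expect_gt(hbo[3], hbo[2])
  expect_lt(hbr[3], hbr[1])          # HbR decreases
  expect_lt(hbo[4], hbo[3])          # recovery after breathing resumes
})

test_that("TDDR repairs artifacts and leaves clean records untouched", {
  t <- seq(0, 120, by = 1 / 3.76)
  clean <- sin(2 * pi * 0.05 * t)
  expect_gt(cor(tddr(clean), clean), 0.99)
  expect_equal(tddr(rep(2, 100)), rep(2, 100))
  # 10x-amplitude spike: peak residual reduced by > 80%
  spiky <- clean; spiky[200] <- spiky[200] + 10
  y <- tddr(spiky)
  expect_lt(abs(y[200] - clean[200]), 2)
  # artifact-free noisy record passes through unchanged (repair gate)
  set.seed(5)
  noisy <- clean + rnorm(length(t), 0, 0.3)
  expect_identical(tddr(noisy), noisy)
  # motion-like baseline shift is removed
  shifted <- clean; shifted[300:length(t)] <- shifted[300:length(t)] + 5
  ys <- tddr(shifted)
  resid <- ys - clean - (mean(shifted) - mean(clean))
  expect_lt(max(abs(resid)), 0.5)
  expect_identical(tddr(c(1, 2)), c(1, 2))    # too short: identity
})

test_that("spline spike repair replaces only the flagged samples", {
  t <- seq(0, 60, by = 0.25)
  x <- sin(2 * pi * 0.05 * t)
  expect_equal(spline_spike_repair(x), x)
  xs <- x; xs[100] <- xs[100] + 8
  y <- spline_spike_repair(xs)
  expect_lt(abs(y[100] - x[100]), 0.2)
  expect_equal(y[-100], x[-100])
  # boundary spike: nearest-value fill
  xb <- x; xb[1] <- xb[1] + 8
  yb <- spline_spike_repair(xb)
  expect_equal(yb[1], xb[2])
})

test_that("moving-average detrend removes slow trends and keeps fast structure", {
  fs <- 4
  expect_equal(detrend_moving_average(rep(3, 100), fs), rep(0, 100))
  t <- seq(0, 500, by = 1 / fs)
  slow <- 0.02 * t                              # slow ramp
  fast <- sin(2 * pi * 0.05 * t)
  y <- detrend_moving_average(slow + fast, fs, kernel_s = 100)
  interior <- seq(300, length(t) - 300)
  expect_lt(sd(y[interior] - fast[interior]), 0.1 * sd(fast))
  # kernel longer than the series: global mean subtracted
  x <- rnorm(50) + 10
  expect_equal(detrend_moving_average(x, fs, kernel_s = 1e5), x - mean(x))
})

test_that("short-channel regression removes shared superficial variance", {
  set.seed(12)
  n <- 1000
  sup <- sin(2 * pi * 0.1 * (1:n) / 4) + 0.5 * rnorm(n)
  brain <- sin(2 * pi * 0.02 * (1:n) / 4)
  long <- brain + 0.8 * sup + 0.1 * rnorm(n)
  short <- sup + 0.1 * rnorm(n)
  cleaned <- short_channel_regression(long, short)
  resid_var <- function(x) var(lm.fit(cbind(1, sup), x)$fitted.values)
  expect_lt(resid_var(cleaned), 0.2 * resid_var(long))
  # orthogonal signals pass through
  orth <- short_channel_regression(brain, sup * 0 + rnorm(n))
  expect_gt(cor(orth, brain), 0.999)
  # long = short: residual ~ 0
  self <- short_channel_regression(sup, sup)
  expect_lt(sd(self - mean(self)), 1e-10)
  expect_warning(out <- short_channel_regression(long, NULL), "no short")
  expect_identical(out, long)
})

test_that("the FIR band-pass has the designed frequency response", {
  fs <- 3.76
  t <- seq(0, 1000, by = 1 / fs)
  inband <- sin(2 * pi * 0.05 * t)
  y <- bandpass_fir(inband, fs)
  mid <- seq(500, length(t) - 500)
  gain <- sd(y[mid]) / sd(inband[mid])
  expect_gt(gain, 0.9); expect_lt(gain, 1.1)
  # DC removed
  ydc <- bandpass_fir(rep(1, length(t)), fs)
  expect_lt(max(abs(ydc[mid])), 0.01)
  # cardiac-band attenuation > 20 dB
  card <- sin(2 * pi * 1 * t)
  yc <- bandpass_fir(card, fs)
  expect_lt(20 * log10(sd(yc[mid]) / sd(card[mid])), -20)
  expect_error(bandpass_fir(rnorm(20), fs, order = 600), "too short")
})

test_that("heart rate is recovered with RSA visible and noise flagged", {
  fc <- simulate_fast_cardiac_channel(duration_s = 120, seed = 2)
  hr <- heart_rate(fc$hbo_uM, fc$fs_hz)
  expect_lt(abs(median(hr$bpm) - 66), 2)
  expect_false(attr(hr, "low_confidence"))

  phys <- physiology_model(resp_hz = 0.1, rsa_depth = 0.15)
  fc2 <- simulate_fast_cardiac_channel(duration_s = 180, phys = phys,
                                       seed = 4)
  hr2 <- heart_rate(fc2$hbo_uM, fc2$fs_hz, window_s = 4, step_s = 1)
  sp <- stats::spec.pgram(stats::ts(hr2$bpm - mean(hr2$bpm), frequency = 1),
                          plot = FALSE)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 0.1), 0.03)

  set.seed(3)
  hr3 <- heart_rate(rnorm(900), 7.52)
  expect_true(attr(hr3, "low_confidence"))
  expect_error(heart_rate(rnorm(100), 4), "Nyquist")
})

test_that("the full pipeline recovers injected block amplitudes within 20%", {
  devs <- vapply(1:5, function(s) {
    ses <- task_session(paradigm_finger_tapping(), seed = s)
    hr <- hemo_pipeline(ses)
    des <- build_design(ses$events, length(ses$t_s), ses$sampling_hz)
    est <- vapply(c("right_motor", "left_motor"), function(rg) {
      long <- which(hr$pairs$sds_mm > 20 & hr$pairs$region == rg)
      g <- fit_glm(hr$dhbo[, long], des,
                   contrasts = list(lr = c(left = 1, right = -1)))
      mean(g$contrasts$lr$estimate) * (if (rg == "right_motor") 1 else -1)
    }, numeric(1))
    max(abs(est - 1))                 # truth contrast: +-1 uM
  }, numeric(1))
  expect_lt(max(devs), 0.2)
})

test_that("the pipeline is bit-reproducible and logs its stages in order", {
  ses <- task_session(paradigm_auditory(),
                      responses = response_spec_auditory(),
                      module_regions = c("0" = "left_auditory",
                                         "1" = "right_auditory"),
                      seed = 12)
  h1 <- hemo_pipeline(ses)
  h2 <- hemo_pipeline(ses)
  expect_identical(h1$dhbo, h2$dhbo)
  stages <- vapply(h1$provenance, `[[`, character(1), "stage")
  expect_equal(stages,
               c("moments_to_dmua", "mbll", "tddr", "spline_spike_repair",
                 "detrend_moving_average", "short_channel_regression"))
})
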