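# BIP / MEDPHOT / nEUROPt figures of merit.

test_that("differential non-linearity is the normalized peak-to-peak spread", {
  expect_equal(dnl(rep(1000, 64)), 0)
  expect_equal(dnl(c(90, 100, 110)), 0.2)
  # adding a constant strictly decreases the ratio
  x <- c(90, 100, 110)
  expect_lt(dnl(x + 100), dnl(x))
  expect_error(dnl(c(5)), "2 bins")
  expect_error(dnl(c(0, 0, 0)), "zero")
})

test_that("afterpulse ratio follows its definition", {
  expect_equal(afterpulse_ratio(10, 10, 1e6, 50e3, 50), 0)
  expect_equal(afterpulse_ratio(10, 2, 1e6, 50e3, 50), 8e-3)
  expect_equal(afterpulse_ratio(10, 2, 1e6, 50e3, 100),
               afterpulse_ratio(10, 2, 1e6, 50e3, 50) / 2)
  expect_error(afterpulse_ratio(10, 2, 0, 50e3, 50), "> 0")
  expect_error(afterpulse_ratio(10, 2, 1e6, 50, 50), "exceed")
})

test_that("responsivity is linear and round-trips a synthetic setup", {
  expect_equal(responsivity(0, 1e14, 2e-4), 0)
  expect_equal(responsivity(2e3, 1e14, 2e-4),
               2 * responsivity(1e3, 1e14, 2e-4))
  # closed loop: generate the photon rate from an assumed responsivity
  resp_true <- 9.97e-9
  cal <- 3.2e13; p <- 2e-4
  rate <- resp_true * cal * p
  expect_equal(responsivity(rate, cal, p), resp_true)
  expect_error(responsivity(1e3, NULL, 2e-4), "required")
})

test_that("IRF width metrics match closed forms and a dense-grid oracle", {
  # Gaussian, sigma = 100 ps -> FWHM = 235.48 ps
  tg <- time_grid(2, 2000)
  t <- time_centers(tg)
  g <- exp(-(t - 1500)^2 / (2 * 100^2))
  w <- irf_width_metrics(g, 2)
  expect_equal(w$fwhm_ps, 2 * sqrt(2 * log(2)) * 100, tolerance = 2 / 235)
  expect_equal(w$fw10_ps, 2 * sqrt(2 * log(10)) * 100, tolerance = 2 / 430)

  # pure exponential tail: decay constant recovered
  y <- exp(-pmax(t - 200, 0) / 300); y[t < 200] <- 0; y[t >= 200][1] <- 1
  w2 <- irf_width_metrics(y, 2)
  expect_equal(w2$tail_tau_ps, 300, tolerance = 0.01)

  # exGaussian versus dense brute-force widths
  fine <- time_grid(1, 8000)
  ik <- irf_curve(irf_model(), 905, fine)
  wd <- irf_width_metrics(ik, 1)
  tt <- time_centers(fine)
  brute_width <- function(frac) {
    lev <- frac * max(ik)
    idx <- range(which(ik >= lev))
    tt[idx[2]] - tt[idx[1]]
  }
  expect_equal(wd$fwhm_ps, brute_width(0.5), tolerance = 2 / 270)
  expect_equal(wd$fw10_ps, brute_width(0.1), tolerance = 2 / 700)
  expect_equal(wd$fw1_ps, brute_width(0.01), tolerance = 2 / 1400)

  # curve not reaching 1% within the window is flagged
  w3 <- irf_width_metrics(g[t > 1330 & t < 1670], 2)
  expect_false(w3$fw1_available)
})

test_that("optical-property fitting recovers noiseless truth within 1%", {
  tg <- time_grid(25, 400)
  ik <- fixture_irf(905, tg)
  props <- optical_properties(0.01, 1.0, 1.41)
  d <- simulate_dtof(scene(props), list(sds_mm = 26.5, wavelength_nm = 905),
                     ik, tg, 1e6, noise = FALSE)
  fit <- fit_optical_properties(d, ik, 26.5, 1.41)
  expect_true(fit$converged)
  expect_lt(abs(fit$mua / 0.01 - 1), 0.01)
  expect_lt(abs(fit$musp / 1.0 - 1), 0.01)
})

test_that("optical-property fitting: Poisson noise keeps median error within 5%", {
  tg <- time_grid(25, 400)
  ik <- fixture_irf(905, tg)
  props <- optical_properties(0.015, 1.2, 1.41)
  errs <- t(vapply(1:20, function(s) {
    d <- simulate_dtof(scene(props), list(sds_mm = 26.5, wavelength_nm = 905),
                       ik, tg, 1e6, noise = TRUE, seed = 100 + s)
    f <- fit_optical_properties(d, ik, 26.5, 1.41)
    c(abs(f$mua / 0.015 - 1), abs(f$musp / 1.2 - 1))
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.05)
  expect_lt(median(errs[, 2]), 0.05)
})

test_that("a non-absorbing medium fits to near-zero absorption", {
  tg <- time_grid(25, 400)
  ik <- fixture_irf(905, tg)
  d <- simulate_dtof(scene(optical_properties(1e-9, 1.0, 1.41)),
                     list(sds_mm = 26.5, wavelength_nm = 905), ik, tg, 1e6,
                     noise = FALSE)
  fit <- fit_optical_properties(d, ik, 26.5, 1.41,
                                init = c(mua = 0.005, musp = 1.2))
  expect_lt(fit$mua, 5e-4)
})

test_that("fit error grows with the absorption level", {
  tg <- time_grid(25, 400)
  ik <- fixture_irf(905, tg)
  levels <- c(0.005, 0.015, 0.025)
  med_err <- vapply(levels, function(a) {
    errs <- vapply(1:8, function(s) {
      d <- simulate_dtof(scene(optical_properties(a, 1.0, 1.41)),
                         list(sds_mm = 26.5, wavelength_nm = 905), ik, tg,
                         1e5, noise = TRUE, seed = 7 * s)
      abs(fit_optical_properties(d, ik, 26.5, 1.41)$mua / a - 1)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_gt(cor(levels, med_err), 0)
  expect_gt(med_err[3], med_err[1])
})

test_that("contrast metrics follow their definitions", {
  ref <- c(1000, 1002, 998, 1001, 999)
  cm <- contrast_metrics(ref, list(mean(ref)), measurand = "sum",
                         is_counts = TRUE)
  expect_equal(cm$C, 0)
  expect_equal(cm$CNR, 0)
  cm2 <- contrast_metrics(rep(1000, 3) + c(-1, 0, 1), list(900),
                          measurand = "sum", is_counts = TRUE)
  expect_equal(cm2$Cr, -0.1)
  # CNR scales inversely with the baseline noise
  cm_a <- contrast_metrics(c(-2, 0, 2), 5)
  cm_b <- contrast_metrics(c(-1, 0, 1), 5)
  expect_equal(cm_b$CNR / cm_a$CNR, 2)
  cm_c <- contrast_metrics(rep(1, 4), 2)
  expect_true(is.na(cm_c$CNR))
  expect_equal(attr(cm_c, "cnr_flag"), "sigma(M0) undefined")
})

test_that("stability normalization anchors the first sample at (1, 0, 0)", {
  mo <- data.frame(N = c(100, 110, 121), m1_ps = c(1000, 1010, 1020),
                   V_ps2 = c(5000, 5100, 5200))
  st <- stability_report(mo)
  expect_equal(st$N_rel[1], 1)
  expect_equal(st$m1_delta_ps[1], 0)
  expect_equal(st$V_delta_ps2[1], 0)
  expect_equal(st$N_rel, c(1, 1.1, 1.21))

  cst <- stability_report(data.frame(N = rep(50, 4), m1_ps = rep(900, 4),
                                     V_ps2 = rep(4e4, 4)))
  expect_true(all(cst$N_rel == 1))
  expect_true(all(cst$m1_delta_ps == 0))

  # drift shared with the IRF cancels in the corrected curves
  drift <- c(0, 10, 20, 30)
  mo2 <- data.frame(N = 100 * (1 - drift / 300), m1_ps = 1000 + drift,
                    V_ps2 = 5000 + 20 * drift)
  irf2 <- data.frame(N = 40 * (1 - drift / 300), m1_ps = 500 + drift,
                     V_ps2 = 2000 + 20 * drift)
  st2 <- stability_report(mo2, irf2)
  expect_gt(max(abs(st2$m1_delta_ps)), 25)
  expect_lt(max(abs(st2$corrected_m1_delta_ps)), 1e-9)
  expect_lt(max(abs(st2$corrected_N_rel - 1)), 1e-9)
  expect_lt(max(abs(st2$corrected_V_delta_ps2)), 1e-9)
})

test_that("1 s accumulation histograms are sums of short integrations", {
  tg <- time_grid(50, 100)
  set.seed(3)
  short <- lapply(1:600, function(k)
    dtof(rpois(100, 2), 50, 690, integration_time_ms = 3.5))
  acc <- accumulate_histograms(short, 3.5, 1000)
  per <- ceiling(1000 / 3.5)          # 286 histograms -> 1001 ms
  expect_equal(length(acc), floor(600 / per))
  expect_equal(acc[[1]]$integration_time_ms, per * 3.5)
  expect_equal(acc[[1]]$counts,
               Reduce(`+`, lapply(short[1:per], `[[`, "counts")))
  expect_error(accumulate_histograms(short[1:10], 3.5, 1000), "not enough")
})

test_that("depth-scan CNR profiles favor higher moments", {
  tg <- time_grid(50, 200)
  im <- irf_model()
  ch <- list(sds_mm = 26.5, wavelength_nm = 905)
  props <- optical_properties(0.01, 1.0, 1.33)
  scan <- neuropt_scan(props, ch, im, tg, depths_mm = seq(8, 36, 4),
                       volume_mm3 = 100, n_reference = 30, n_per_depth = 4,
                       target_counts = 1e6, seed = 21)
  res <- neuropt_contrast_analysis(scan, irf = fixture_irf(905, tgrid = tg))
  dl <- res$depth_limit
  expect_true(dl["sum"] <= dl["mean"])
  expect_true(dl["mean"] <= dl["variance"])
  expect_true(all(c("gate1", "gate2") %in% unique(res$table$measurand)))
})
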