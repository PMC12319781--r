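# Instrument characterization figures of merit: BIP (differential
# non-linearity, afterpulsing, responsivity, IRF width and stability),
# MEDPHOT (optical-property retrieval by curve fitting) and nEUROPt
# (depth contrast and contrast-to-noise).

#' Differential non-linearity of the timing electronics
#'
#' Peak-to-peak spread of per-bin counts under continuous-wave illumination,
#' normalized by the mean: `(max - min) / mean` over the included bins.
#'
#' @param counts per-bin counts of the CW measurement
#' @export
dnl <- function(counts) {
  if (length(counts) < 2) stop("DNL needs at least 2 bins", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative", call. = FALSE)
  m <- mean(counts)
  if (m == 0) stop("mean counts is zero", call. = FALSE)
  (max(counts) - min(counts)) / m
}

#' Afterpulse ratio
#'
#' `R_AP = (N_mean_bkg - N_mean_dark) / N_total_irf * (T_laser / dt)`:
#' the excess background in the tail of the IRF relative to the dark level,
#' normalized by the IRF intensity and scaled to the full laser period.
#'
#' @param n_mean_bkg mean background counts per bin in the IRF tail
#' @param n_mean_dark mean dark counts per bin
#' @param n_total_irf total counts in the IRF
#' @param t_laser_ps full laser period (1 / repetition rate)
#' @param bin_width_ps time bin width
#' @export
afterpulse_ratio <- function(n_mean_bkg, n_mean_dark, n_total_irf,
                             t_laser_ps, bin_width_ps) {
  .check_num(n_mean_bkg, "n_mean_bkg", lower = 0)
  .check_num(n_mean_dark, "n_mean_dark", lower = 0)
  .check_num(t_laser_ps, "t_laser_ps", lower = 1e-12)
  .check_num(bin_width_ps, "bin_width_ps", lower = 1e-12)
  if (t_laser_ps <= bin_width_ps)
    stop("laser period must exceed the bin width", call. = FALSE)
  if (n_total_irf <= 0) stop("IRF total counts must be > 0", call. = FALSE)
  (n_mean_bkg - n_mean_dark) / n_total_irf * (t_laser_ps / bin_width_ps)
}

#' Detector responsivity
#'
#' Ratio of the measured photon rate exiting a calibrated diffuse phantom to
#' the input illumination, scaled by the phantom's calibration transfer
#' factor (radiance per input power, supplied with the phantom).
#'
#' @param measured_photon_rate detected photons per second
#' @param calibration_factor calibrated phantom transfer factor
#'   (photons s^-1 W^-1 m^-2 sr^-1 exiting per input power); required.
#' @param input_power_W input illumination power (> 0)
#' @return responsivity in m^2 sr
#' @export
responsivity <- function(measured_photon_rate, calibration_factor,
                         input_power_W) {
  if (missing(calibration_factor) || is.null(calibration_factor) ||
      !is.finite(calibration_factor))
    stop("calibration_factor for the phantom is required", call. = FALSE)
  .check_num(input_power_W, "input_power_W", lower = 1e-15)
  .check_num(measured_photon_rate, "measured_photon_rate", lower = 0)
  measured_photon_rate / (calibration_factor * input_power_W)
}

#' IRF width and tail metrics
#'
#' Full width of a single-peaked IRF at 50%, 10% and 1% of its maximum
#' (linear interpolation of the crossings) and the exponential decay
#' constant of the tail, fitted log-linearly over the span from 50% down to
#' 0.05% of the peak (three decades) on the falling edge.
#'
#' @param irf a [dtof()] or numeric vector
#' @param bin_width_ps bin width when `irf` is a bare vector
#' @return list of class `irf_width_report`: `fwhm_ps`, `fw10_ps`, `fw1_ps`
#'   (NA with a flag when the curve does not reach the level), `tail_tau_ps`.
#' @export
irf_width_metrics <- function(irf, bin_width_ps = NULL) {
  if (inherits(irf, "dtof")) {
    y <- irf$counts; bw <- irf$bin_width_ps; t0 <- irf$origin_ps
  } else {
    y <- as.numeric(irf); bw <- bin_width_ps; t0 <- 0
  }
  if (is.null(bw)) stop("bin_width_ps required", call. = FALSE)
  t <- t0 + (seq_along(y) - 0.5) * bw
  ipk <- which.max(y)
  pk <- y[ipk]
  if (pk <= 0) stop("IRF peak is zero", call. = FALSE)

  width_at <- function(frac) {
    lev <- frac * pk
    lo <- y[seq_len(ipk)]
    hi <- y[ipk:length(y)]
    il <- which(lo >= lev)[1]
    ih <- ipk - 1 + rev(which(hi >= lev))[1]
    if (is.na(il) || is.na(ih) || ih >= length(y)) return(NA_real_)
    # linear interpolation of the two crossings
    tl <- if (il == 1) t[1] else
      approx(y[c(il - 1, il)], t[c(il - 1, il)], xout = lev)$y
    th <- approx(y[c(ih, ih + 1)], t[c(ih, ih + 1)], xout = lev)$y
    th - tl
  }
  fwhm <- width_at(0.5)
  fw10 <- width_at(0.1)
  fw1 <- width_at(0.01)

  # tail decay constant: log-linear fit on the falling edge, 50% .. 0.05%
  tail_idx <- which(seq_along(y) > ipk & y > 0 & y <= 0.5 * pk &
                      y >= 5e-4 * pk)
  tau <- if (length(tail_idx) >= 5) {
    fit <- lm.fit(cbind(1, t[tail_idx]), log(y[tail_idx]))
    -1 / fit$coefficients[2]
  } else NA_real_
  structure(list(fwhm_ps = fwhm, fw10_ps = fw10, fw1_ps = fw1,
                 fw1_available = !is.na(fw1),
                 tail_tau_ps = unname(tau)),
            class = "irf_width_report")
}

#' @export
print.irf_width_report <- function(x, ...) {
  cat(sprintf("<irf_width_report> FWHM %.0f ps, FW10%% %s, FW1%% %s, tail tau %.0f ps\n",
              x$fwhm_ps,
              ifelse(is.na(x$fw10_ps), "NA", sprintf("%.0f ps", x$fw10_ps)),
              ifelse(is.na(x$fw1_ps), "NA", sprintf("%.0f ps", x$fw1_ps)),
              x$tail_tau_ps))
  invisible(x)
}

#' Fit absolute optical properties to a measured DTOF (MEDPHOT)
#'
#' Levenberg-Marquardt minimization of the disparity between the measured
#' histogram and a predicted histogram obtained by convolving the measured
#' IRF with the analytical semi-infinite temporal point spread function;
#' free parameters are `mua`, `musp` and an amplitude. Residuals are
#' Poisson-weighted (`1/sqrt(model)`) inside the fit window, which spans
#' from 80% of the peak on the rising edge to 0.1% of the peak on the
#' falling edge of the measured curve.
#'
#' @param d measured [dtof()]
#' @param irf IRF on the same bin grid ([dtof()] or numeric vector)
#' @param sds_mm source-detector separation
#' @param n_refractive refractive index of the medium (1.41 for the standard
#'   phantom protocol)
#' @param init named start values `c(mua = ..., musp = ...)`
#' @param rise_fraction,fall_fraction fit-window fractions of the peak
#' @param background background level subtracted before fitting (`"auto"` or
#'   a number)
#' @return list of class `op_fit`: `mua`, `musp`, `amplitude`,
#'   `converged`, `residual_norm`, `n_window_bins`, `info`
#' @export
fit_optical_properties <- function(d, irf, sds_mm, n_refractive = 1.41,
                                   init = c(mua = 0.012, musp = 1.2),
                                   rise_fraction = 0.8,
                                   fall_fraction = 0.001,
                                   background = "auto") {
  stopifnot(inherits(d, "dtof"))
  iv <- if (inherits(irf, "dtof")) irf$counts else as.numeric(irf)
  if (length(iv) != length(d$counts))
    stop("DTOF and IRF must share the bin grid", call. = FALSE)
  bw <- d$bin_width_ps
  tg <- time_grid(bw, length(d$counts), d$origin_ps)
  bg <- if (identical(background, "auto")) dtof_background(d) else background
  y <- pmax(d$counts - bg, 0)
  ik <- iv / sum(iv)

  # fit window from the measured curve
  ipk <- which.max(y)
  pk <- y[ipk]
  i0 <- which(y[seq_len(ipk)] >= rise_fraction * pk)[1]
  i1 <- ipk - 1 + rev(which(y[ipk:length(y)] >= fall_fraction * pk))[1]
  win <- seq(i0, i1)

  n <- length(y)
  nfft <- nextn(2L * n, 2)
  Ifft <- fft(c(ik, numeric(nfft - n)))
  model_curve <- function(mua, musp) {
    props <- optical_properties(mua, musp, n_refractive)
    tp <- suppressWarnings(tpsf_semi_infinite(props, sds_mm, tg))
    m <- Re(fft(fft(c(tp, numeric(nfft - n))) * Ifft,
                inverse = TRUE))[seq_len(n)] / nfft
    pmax(m, 0)
  }

  resid_fn <- function(p) {
    mua <- exp(p[1]); musp <- exp(p[2]); amp <- exp(p[3])
    m <- amp * model_curve(mua, musp)[win]
    (y[win] - m) / sqrt(pmax(m, 1e-12))
  }

  m0 <- model_curve(init["mua"], init["musp"])
  amp0 <- sum(y[win]) / max(sum(m0[win]), 1e-300)
  p0 <- c(log(init["mua"]), log(init["musp"]), log(amp0))
  fit <- minpack.lm::nls.lm(p0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-10, ptol = 1e-10))
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("optical-property fit did not converge (info = ", fit$info, ")")
  p <- fit$par
  structure(list(mua = exp(p[1]), musp = exp(p[2]), amplitude = exp(p[3]),
                 converged = converged,
                 residual_norm = sqrt(sum(fit$fvec^2)),
                 n_window_bins = length(win), info = fit$info),
            class = "op_fit")
}

#' @export
print.op_fit <- function(x, ...) {
  cat(sprintf("<op_fit> mua = %.5f /mm, musp = %.4f /mm%s\n",
              x$mua, x$musp, if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Contrast, relative contrast and contrast-to-noise ratio
#'
#' For a measurand M with reference (baseline) samples and one value (or
#' sample set) per perturbation step: `C = M_i - M_0`,
#' `Cr = (N_i - N_0)/N_0` (for counts), and `CNR = (M_i - M_0)/sigma(M_0)`
#' with `sigma` the standard deviation of the reference across time samples.
#'
#' @param reference numeric vector of reference samples (>= 2 for CNR)
#' @param perturbed list or vector: one measurand value per depth/step
#'   (vectors of replicate samples are averaged)
#' @param measurand label; `is_counts = TRUE` additionally reports `Cr`
#' @param is_counts whether the measurand is a photon count
#' @return data frame: `measurand`, `step`, `M`, `C`, `Cr`, `CNR`
#' @export
contrast_metrics <- function(reference, perturbed, measurand = "M",
                             is_counts = FALSE) {
  if (length(reference) < 1) stop("empty reference", call. = FALSE)
  M0 <- mean(reference)
  s0 <- if (length(reference) >= 2) sd(reference) else NA_real_
  if (!is.list(perturbed)) perturbed <- as.list(perturbed)
  Mi <- vapply(perturbed, function(x) mean(as.numeric(x)), numeric(1))
  out <- data.frame(measurand = measurand, step = seq_along(Mi), M = Mi,
                    C = Mi - M0,
                    Cr = if (is_counts) (Mi - M0) / M0 else NA_real_,
                    CNR = if (!is.na(s0) && s0 > 0) (Mi - M0) / s0
                          else NA_real_)
  if (is.na(s0) || s0 == 0) attr(out, "cnr_flag") <- "sigma(M0) undefined"
  out
}

#' Moment and gate features of a DTOF for depth-contrast analysis
#'
#' Computes the three moments of the raw histogram and, after FFT
#' deconvolution of the IRF, per-gate counts on a fixed gate width.
#'
#' @param d a [dtof()]
#' @param irf IRF for deconvolution (same grid); `NULL` skips gates
#' @param gate_width_ps gate width (default 500 ps)
#' @param n_gates number of gates to report
#' @param gate_origin_ps gates start at this time (default: IRF-corrected
#'   zero = histogram origin)
#' @return named numeric vector: `sum`, `mean`, `variance`, `gate1` ...
#' @export
dtof_features <- function(d, irf = NULL, gate_width_ps = 500, n_gates = 6,
                          gate_origin_ps = NULL) {
  m <- dtof_moments(d, background = 0)
  out <- c(sum = m$N, mean = m$m1_ps, variance = m$V_ps2)
  if (!is.null(irf)) {
    tp <- deconvolve_irf(d, irf)
    if (!is.null(gate_origin_ps)) {
      # shift gate origin by dropping leading bins
      k <- max(0L, round((gate_origin_ps - tp$origin_ps) / tp$bin_width_ps))
      tp$counts <- tp$counts[(k + 1):length(tp$counts)]
    }
    g <- coarse_gates(tp, gate_width_ps, n_gates)
    out <- c(out, setNames(g$counts, paste0("gate", seq_along(g$counts))))
  }
  out
}

#' Contrast analysis of a simulated nEUROPt depth scan
#'
#' Applies [dtof_features()] to the reference series and every depth of a
#' [neuropt_scan()], and reports contrast / relative contrast / CNR per
#' measurand and depth, plus the deepest depth at which |CNR| >= `cnr_limit`
#' for each measurand.
#'
#' @param scan a [neuropt_scan()]
#' @param irf IRF density or [dtof()] on the scan grid (enables gates)
#' @param cnr_limit detectability limit (default 2)
#' @param gate_width_ps,n_gates gate settings
#' @return list: `table` (long data frame), `depth_limit` (named vector of
#'   deepest detectable depth per measurand, NA if never detected)
#' @export
neuropt_contrast_analysis <- function(scan, irf = NULL, cnr_limit = 2,
                                      gate_width_ps = 500, n_gates = 6) {
  stopifnot(inherits(scan, "neuropt_scan"))
  featmat <- function(ds) t(vapply(ds, dtof_features, irf = irf,
                                   gate_width_ps = gate_width_ps,
                                   n_gates = n_gates,
                                   FUN.VALUE = numeric(3 + if (is.null(irf)) 0
                                                       else n_gates)))
  ref <- featmat(scan$reference)
  per_depth <- lapply(scan$scans, featmat)
  meas <- colnames(ref)
  rows <- list()
  for (mname in meas) {
    cm <- contrast_metrics(ref[, mname],
                           lapply(per_depth, function(x) x[, mname]),
                           measurand = mname,
                           is_counts = mname %in% c("sum",
                                                    grep("^gate", meas,
                                                         value = TRUE)))
    cm$depth_mm <- scan$depths_mm[cm$step]
    rows[[mname]] <- cm
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  depth_limit <- vapply(meas, function(mname) {
    sub <- tab[tab$measurand == mname, ]
    ok <- which(abs(sub$CNR) >= cnr_limit)
    if (length(ok) == 0) NA_real_ else max(sub$depth_mm[ok])
  }, numeric(1))
  list(table = tab, depth_limit = depth_limit)
}

#' Normalized stability curves of a session
#'
#' Normalizes a moment time series the way long-run instrument stability is
#' reported: total counts divided by the value at the first time point, mean
#' and variance with the first time point subtracted. When an IRF moment
#' series is supplied, the IRF-corrected moments
#' ([irf_correct_moments()], referenced to the first IRF sample) are
#' normalized the same way and returned alongside the raw curves.
#'
#' @param moments_ts data frame with columns `N`, `m1_ps`, `V_ps2` (one row
#'   per time sample)
#' @param irf_moments_ts optional data frame of IRF moments, same rows
#' @return data frame with `N_rel`, `m1_delta_ps`, `V_delta_ps2` and, when
#'   IRF moments are given, the `corrected_*` versions.
#' @export
stability_report <- function(moments_ts, irf_moments_ts = NULL) {
  stopifnot(all(c("N", "m1_ps", "V_ps2") %in% names(moments_ts)),
            nrow(moments_ts) >= 2)
  out <- data.frame(
    N_rel = moments_ts$N / moments_ts$N[1],
    m1_delta_ps = moments_ts$m1_ps - moments_ts$m1_ps[1],
    V_delta_ps2 = moments_ts$V_ps2 - moments_ts$V_ps2[1])
  if (!is.null(irf_moments_ts)) {
    stopifnot(nrow(irf_moments_ts) == nrow(moments_ts))
    Nref <- irf_moments_ts$N[1]
    corr <- lapply(seq_len(nrow(moments_ts)), function(i)
      irf_correct_moments(
        structure(list(N = moments_ts$N[i], m1_ps = moments_ts$m1_ps[i],
                       V_ps2 = moments_ts$V_ps2[i]), class = "moment_set"),
        structure(list(N = irf_moments_ts$N[i],
                       m1_ps = irf_moments_ts$m1_ps[i],
                       V_ps2 = irf_moments_ts$V_ps2[i]),
                  class = "moment_set"),
        irf_reference_N = Nref))
    cN <- vapply(corr, `[[`, numeric(1), "N")
    cm <- vapply(corr, `[[`, numeric(1), "m1_ps")
    cV <- vapply(corr, `[[`, numeric(1), "V_ps2")
    out$corrected_N_rel <- cN / cN[1]
    out$corrected_m1_delta_ps <- cm - cm[1]
    out$corrected_V_delta_ps2 <- cV - cV[1]
  }
  out
}

#' Assemble BIP-style 1 s histograms from short integrations
#'
#' Sums consecutive short-integration histograms (e.g. 3.5 ms) into
#' accumulation histograms of approximately the requested duration.
#'
#' @param dtofs list of [dtof()] on a common grid, in acquisition order
#' @param integration_time_ms integration time of each input histogram
#' @param target_ms accumulation target (default 1000 ms; the realized
#'   duration is the smallest multiple of the integration time >= target)
#' @return list of summed [dtof()] objects
#' @export
accumulate_histograms <- function(dtofs, integration_time_ms = 3.5,
                                  target_ms = 1000) {
  per <- ceiling(target_ms / integration_time_ms)
  n_out <- floor(length(dtofs) / per)
  if (n_out < 1) stop("not enough histograms to accumulate", call. = FALSE)
  lapply(seq_len(n_out), function(k) {
    idx <- ((k - 1) * per + 1):(k * per)
    acc <- Reduce(`+`, lapply(dtofs[idx], `[[`, "counts"))
    d0 <- dtofs[[idx[1]]]
    dtof(acc, d0$bin_width_ps, d0$wavelength_nm,
         integration_time_ms = per * integration_time_ms,
         channel = d0$channel, origin_ps = d0$origin_ps)
  })
}
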