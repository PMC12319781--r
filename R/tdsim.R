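# Virtual time-domain instrument and scene simulator.
#
# Emulates the measurement chain of a dual-wavelength (690 / 905 nm)
# multiplexed time-domain optical module: exponentially-modified-Gaussian
# IRFs with thermal drift, DTOF formation as TPSF (*) IRF with Poisson shot
# noise, characterization scenes (MEDPHOT phantom grid, nEUROPt depth scans
# with absorbing inclusions) and block-design task sessions with layered
# hemodynamics and superficial physiology. Every generator is deterministic
# given its seed, which is recorded in the output.

# ---------------------------------------------------------------------------
# Multiplexing timing arithmetic

#' Laser multiplexing schedule
#'
#' @param integration_time_ms histogram integration time (default 3.5 ms)
#' @param n_states number of laser states in the multiplexing pattern
#' @param histograms_per_cycle histograms completing a full cycle over all
#'   modules and wavelengths
#' @export
multiplex_schedule <- function(integration_time_ms = 3.5, n_states = 38,
                               histograms_per_cycle = 76) {
  .check_num(integration_time_ms, "integration_time_ms", lower = 1e-9)
  .check_num(n_states, "n_states", lower = 1)
  .check_num(histograms_per_cycle, "histograms_per_cycle", lower = 1)
  structure(list(integration_time_ms = integration_time_ms,
                 n_states = n_states,
                 histograms_per_cycle = histograms_per_cycle),
            class = "multiplex_schedule")
}

#' Sampling rates implied by a multiplexing schedule
#'
#' Pure timing arithmetic: the histogram rate is the inverse integration
#' time; each histogram carries one wavelength, so spectroscopic (dual
#' wavelength) sampling runs at half that; a full multiplexing cycle of all
#' modules takes `histograms_per_cycle` histograms (system rate); a single
#' source is revisited every `n_states` histograms.
#'
#' @param schedule a [multiplex_schedule()]
#' @return list `histogram_hz`, `spectroscopic_hz`, `system_hz`,
#'   `single_source_hz`
#' @export
sampling_rates <- function(schedule) {
  stopifnot(inherits(schedule, "multiplex_schedule"))
  it_s <- schedule$integration_time_ms / 1000
  list(histogram_hz = 1 / it_s,
       spectroscopic_hz = 1 / (2 * it_s),
       system_hz = 1 / (schedule$histograms_per_cycle * it_s),
       single_source_hz = 1 / (schedule$n_states * it_s))
}

# ---------------------------------------------------------------------------
# IRF model: exponentially modified Gaussian with thermal drift

# exGaussian density (unit area on the real line)
.exgauss <- function(t, mu, sigma, tau) {
  z <- (t - mu) / sigma - sigma / tau
  out <- exp(sigma^2 / (2 * tau^2) - (t - mu) / tau +
               stats::pnorm(z, log.p = TRUE)) / tau
  out[!is.finite(out)] <- 0
  out
}

.exgauss_fwhm <- function(sigma, tau, mu = 0) {
  tt <- seq(mu - 6 * sigma, mu + 8 * (sigma + tau), by = min(sigma, tau) / 50)
  y <- .exgauss(tt, mu, sigma, tau)
  pk <- max(y)
  above <- range(which(y >= pk / 2))
  tt[above[2]] - tt[above[1]]
}

# solve for the Gaussian sigma giving a target exGaussian FWHM at fixed tau
.exgauss_sigma_for_fwhm <- function(fwhm, tau) {
  lo <- 1; hi <- fwhm
  f <- function(s) .exgauss_fwhm(s, tau) - fwhm
  if (f(lo) > 0)
    stop("requested IRF FWHM narrower than the exponential tail allows",
         call. = FALSE)
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(lo, hi), tol = 1e-3)$root
}

#' Instrument response function model
#'
#' Exponentially-modified-Gaussian IRF per wavelength, parameterized by its
#' full width at half maximum and exponential tail time constant (defaults:
#' 240 / 270 ps FWHM and 292 / 265 ps tail at 690 / 905 nm). Thermal drift
#' from a cold start is modeled as a saturating-exponential approach (time
#' constant `warmup_s`) of the FWHM (`fwhm_drift_ps` total), the centroid
#' (`centroid_drift_ps`) and the intensity (`intensity_drift_frac`,
#' relative).
#'
#' @param wavelengths_nm modeled wavelengths
#' @param fwhm_ps per-wavelength FWHM at session start
#' @param tau_ps per-wavelength exponential tail time constant
#' @param t0_ps nominal IRF peak position on the histogram time axis
#' @param fwhm_drift_ps asymptotic FWHM increase from cold start
#' @param centroid_drift_ps asymptotic centroid shift
#' @param intensity_drift_frac asymptotic relative intensity change
#' @param warmup_s thermal time constant of the drift
#' @export
irf_model <- function(wavelengths_nm = c(690, 905),
                      fwhm_ps = c(240, 270),
                      tau_ps = c(292, 265),
                      t0_ps = 500,
                      fwhm_drift_ps = c(45, 35),
                      centroid_drift_ps = c(20, 20),
                      intensity_drift_frac = c(-0.05, -0.05),
                      warmup_s = 2400) {
  stopifnot(length(fwhm_ps) == length(wavelengths_nm),
            length(tau_ps) == length(wavelengths_nm))
  sigma_ps <- mapply(.exgauss_sigma_for_fwhm, fwhm_ps, tau_ps)
  structure(list(wavelengths_nm = wavelengths_nm, fwhm_ps = fwhm_ps,
                 sigma_ps = sigma_ps, tau_ps = tau_ps, t0_ps = t0_ps,
                 fwhm_drift_ps = rep_len(fwhm_drift_ps, length(wavelengths_nm)),
                 centroid_drift_ps = rep_len(centroid_drift_ps,
                                             length(wavelengths_nm)),
                 intensity_drift_frac = rep_len(intensity_drift_frac,
                                                length(wavelengths_nm)),
                 warmup_s = warmup_s),
            class = "irf_model")
}

.irf_index <- function(model, wavelength_nm) {
  i <- match(wavelength_nm, model$wavelengths_nm)
  if (is.na(i)) stop("wavelength not in IRF model", call. = FALSE)
  i
}

#' Evaluate the IRF density on a time grid
#'
#' @param model an [irf_model()]
#' @param wavelength_nm wavelength
#' @param tgrid [time_grid()]
#' @param session_time_s time since cold start (drives the drift model)
#' @return per-bin density, unit area (attribute `intensity_scale` carries
#'   the relative drift of the IRF intensity)
#' @export
irf_curve <- function(model, wavelength_nm, tgrid, session_time_s = 0) {
  stopifnot(inherits(model, "irf_model"), inherits(tgrid, "time_grid"))
  i <- .irf_index(model, wavelength_nm)
  warm <- 1 - exp(-session_time_s / model$warmup_s)
  fwhm <- model$fwhm_ps[i] + warm * model$fwhm_drift_ps[i]
  tau <- model$tau_ps[i]
  sigma <- .exgauss_sigma_for_fwhm(fwhm, tau)
  mu <- model$t0_ps + warm * model$centroid_drift_ps[i]
  t <- time_centers(tgrid)
  y <- .exgauss(t, mu, sigma, tau)
  s <- sum(y) * tgrid$bin_width_ps
  if (s <= 0) stop("IRF not supported on this time grid", call. = FALSE)
  y <- y / s
  attr(y, "intensity_scale") <- 1 + warm * model$intensity_drift_frac[i]
  y
}

#' Simulated IRF histogram from the reference IRF detector
#'
#' @inheritParams irf_curve
#' @param counts expected total counts
#' @param noise add Poisson shot noise
#' @param seed RNG seed (recorded in the object)
#' @export
simulate_irf_dtof <- function(model, wavelength_nm, tgrid, counts = 1e6,
                              session_time_s = 0, noise = TRUE, seed = NULL) {
  y <- irf_curve(model, wavelength_nm, tgrid, session_time_s)
  scale <- attr(y, "intensity_scale")
  expd <- y * tgrid$bin_width_ps * counts * scale
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    expd <- rpois(length(expd), expd)
  }
  d <- dtof(expd, tgrid$bin_width_ps, wavelength_nm,
            origin_ps = tgrid$origin_ps, timestamp = session_time_s)
  d$seed <- seed
  d
}

# ---------------------------------------------------------------------------
# Scenes and DTOF synthesis

#' Measurement scene
#'
#' @param props_by_wavelength named list of [optical_properties()], names are
#'   wavelengths in nm (e.g. `list("690" = ..., "905" = ...)`); a single
#'   unnamed `optical_properties` applies to all wavelengths.
#' @param inclusion optional absorbing inclusion:
#'   `list(position_mm = c(x,y,z), volume_mm3, delta_mua)`
#' @param seed RNG seed recorded in simulated outputs
#' @export
scene <- function(props_by_wavelength, inclusion = NULL, seed = NULL) {
  if (inherits(props_by_wavelength, "optical_properties"))
    props_by_wavelength <- list(props_by_wavelength)
  stopifnot(all(vapply(props_by_wavelength, inherits, TRUE,
                       "optical_properties")))
  if (!is.null(inclusion)) {
    stopifnot(length(inclusion$position_mm) == 3,
              inclusion$volume_mm3 >= 0)
    if (inclusion$position_mm[3] < 0)
      stop("inclusion must lie inside the medium (z >= 0)", call. = FALSE)
  }
  structure(list(props = props_by_wavelength, inclusion = inclusion,
                 seed = seed),
            class = "tdot_scene")
}

.scene_props <- function(sc, wavelength_nm) {
  nm <- names(sc$props)
  if (is.null(nm) || all(nm == "")) return(sc$props[[1]])
  i <- match(as.character(wavelength_nm), nm)
  if (is.na(i)) sc$props[[1]] else sc$props[[i]]
}

# Born perturbation of the surface reflectance TPSF by a small absorbing
# inclusion, in the flux measurement convention of tpsf_semi_infinite().
# Returns the per-bin change of the reflectance density.
.inclusion_delta_tpsf <- function(props, sds_mm, tgrid, position_mm,
                                  volume_mm3, delta_mua) {
  v <- tissue_speed(props$n)
  D <- .diffusion_D(props)
  z0 <- 1 / props$musp
  zb <- 2 * boundary_reflection_A(props$n) * D
  t <- time_centers(tgrid)
  src <- c(0, 0, z0); det <- c(sds_mm, 0, z0)
  pt <- matrix(position_mm, nrow = 1)
  Gs <- .green_semi_matrix(pt, src, D, v, props$mua, zb, t)
  Gd <- .green_semi_matrix(pt, det, D, v, props$mua, zb, t)
  kern <- .rowconv(Gs, Gd, tgrid$bin_width_ps)[1, ]
  # rescale the fluence-convention kernel to the flux measurement by the
  # ratio of the two baseline curves (identical first-order time structure)
  A2 <- 2 * boundary_reflection_A(props$n)
  dsd <- sqrt(sum((src - det)^2))
  dim_sq <- sum((src - c(det[1], det[2], -det[3] - 2 * zb))^2)
  fourDvt <- 4 * D * v * t
  tpsf_flu <- (v * (pi * fourDvt)^(-1.5) * exp(-props$mua * v * t) *
                 (exp(-dsd^2 / fourDvt) - exp(-dim_sq / fourDvt))) / A2
  tpsf_flux <- tpsf_semi_infinite(props, sds_mm, tgrid)
  ratio <- ifelse(tpsf_flu > 0, tpsf_flux / tpsf_flu, 0)
  -volume_mm3 * delta_mua / A2 * kern * ratio
}

#' Simulate a measured DTOF for one channel
#'
#' Measurement = (TPSF of the scene medium) convolved with the IRF, scaled to
#' the target total counts, with optional Poisson shot noise. An absorbing
#' inclusion in the scene perturbs the TPSF through the first-order Born
#' kernel. Metadata (seed, truth) is carried on the returned object.
#'
#' @param sc a [scene()]
#' @param channel list with `sds_mm` and `wavelength_nm`
#' @param irf an [irf_model()] (or a numeric IRF density on `tgrid`)
#' @param tgrid [time_grid()]
#' @param target_counts expected total counts (> 0)
#' @param noise add Poisson noise
#' @param seed RNG seed
#' @param session_time_s session time passed to the IRF drift model
#' @export
simulate_dtof <- function(sc, channel, irf, tgrid, target_counts = 1e6,
                          noise = TRUE, seed = NULL, session_time_s = 0) {
  stopifnot(inherits(sc, "tdot_scene"), inherits(tgrid, "time_grid"))
  if (target_counts <= 0) stop("target_counts must be > 0", call. = FALSE)
  props <- .scene_props(sc, channel$wavelength_nm)
  tpsf0 <- suppressWarnings(
    tpsf_semi_infinite(props, channel$sds_mm, tgrid))
  tpsf <- tpsf0
  if (!is.null(sc$inclusion)) {
    tpsf <- tpsf + .inclusion_delta_tpsf(
      props, channel$sds_mm, tgrid, sc$inclusion$position_mm,
      sc$inclusion$volume_mm3, sc$inclusion$delta_mua)
    tpsf <- pmax(tpsf, 0)
  }
  ik <- if (inherits(irf, "irf_model"))
    irf_curve(irf, channel$wavelength_nm, tgrid, session_time_s)
  else as.numeric(irf)
  n <- tgrid$n_bins
  nfft <- nextn(2L * n, 2)
  conv <- Re(fft(fft(c(tpsf, numeric(nfft - n))) *
                   fft(c(ik, numeric(nfft - n))), inverse = TRUE))[seq_len(n)] /
    nfft * tgrid$bin_width_ps
  conv <- pmax(conv, 0)
  if (sum(conv) <= 0) stop("degenerate measurement curve", call. = FALSE)
  # the coupling gain is set by the inclusion-free medium at target_counts,
  # so an absorbing inclusion lowers the collected counts as it should
  baseline_total <- sum(tpsf0) * sum(ik) * tgrid$bin_width_ps
  expd <- conv / baseline_total * target_counts
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    expd <- rpois(length(expd), expd)
  }
  d <- dtof(expd, tgrid$bin_width_ps, channel$wavelength_nm,
            channel = channel, origin_ps = tgrid$origin_ps)
  d$seed <- seed
  d$truth <- list(mua = props$mua, musp = props$musp, n = props$n,
                  inclusion = sc$inclusion)
  d
}

# ---------------------------------------------------------------------------
# Characterization scenes

#' MEDPHOT-style phantom grid
#'
#' 12 homogeneous phantoms spanning 4 nominal reduced-scattering levels
#' (A-D) by 3 absorption levels (1, 3, 5), covering the physiological range
#' of human head tissue. Nominal values are configurable.
#'
#' @param musp_levels reduced scattering levels (1/mm), labeled A, B, C, D
#' @param mua_levels absorption levels (1/mm), labeled 1, 3, 5
#' @param n_refractive phantom refractive index
#' @return data frame: `phantom`, `scatter_label`, `absorption_label`,
#'   `mua`, `musp`, `n`
#' @export
medphot_phantom_grid <- function(musp_levels = c(0.5, 1.0, 1.5, 2.0),
                                 mua_levels = c(0.005, 0.015, 0.025),
                                 n_refractive = 1.41) {
  sl <- LETTERS[seq_along(musp_levels)]
  al <- as.character(c(1, 3, 5, 7, 9)[seq_along(mua_levels)])
  g <- expand.grid(si = seq_along(musp_levels), ai = seq_along(mua_levels),
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(phantom = paste0(sl[g$si], al[g$ai]),
             scatter_label = sl[g$si], absorption_label = al[g$ai],
             mua = mua_levels[g$ai], musp = musp_levels[g$si],
             n = n_refractive)
}

#' nEUROPt-style depth scan with an absorbing inclusion
#'
#' Simulates a reference (inclusion-free) DTOF series and one DTOF series
#' per inclusion depth (default 8 to 36 mm in 2 mm steps below the
#' source-detector plane, inclusion centered laterally between the optodes).
#' The black-target occlusion is emulated as a volume-matched localized
#' absorption increase applied through the Born kernel; truly opaque targets
#' violate the linearization, so only contrast curves (not absolute
#' equivalence) should be interpreted.
#'
#' @param baseline_props [optical_properties()] of the liquid phantom
#'   (defaults: mua 0.01, musp 1.0 at the scan wavelength)
#' @param channel list with `sds_mm`, `wavelength_nm`
#' @param irf [irf_model()] or IRF density vector
#' @param tgrid [time_grid()]
#' @param depths_mm inclusion depths
#' @param volume_mm3 inclusion volume (25, 100 or 250 in the standard set)
#' @param delta_mua equivalent absorption increase of the black target
#' @param n_reference number of reference time samples
#' @param n_per_depth number of time samples per depth
#' @param target_counts expected counts per histogram
#' @param seed RNG seed
#' @return list of class `neuropt_scan`: `reference` (list of [dtof()]),
#'   `depths_mm`, `scans` (list per depth of lists of [dtof()]), metadata.
#' @export
neuropt_scan <- function(baseline_props, channel, irf, tgrid,
                         depths_mm = seq(8, 36, by = 2),
                         volume_mm3 = 100, delta_mua = 0.2,
                         n_reference = 50, n_per_depth = 5,
                         target_counts = 1e6, seed = 1) {
  stopifnot(inherits(baseline_props, "optical_properties"))
  if (any(depths_mm < 0)) stop("depth outside medium", call. = FALSE)
  set.seed(seed)
  ref_scene <- scene(baseline_props)
  reference <- lapply(seq_len(n_reference), function(k)
    simulate_dtof(ref_scene, channel, irf, tgrid, target_counts,
                  noise = TRUE))
  scans <- lapply(depths_mm, function(dep) {
    sc <- scene(baseline_props,
                inclusion = list(position_mm = c(channel$sds_mm / 2, 0, dep),
                                 volume_mm3 = volume_mm3,
                                 delta_mua = delta_mua))
    lapply(seq_len(n_per_depth), function(k)
      simulate_dtof(sc, channel, irf, tgrid, target_counts, noise = TRUE))
  })
  structure(list(reference = reference, depths_mm = depths_mm, scans = scans,
                 channel = channel, volume_mm3 = volume_mm3,
                 delta_mua = delta_mua, target_counts = target_counts,
                 seed = seed),
            class = "neuropt_scan")
}

# ---------------------------------------------------------------------------
# Task paradigms

.paradigm <- function(df, name) {
  structure(df, paradigm = name)
}

#' Breath-hold paradigm preset
#'
#' Six 30 s paced-breathing blocks (6 s breath cycle) interleaved with six
#' 20 s breath-hold blocks.
#' @return data frame `onset_s`, `duration_s`, `condition` with attribute
#'   `breath_cycle_s`
#' @export
paradigm_breath_hold <- function() {
  onsets_p <- (0:5) * 50
  onsets_h <- onsets_p + 30
  df <- rbind(data.frame(onset_s = onsets_p, duration_s = 30,
                         condition = "paced"),
              data.frame(onset_s = onsets_h, duration_s = 20,
                         condition = "hold"))
  df <- df[order(df$onset_s), ]
  rownames(df) <- NULL
  attr(df, "breath_cycle_s") <- 6
  .paradigm(df, "breath_hold")
}

#' Passive auditory paradigm preset
#'
#' Eight 20 s story blocks and seven 20 s noise blocks in a fixed
#' pseudo-randomized order after an initial 10 s rest.
#' @export
paradigm_auditory <- function() {
  order <- c("story", "noise", "story", "noise", "story", "story", "noise",
             "story", "noise", "story", "noise", "story", "noise", "story",
             "noise")
  df <- data.frame(onset_s = 10 + 20 * (seq_along(order) - 1),
                   duration_s = 20, condition = order)
  .paradigm(df, "auditory")
}

#' Finger-tapping paradigm preset
#'
#' Ten left-hand and ten right-hand tapping blocks (17.3 s each, fixed
#' pseudo-random order), each followed by a 20 s rest. Each block contains
#' 13 trials of 0.75 s with a 0.50 s inter-trial interval (attribute
#' `trials`).
#' @export
paradigm_finger_tapping <- function() {
  order <- c("left", "right", "right", "left", "right", "left", "left",
             "right", "left", "right", "right", "left", "left", "right",
             "right", "left", "left", "right", "left", "right")
  onsets <- (seq_along(order) - 1) * (17.3 + 20)
  df <- data.frame(onset_s = onsets, duration_s = 17.3, condition = order)
  trials <- do.call(rbind, lapply(seq_along(order), function(i) {
    data.frame(block = i, condition = order[i],
               onset_s = onsets[i] + (0:12) * 1.25, duration_s = 0.75)
  }))
  out <- .paradigm(df, "finger_tapping")
  attr(out, "trials") <- trials
  out
}

.check_paradigm <- function(events) {
  stopifnot(all(c("onset_s", "duration_s", "condition") %in% names(events)))
  ev <- events[order(events$onset_s), ]
  if (nrow(ev) > 1 &&
      any(ev$onset_s[-1] < (ev$onset_s + ev$duration_s)[-nrow(ev)] - 1e-9))
    stop("overlapping blocks in paradigm", call. = FALSE)
  ev
}

# ---------------------------------------------------------------------------
# Superficial physiology

#' Superficial physiology model
#'
#' Amplitudes are superficial-layer HbO excursions in uM; HbR follows with
#' ratio `hbr_ratio`. The cardiac oscillation is frequency-modulated by the
#' respiratory signal (respiratory sinus arrhythmia).
#'
#' @param cardiac_hz,cardiac_amp_uM cardiac frequency and amplitude
#' @param resp_hz,resp_amp_uM respiratory frequency and amplitude
#' @param rsa_depth relative cardiac-frequency modulation by respiration
#' @param mayer_hz,mayer_amp_uM Mayer-wave frequency and amplitude
#' @param drift_amp_uM amplitude of a very-low-frequency drift
#' @param hbr_ratio superficial HbR = `hbr_ratio` * HbO
#' @param deep_fraction fraction of the physiological oscillations also
#'   present in the deep (cerebral) layer: systemic cardiac and
#'   Mayer-wave pulsatility propagates into cortical vasculature and is
#'   seen by long channels even after superficial-signal removal
#' @export
physiology_model <- function(cardiac_hz = 1.1, cardiac_amp_uM = 0.3,
                             resp_hz = 0.25, resp_amp_uM = 0.15,
                             rsa_depth = 0.08,
                             mayer_hz = 0.1, mayer_amp_uM = 0.1,
                             drift_amp_uM = 0.2, hbr_ratio = -0.3,
                             deep_fraction = 0.3) {
  structure(as.list(environment()), class = "physiology_model")
}

# superficial HbO time course (uM) at sample times t (s)
.physio_hbo <- function(phys, t, rng_phase = c(0, 0, 0)) {
  resp <- sin(2 * pi * phys$resp_hz * t + rng_phase[1])
  # RSA: cardiac instantaneous frequency modulated by respiration
  inst_phase <- 2 * pi * phys$cardiac_hz *
    (t + phys$rsa_depth / (2 * pi * phys$resp_hz) *
       -cos(2 * pi * phys$resp_hz * t + rng_phase[1]))
  phys$cardiac_amp_uM * sin(inst_phase + rng_phase[2]) +
    phys$resp_amp_uM * resp +
    phys$mayer_amp_uM * sin(2 * pi * phys$mayer_hz * t + rng_phase[3]) +
    phys$drift_amp_uM * sin(2 * pi * 0.004 * t)
}

#' Simulated fast-sampling channel carrying the cardiac signal
#'
#' A single superficial channel sampled at the single-source revisit rate,
#' suitable for heart-rate extraction.
#'
#' @param duration_s recording length
#' @param fs_hz sampling rate (default: single-source rate of the default
#'   schedule)
#' @param phys a [physiology_model()]
#' @param noise_sd additive white noise (uM)
#' @param seed RNG seed
#' @return list `t_s`, `hbo_uM`, `fs_hz`, `truth`
#' @export
simulate_fast_cardiac_channel <- function(duration_s = 120,
                                          fs_hz = sampling_rates(
                                            multiplex_schedule())$single_source_hz,
                                          phys = physiology_model(),
                                          noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  t <- seq(0, duration_s, by = 1 / fs_hz)
  y <- .physio_hbo(phys, t, rng_phase = runif(3, 0, 2 * pi)) +
    rnorm(length(t), 0, noise_sd)
  list(t_s = t, hbo_uM = y, fs_hz = fs_hz,
       truth = list(cardiac_hz = phys$cardiac_hz, resp_hz = phys$resp_hz,
                    seed = seed))
}

# ---------------------------------------------------------------------------
# Task sessions in channel space

#' Hemodynamic response specification for task simulation
#'
#' One row per (condition, region): deep-layer HbO/HbR block amplitudes in
#' uM. Conditions not listed evoke no response; regions are labels attached
#' to modules of the simulated layout.
#'
#' @param condition,region character vectors (recycled to common length)
#' @param dhbo_uM,dhbr_uM amplitudes
#' @export
response_spec <- function(condition, region, dhbo_uM, dhbr_uM = -0.25 * dhbo_uM) {
  data.frame(condition = condition, region = region,
             dhbo_uM = dhbo_uM, dhbr_uM = dhbr_uM)
}

#' @rdname response_spec
#' @export
response_spec_finger_tapping <- function() {
  response_spec(condition = c("left", "right"),
                region = c("right_motor", "left_motor"),
                dhbo_uM = c(1, 1))
}

#' @rdname response_spec
#' @export
response_spec_auditory <- function() {
  response_spec(condition = c("story", "story", "noise", "noise"),
                region = c("left_auditory", "right_auditory",
                           "left_auditory", "right_auditory"),
                dhbo_uM = c(1, 1, 0.3, 0.3))
}

#' Simulate a block-design task session in channel space
#'
#' Builds, for each simulated module, the layered moment sensitivities of its
#' three intra-module separations, drives the deep layer with
#' condition-specific hemodynamic responses (block regressor convolved with
#' the canonical HRF) and the superficial layer with shared physiology, maps
#' the layered absorption changes at both wavelengths through the
#' sensitivities into moment feature time series (relative intensity, mean
#' time-of-flight, variance), and adds photon-counting noise appropriate for
#' the per-histogram count level. Ground-truth time courses and seeds are
#' recorded.
#'
#' @param paradigm event data frame (see [paradigm_finger_tapping()] etc.)
#' @param responses a [response_spec()] (amplitudes may be zero for a null
#'   session)
#' @param module_regions named character vector mapping module ids to region
#'   labels, e.g. `c("0" = "left_motor", "1" = "right_motor")`; one module
#'   per region is simulated.
#' @param baseline list of [optical_properties()] per wavelength for the
#'   two-layer background (superficial and deep identical by default)
#' @param phys a [physiology_model()]; `NULL` disables superficial signals
#' @param sampling_hz feature sampling rate (default: system rate 3.76 Hz)
#' @param counts_per_histogram expected DTOF counts driving the noise level
#' @param extinction extinction table from [extinction_table()]
#' @param tgrid time grid for the sensitivity model
#' @param seed RNG seed
#' @param rest_tail_s rest appended after the last block
#' @return `task_session` object: `features` array
#'   `[channel, time, c(intensity, meantime, variance)]` (absolute units:
#'   relative counts, ps, ps^2), `channels`, `t_s`, `sampling_hz`, `events`,
#'   `truth` (regional hemodynamics, superficial physiology, sensitivities,
#'   baselines, seed).
#' @export
task_session <- function(paradigm,
                         responses = response_spec_finger_tapping(),
                         module_regions = c("0" = "left_motor",
                                            "1" = "right_motor"),
                         baseline = NULL,
                         phys = physiology_model(),
                         sampling_hz = sampling_rates(multiplex_schedule())$system_hz,
                         counts_per_histogram = 1e5,
                         extinction = extinction_table(),
                         tgrid = time_grid(20, 256),
                         seed = 1) {
  events <- .check_paradigm(paradigm)
  set.seed(seed)
  wl <- c(690, 905)
  if (is.null(baseline))
    baseline <- list(`690` = optical_properties(0.0095, 1.1, 1.4),
                     `905` = optical_properties(0.0125, 0.95, 1.4))
  duration <- max(events$onset_s + events$duration_s) + 20
  t_s <- seq(0, duration, by = 1 / sampling_hz)
  nt <- length(t_s)

  # regional deep-layer hemodynamics: block wave (x) canonical HRF
  regions <- unique(unname(module_regions))
  hb_deep <- lapply(regions, function(rg) {
    hbo <- numeric(nt); hbr <- numeric(nt)
    rs <- responses[responses$region == rg, , drop = FALSE]
    for (k in seq_len(nrow(rs))) {
      ev <- events[events$condition == rs$condition[k], , drop = FALSE]
      if (nrow(ev) == 0) next
      reg <- .block_regressor(ev, t_s, sampling_hz)
      hbo <- hbo + rs$dhbo_uM[k] * reg
      hbr <- hbr + rs$dhbr_uM[k] * reg
    }
    list(hbo = hbo, hbr = hbr)
  })
  names(hb_deep) <- regions

  # shared superficial physiology
  if (!is.null(phys)) {
    ph <- runif(3, 0, 2 * pi)
    hbo_sup <- .physio_hbo(phys, t_s, ph)
    hbr_sup <- phys$hbr_ratio * hbo_sup
    # cerebral share of the systemic oscillations, phase-shifted
    ph_deep <- ph + c(0, pi / 4, pi / 6)
    hbo_deep_phys <- phys$deep_fraction * .physio_hbo(phys, t_s, ph_deep)
    hbr_deep_phys <- phys$hbr_ratio * hbo_deep_phys
  } else {
    hbo_sup <- numeric(nt); hbr_sup <- numeric(nt)
    hbo_deep_phys <- numeric(nt); hbr_deep_phys <- numeric(nt)
  }
  hb_deep_task <- hb_deep
  hb_deep <- lapply(hb_deep, function(h)
    list(hbo = h$hbo + hbo_deep_phys, hbr = h$hbr + hbr_deep_phys))

  # channels: default module geometry per region
  mod_ids <- as.integer(names(module_regions))
  chans <- do.call(rbind, lapply(mod_ids, function(mid) {
    ch <- enumerate_channels(optical_module(module_id = mid), max_sds_mm = 30)
    ch$region <- module_regions[as.character(mid)]
    ch
  }))
  chans$sds_mm <- round(chans$sds_mm, 3)

  # layered moment sensitivities per (sds, wavelength)
  sds_u <- sort(unique(chans$sds_mm))
  S <- list()
  base_moments <- list()
  for (w in wl) {
    pw <- baseline[[as.character(w)]]
    for (s in sds_u) {
      key <- paste(w, s)
      ls <- layer_sensitivities(
        medium_two_layer(pw, pw, 12), sds_mm = s, tgrid = tgrid)
      S[[key]] <- ls$S
      tp <- suppressWarnings(tpsf_semi_infinite(pw, s, tgrid))
      base_moments[[key]] <- .curve_moments(tp, time_centers(tgrid))
    }
  }

  # extinction matrix rows per wavelength: dmua = eps_hbo*dHbO + eps_hbr*dHbR
  E <- extinction_matrix(extinction, wl)

  nch <- nrow(chans)
  features <- array(NA_real_, dim = c(nch, nt, 3),
                    dimnames = list(NULL, NULL,
                                    c("intensity", "meantime", "variance")))
  for (i in seq_len(nch)) {
    w <- chans$wavelength_nm[i]
    key <- paste(w, chans$sds_mm[i])
    Sw <- S[[key]]
    ew <- E[as.character(w), ]
    rg <- chans$region[i]
    dmua_sup <- ew["hbo"] * hbo_sup + ew["hbr"] * hbr_sup
    dmua_deep <- ew["hbo"] * hb_deep[[rg]]$hbo + ew["hbr"] * hb_deep[[rg]]$hbr
    df <- Sw %*% rbind(dmua_sup, dmua_deep)     # 3 x nt
    bm <- base_moments[[key]]
    Nc <- counts_per_histogram
    sig <- c(1 / sqrt(Nc),
             sqrt(bm$V / Nc),
             sqrt(max(bm$m4c - bm$V^2, 0) / Nc))
    noise <- matrix(rnorm(3L * nt), nrow = 3) * sig
    abs_feat <- rbind(1 + df[1, ], bm$m1 + df[2, ], bm$V + df[3, ]) + noise
    features[i, , ] <- t(abs_feat)
  }

  structure(list(features = features, channels = chans, t_s = t_s,
                 sampling_hz = sampling_hz, events = events,
                 truth = list(hb_deep = hb_deep_task,
                              hb_deep_total = hb_deep, hbo_sup = hbo_sup,
                              hbr_sup = hbr_sup, S = S,
                              base_moments = base_moments,
                              baseline = baseline, extinction = E,
                              counts_per_histogram = counts_per_histogram,
                              seed = seed)),
            class = "task_session")
}

# block square wave convolved with the canonical HRF, unit plateau
.block_regressor <- function(events, t_s, fs) {
  box <- numeric(length(t_s))
  for (k in seq_len(nrow(events)))
    box[t_s >= events$onset_s[k] &
          t_s < events$onset_s[k] + events$duration_s[k]] <- 1
  h <- canonical_hrf(seq(0, 32, by = 1 / fs))
  h <- h / max(cumsum(h) / fs)    # unit response to a sustained block
  out <- convolve(box, rev(h), type = "open")[seq_along(box)] / fs
  out
}

# moments (and 4th central moment) of a nonnegative curve
.curve_moments <- function(y, t) {
  N <- sum(y)
  m1 <- sum(t * y) / N
  V <- sum((t - m1)^2 * y) / N
  m4c <- sum((t - m1)^4 * y) / N
  list(N = N, m1 = m1, V = V, m4c = m4c)
}
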