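# DTOF (distribution of times of flight) data model and featurization:
# moments, IRF drift correction, FFT deconvolution, coarse time gates, and
# histogram-shape channel selection.

#' Construct a DTOF histogram object
#'
#' @param counts per-bin photon counts (nonnegative; expected values allowed)
#' @param bin_width_ps bin width
#' @param wavelength_nm wavelength tag (690 or 905 for the default instrument)
#' @param integration_time_ms histogram integration time
#' @param channel optional channel descriptor (list or data-frame row)
#' @param origin_ps left edge of the first bin
#' @param timestamp optional acquisition time tag (seconds)
#' @export
dtof <- function(counts, bin_width_ps, wavelength_nm = NA_real_,
                 integration_time_ms = NA_real_, channel = NULL,
                 origin_ps = 0, timestamp = NA_real_) {
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative", call. = FALSE)
  .check_num(bin_width_ps, "bin_width_ps", lower = 1e-12)
  structure(list(counts = as.numeric(counts),
                 bin_width_ps = bin_width_ps,
                 origin_ps = origin_ps,
                 wavelength_nm = wavelength_nm,
                 integration_time_ms = integration_time_ms,
                 channel = channel,
                 timestamp = timestamp),
            class = "dtof")
}

#' @export
print.dtof <- function(x, ...) {
  cat(sprintf("<dtof> %d bins x %.0f ps, %.3g counts, %s nm\n",
              length(x$counts), x$bin_width_ps, sum(x$counts),
              format(x$wavelength_nm)))
  invisible(x)
}

.dtof_centers <- function(d) d$origin_ps + (seq_along(d$counts) - 0.5) * d$bin_width_ps

#' Estimate the background (dark) level of a DTOF from pre-peak bins
#'
#' Median of the bins preceding the rising edge, excluding a guard interval
#' before the edge. The rising edge is detected at 25% of the peak above
#' the histogram floor (the median of the lowest-quintile bins), so the
#' estimate also works for signals riding on a strong dark level. Returns 0
#' when no usable pre-peak window exists.
#'
#' @param d a [dtof()]
#' @param guard_ps guard interval before the rising edge excluded from the
#'   background window
#' @export
dtof_background <- function(d, guard_ps = 250) {
  stopifnot(inherits(d, "dtof"))
  c0 <- d$counts
  ipk <- which.max(c0)
  floor_lvl <- stats::median(sort(c0)[seq_len(max(3L, length(c0) %/% 5))])
  thr <- floor_lvl + 0.25 * (c0[ipk] - floor_lvl)
  rise <- which(c0[seq_len(ipk)] > thr)[1]
  if (is.na(rise)) return(0)
  last <- rise - 1L - ceiling(guard_ps / d$bin_width_ps)
  if (last < 3L) return(0)
  stats::median(c0[seq_len(last)])
}

#' Moments of a DTOF
#'
#' Total counts N, mean time-of-flight m1 (ps) and variance V (ps^2) of the
#' background-subtracted histogram, computed at bin centers over the full
#' histogram (or an explicit window).
#'
#' @param d a [dtof()]
#' @param background background level per bin to subtract: a number, or
#'   `"auto"` to estimate from pre-peak bins ([dtof_background()]).
#' @param window optional `c(t_min_ps, t_max_ps)` restricting the moment
#'   integration window (bin centers inside the window are used).
#' @return list of class `moment_set`: `N`, `m1_ps`, `V_ps2`.
#' @export
dtof_moments <- function(d, background = 0, window = NULL) {
  stopifnot(inherits(d, "dtof"))
  bg <- if (identical(background, "auto")) dtof_background(d) else background
  .check_num(bg, "background", lower = 0)
  cc <- pmax(d$counts - bg, 0)
  t <- .dtof_centers(d)
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    cc <- cc[keep]; t <- t[keep]
  }
  N <- sum(cc)
  if (N <= 0) stop("all-zero histogram after background subtraction",
                   call. = FALSE)
  m1 <- sum(t * cc) / N
  V <- sum((t - m1)^2 * cc) / N
  structure(list(N = N, m1_ps = m1, V_ps2 = V), class = "moment_set")
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf("<moment_set> N = %.4g, m1 = %.1f ps, V = %.1f ps^2\n",
              x$N, x$m1_ps, x$V_ps2))
  invisible(x)
}

#' IRF-correct DTOF moments using the reference IRF detector
#'
#' Under convolution (`DTOF = TPSF (*) IRF`) the moments compose: total
#' counts multiply, mean times and variances add. The instrument drift seen
#' by the internal IRF detector is therefore removed by dividing counts by
#' the relative IRF intensity and subtracting the IRF mean time and variance:
#' `N' = N / (N_irf / N_irf_ref)`, `m1' = m1 - m1_irf`, `V' = V - V_irf`.
#'
#' @param dtof_moments,irf_moments `moment_set`s from the same wavelength and
#'   time window
#' @param irf_reference_N reference IRF intensity (the session's first IRF
#'   sample by convention); defaults to `irf_moments$N` (pure shape
#'   correction, counts unchanged).
#' @export
irf_correct_moments <- function(dtof_moments, irf_moments,
                                irf_reference_N = irf_moments$N) {
  stopifnot(inherits(dtof_moments, "moment_set"),
            inherits(irf_moments, "moment_set"))
  if (irf_moments$N <= 0) stop("IRF total counts must be > 0", call. = FALSE)
  structure(list(N = dtof_moments$N / (irf_moments$N / irf_reference_N),
                 m1_ps = dtof_moments$m1_ps - irf_moments$m1_ps,
                 V_ps2 = dtof_moments$V_ps2 - irf_moments$V_ps2),
            class = "moment_set")
}

#' FFT deconvolution of the IRF from a DTOF
#'
#' Wiener-style frequency-domain division with a regularization term that
#' dampens high-frequency content:
#' \deqn{\hat{T}(f) = D(f)\,\bar{I}(f) / (|I(f)|^2 + \alpha\,\max|I|^2),}
#' followed by clamping to nonnegative values and renormalization to the
#' input total counts.
#'
#' @param d measured [dtof()]
#' @param irf IRF histogram ([dtof()] or numeric vector on the same grid)
#' @param regularization relative damping factor `alpha` (> 0)
#' @return a [dtof()] holding the TPSF estimate
#' @export
deconvolve_irf <- function(d, irf, regularization = 1e-4) {
  stopifnot(inherits(d, "dtof"))
  iv <- if (inherits(irf, "dtof")) irf$counts else as.numeric(irf)
  if (length(iv) != length(d$counts))
    stop("DTOF and IRF must share the bin grid", call. = FALSE)
  if (sum(iv) <= 0) stop("IRF spectrum is zero at DC", call. = FALSE)
  .check_num(regularization, "regularization", lower = 1e-15)
  iv <- iv / sum(iv)                      # unit-area kernel
  n <- length(d$counts)
  nfft <- nextn(2L * n, 2)
  Df <- fft(c(d$counts, numeric(nfft - n)))
  If <- fft(c(iv, numeric(nfft - n)))
  P <- Mod(If)^2
  Tf <- Df * Conj(If) / (P + regularization * max(P))
  est <- Re(fft(Tf, inverse = TRUE))[seq_len(n)] / nfft
  est <- pmax(est, 0)
  if (sum(est) > 0) est <- est * sum(d$counts) / sum(est)
  dtof(est, d$bin_width_ps, d$wavelength_nm, d$integration_time_ms,
       d$channel, d$origin_ps, d$timestamp)
}

#' Coarsen a time-resolved curve into fixed-width gates
#'
#' Sums per-bin counts into consecutive gates (default 500 ps: 0-500,
#' 500-1000, ...). If the gate width is not a multiple of the bin width the
#' curve is first resampled onto a compatible grid by linear interpolation
#' of the cumulative counts, and the result is flagged (`resampled`).
#'
#' @param d a [dtof()] (typically an IRF-deconvolved TPSF estimate)
#' @param gate_width_ps gate width
#' @param n_gates number of gates; default covers the full histogram
#' @return `gate_vector`: list with `edges_ps`, `counts`, `resampled`.
#' @export
coarse_gates <- function(d, gate_width_ps = 500, n_gates = NULL) {
  stopifnot(inherits(d, "dtof"))
  .check_num(gate_width_ps, "gate_width_ps", lower = 1e-9)
  span <- length(d$counts) * d$bin_width_ps
  if (is.null(n_gates)) n_gates <- floor(span / gate_width_ps)
  stopifnot(n_gates >= 1)
  edges <- d$origin_ps + gate_width_ps * (0:n_gates)
  ratio <- gate_width_ps / d$bin_width_ps
  resampled <- abs(ratio - round(ratio)) > 1e-9
  bin_edges <- d$origin_ps + d$bin_width_ps * (0:length(d$counts))
  cum <- c(0, cumsum(d$counts))
  cg <- approx(bin_edges, cum, xout = pmin(edges, max(bin_edges)),
               rule = 2)$y
  structure(list(edges_ps = edges, counts = diff(cg), resampled = resampled),
            class = "gate_vector")
}

#' Default histogram-shape channel-selection criteria
#'
#' Four independently switchable rules (set a threshold to `NA` to disable):
#' minimum total counts, saturation ceiling on the peak bin, minimum
#' peak-to-background ratio, and a DTOF-width sanity band relative to the
#' IRF width (a physical DTOF is broader than the IRF but not arbitrarily
#' so).
#'
#' @param min_total minimum background-subtracted total counts
#' @param saturation_peak ceiling on the raw peak-bin count
#' @param min_peak_to_background minimum ratio of peak to background level
#' @param width_ratio_range allowed range of DTOF FWHM / IRF FWHM
#' @export
channel_criteria <- function(min_total = 1000,
                             saturation_peak = 2^15,
                             min_peak_to_background = 20,
                             width_ratio_range = c(1, 20)) {
  structure(list(min_total = min_total, saturation_peak = saturation_peak,
                 min_peak_to_background = min_peak_to_background,
                 width_ratio_range = width_ratio_range),
            class = "channel_criteria")
}

.fwhm_of <- function(counts, bw) {
  pk <- max(counts)
  if (pk <= 0) return(NA_real_)
  above <- which(counts >= pk / 2)
  (max(above) - min(above) + 1) * bw
}

#' Histogram-shape channel selection
#'
#' Annotates each DTOF pass/fail on the rules of [channel_criteria()];
#' a pure function of (DTOF, IRF, criteria).
#'
#' @param dtofs list of [dtof()] objects (names used as channel labels)
#' @param irf IRF histogram ([dtof()]) used for the width sanity rule
#' @param criteria a [channel_criteria()]
#' @return data frame: `channel`, `keep`, `reason` (comma-joined failed
#'   rules, `""` when kept), plus the measured quantities.
#' @export
select_channels <- function(dtofs, irf, criteria = channel_criteria()) {
  stopifnot(is.list(dtofs), inherits(criteria, "channel_criteria"))
  if (inherits(dtofs, "dtof")) dtofs <- list(dtofs)
  irf_fwhm <- if (!is.null(irf)) .fwhm_of(irf$counts, irf$bin_width_ps) else NA
  labels <- names(dtofs)
  if (is.null(labels)) labels <- as.character(seq_along(dtofs))
  rows <- lapply(seq_along(dtofs), function(k) {
    d <- dtofs[[k]]
    bg <- dtof_background(d)
    tot <- sum(pmax(d$counts - bg, 0))
    pk <- max(d$counts)
    p2b <- if (bg > 0) pk / bg else Inf
    fw <- .fwhm_of(pmax(d$counts - bg, 0), d$bin_width_ps)
    wr <- if (is.na(irf_fwhm)) NA_real_ else fw / irf_fwhm
    fails <- character()
    cr <- criteria
    if (!is.na(cr$min_total) && tot < cr$min_total)
      fails <- c(fails, "min-total-counts")
    if (!is.na(cr$saturation_peak) && pk >= cr$saturation_peak)
      fails <- c(fails, "saturation")
    if (!is.na(cr$min_peak_to_background) && p2b < cr$min_peak_to_background)
      fails <- c(fails, "peak-to-background")
    if (!any(is.na(cr$width_ratio_range)) && !is.na(wr) &&
        (wr < cr$width_ratio_range[1] || wr > cr$width_ratio_range[2]))
      fails <- c(fails, "width-vs-irf")
    data.frame(channel = labels[k], keep = length(fails) == 0L,
               reason = paste(fails, collapse = ","),
               total_counts = tot, peak = pk, peak_to_background = p2b,
               fwhm_ratio = wr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
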