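# GLM inference on channel or voxel time series: design construction with a
# canonical double-gamma HRF, ordinary-least-squares fitting with contrast
# t-statistics, and block epoch averaging.

#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = g(t; 6, 1) - ratio * g(t; 16, 1)` with gamma densities `g`,
#' peaking near 6 s with an undershoot near 16 s; normalized to unit peak.
#'
#' @param t_s time in seconds (>= 0)
#' @param peak_s,undershoot_s gamma shape parameters (seconds; rate 1/s)
#' @param ratio undershoot amplitude ratio (default 1/6)
#' @export
canonical_hrf <- function(t_s, peak_s = 6, undershoot_s = 16, ratio = 1 / 6) {
  h <- dgamma(t_s, shape = peak_s, rate = 1) -
    ratio * dgamma(t_s, shape = undershoot_s, rate = 1)
  h / max(dgamma(seq(0, peak_s * 3, by = 0.01), shape = peak_s, rate = 1) -
            ratio * dgamma(seq(0, peak_s * 3, by = 0.01),
                           shape = undershoot_s, rate = 1))
}

#' Build a GLM design matrix for a block paradigm
#'
#' One column per condition (block square wave convolved with the canonical
#' HRF), plus an intercept, a linear drift and low-frequency cosine terms up
#' to `cosine_cutoff_hz`.
#'
#' @param events data frame `onset_s`, `duration_s`, `condition`
#' @param n_samples number of time samples
#' @param sampling_hz sampling rate
#' @param hrf function of time in seconds returning the HRF (default
#'   [canonical_hrf()])
#' @param linear_drift include a linear drift column
#' @param cosine_cutoff_hz highest cosine drift frequency (default 1/128 Hz;
#'   `0` disables the cosine basis)
#' @return list of class `design_matrix`: `X`, `labels`, `condition_cols`,
#'   `sampling_hz`, `rank`; a warning is raised (and `collinear = TRUE`
#'   set) when the design is rank deficient.
#' @export
build_design <- function(events, n_samples, sampling_hz,
                         hrf = canonical_hrf, linear_drift = TRUE,
                         cosine_cutoff_hz = 1 / 128) {
  t_s <- (seq_len(n_samples) - 1) / sampling_hz
  if (nrow(events) > 0 &&
      any(events$onset_s + events$duration_s > max(t_s) + 1 / sampling_hz))
    stop("events extend beyond the sampled series", call. = FALSE)
  conds <- sort(unique(events$condition))
  hker <- hrf(seq(0, 32, by = 1 / sampling_hz))
  hker <- hker / max(cumsum(hker) / sampling_hz)
  task <- sapply(conds, function(cn) {
    ev <- events[events$condition == cn, , drop = FALSE]
    box <- numeric(n_samples)
    for (k in seq_len(nrow(ev)))
      box[t_s >= ev$onset_s[k] & t_s < ev$onset_s[k] + ev$duration_s[k]] <- 1
    convolve(box, rev(hker), type = "open")[seq_len(n_samples)] / sampling_hz
  })
  if (length(conds) == 0) task <- matrix(numeric(0), n_samples, 0)

  drift <- cbind(intercept = rep(1, n_samples))
  if (linear_drift)
    drift <- cbind(drift, drift_linear = scale(t_s, scale = FALSE)[, 1])
  if (cosine_cutoff_hz > 0) {
    dur <- n_samples / sampling_hz
    K <- floor(2 * dur * cosine_cutoff_hz)
    if (K >= 1) {
      cosb <- sapply(seq_len(K), function(k)
        cos(pi * k * (2 * seq_len(n_samples) - 1) / (2 * n_samples)))
      colnames(cosb) <- paste0("cosine", seq_len(K))
      drift <- cbind(drift, cosb)
    }
  }
  X <- cbind(task, drift)
  labels <- colnames(X)
  if (any(colSums(abs(X)) == 0))
    stop("design contains an all-zero column", call. = FALSE)
  r <- qr(X)$rank
  collinear <- r < ncol(X)
  if (collinear) warning("design matrix is rank deficient")
  structure(list(X = X, labels = labels,
                 condition_cols = seq_along(conds),
                 conditions = conds, sampling_hz = sampling_hz,
                 rank = r, collinear = collinear),
            class = "design_matrix")
}

#' Fit a GLM and evaluate contrasts
#'
#' Ordinary least squares `y = X beta + eps`; for each contrast `c`,
#' `t = c' beta / sqrt(sigma2 * c' (X'X)^{-1} c)` with
#' `dof = n - rank(X)` and a two-sided p-value.
#'
#' @param y numeric vector or matrix `[time x units]`
#' @param design a `design_matrix` from [build_design()] (or a bare matrix)
#' @param contrasts named list; each element is either a full-length
#'   numeric vector over design columns or a named vector over condition
#'   labels (zeros elsewhere)
#' @return list of class `glm_result`: `beta` `[cols x units]`, `sigma2`,
#'   `dof`, and `contrasts`: per contrast a data frame `estimate`, `se`,
#'   `t`, `p` (one row per unit)
#' @export
fit_glm <- function(y, design, contrasts = list()) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  labels <- colnames(X)
  Y <- as.matrix(y)
  if (nrow(Y) != nrow(X)) stop("length mismatch between y and X", call. = FALSE)
  qx <- qr(X)
  r <- qx$rank
  if (r < ncol(X)) warning("rank-deficient design; using pseudoinverse")
  beta <- qr.coef(qx, Y)
  beta[is.na(beta)] <- 0
  resid <- Y - X %*% beta
  dof <- nrow(Y) - r
  sigma2 <- colSums(resid^2) / dof
  XtXinv <- tryCatch(chol2inv(qr.R(qx)[seq_len(r), seq_len(r), drop = FALSE]),
                     error = function(e) MASS_ginv(crossprod(X)))
  # embed back when rank deficient (pivoting)
  if (r < ncol(X)) {
    full <- matrix(0, ncol(X), ncol(X))
    piv <- qx$pivot[seq_len(r)]
    full[piv, piv] <- XtXinv
    XtXinv <- full
  }

  expand_contrast <- function(cv) {
    if (!is.null(names(cv)) && !all(names(cv) %in% labels) )
      stop("unknown contrast labels: ",
           paste(setdiff(names(cv), labels), collapse = ", "), call. = FALSE)
    if (!is.null(names(cv))) {
      full <- setNames(numeric(ncol(X)), labels)
      full[names(cv)] <- cv
      full
    } else {
      stopifnot(length(cv) == ncol(X))
      cv
    }
  }
  cres <- lapply(contrasts, function(cv) {
    cc <- expand_contrast(cv)
    est <- as.numeric(crossprod(cc, beta))
    se <- sqrt(pmax(sigma2 * as.numeric(crossprod(cc, XtXinv %*% cc)), 0))
    tt <- ifelse(se > 0, est / se, 0)
    data.frame(estimate = est, se = se, t = tt,
               p = 2 * pt(-abs(tt), dof))
  })
  structure(list(beta = beta, sigma2 = sigma2, dof = dof,
                 contrasts = cres, rank = r),
            class = "glm_result")
}

# minimal Moore-Penrose pseudoinverse (SVD), used only for degenerate designs
MASS_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Epoch (block) averaging of a time series
#'
#' Windows the series around every block onset (`window`, seconds relative
#' to onset), baselines each epoch by its own pre-onset mean
#' (`baseline_window`) and averages per condition. Epochs whose window
#' extends outside the recording are dropped with a warning; conditions
#' with no usable epochs are omitted with a warning.
#'
#' @param x numeric vector (one channel/voxel)
#' @param events data frame `onset_s`, `duration_s`, `condition`
#' @param sampling_hz sampling rate
#' @param window epoch window `c(-5, 30)` seconds
#' @param baseline_window baseline window `c(-5, -1)` seconds
#' @return list of class `epoch_set`: per condition `time_s`, `mean`, `se`,
#'   `n_epochs`, plus `window`, `baseline_window`
#' @export
epoch_average <- function(x, events, sampling_hz, window = c(-5, 30),
                          baseline_window = c(-5, -1)) {
  n <- length(x)
  i_rel <- seq(round(window[1] * sampling_hz), round(window[2] * sampling_hz))
  time_s <- i_rel / sampling_hz
  ibase <- which(time_s >= baseline_window[1] & time_s <= baseline_window[2])
  out <- list()
  for (cn in sort(unique(events$condition))) {
    ev <- events[events$condition == cn, , drop = FALSE]
    eps <- list()
    for (k in seq_len(nrow(ev))) {
      i0 <- round(ev$onset_s[k] * sampling_hz) + 1L
      idx <- i0 + i_rel
      if (min(idx) < 1 || max(idx) > n) next   # truncation rule: drop
      ep <- x[idx]
      eps[[length(eps) + 1]] <- ep - mean(ep[ibase])
    }
    if (length(eps) < nrow(ev))
      warning(sprintf("condition '%s': %d epoch(s) outside the recording dropped",
                      cn, nrow(ev) - length(eps)))
    if (length(eps) == 0) {
      warning(sprintf("condition '%s' has no usable epochs; omitted", cn))
      next
    }
    M <- do.call(cbind, eps)
    out[[cn]] <- list(time_s = time_s, mean = rowMeans(M),
                      se = apply(M, 1, sd) / sqrt(ncol(M)),
                      n_epochs = ncol(M))
  }
  structure(c(out, list(window = window, baseline_window = baseline_window)),
            class = "epoch_set")
}
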