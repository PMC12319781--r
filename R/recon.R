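# Moment-based linear TD-DOT reconstruction on a voxel basis: Jacobian
# assembly with per-data-type [-1, 1] normalization, Tikhonov-regularized
# Moore-Penrose inversion, differential time-series recovery, and ROI
# extraction. The intensity-only subset reproduces what a continuous-wave
# system would measure.

#' Assemble the multi-data-type Jacobian stack of a channel set
#'
#' Stacks the voxel Jacobians of every channel, mapped to the requested
#' data types (intensity as relative change dN/N, mean time-of-flight,
#' variance), for absorption and optionally reduced scattering columns.
#' Each data-type block is normalized to the [-1, 1] range by its maximum
#' absolute entry; the factors are recorded so the same normalization can
#' be applied to measured data.
#'
#' @param channels data frame from [enumerate_channels()] (one wavelength;
#'   optode x/y positions are taken from the midpoint and separation along
#'   x by convention of the slab frame) — or a data frame with explicit
#'   `src_x, src_y, det_x, det_y` columns.
#' @param medium `voxel_slab` medium from [medium_voxel_slab()]
#' @param tgrid [time_grid()]
#' @param data_types subset of `c("intensity", "meantime", "variance")`
#' @param parameters subset of `c("mua", "musp")`
#' @return `jacobian_stack`: `J` (normalized, rows = data types x channels,
#'   columns = voxels x parameters), `row_meta`, `col_meta`,
#'   `norm_factors`, `grid`, `channels`, `model_moments` (per channel
#'   N/m1/V/m4c of the model curve), `tgrid`
#' @export
assemble_jacobian <- function(channels, medium, tgrid,
                              data_types = c("intensity", "meantime",
                                             "variance"),
                              parameters = c("mua", "musp")) {
  stopifnot(inherits(medium, "medium"), medium$kind == "voxel_slab")
  data_types <- match.arg(data_types, several.ok = TRUE)
  parameters <- match.arg(parameters, several.ok = TRUE)
  nch <- nrow(channels)
  if (nch == 0) stop("no channels to assemble", call. = FALSE)
  nvox <- nrow(medium$grid$voxels)

  has_xy <- all(c("src_x", "src_y", "det_x", "det_y") %in% names(channels))
  blocks <- vector("list", nch)
  mm <- vector("list", nch)
  for (i in seq_len(nch)) {
    if (has_xy) {
      sp <- c(channels$src_x[i], channels$src_y[i], 0)
      dp <- c(channels$det_x[i], channels$det_y[i], 0)
    } else {
      # place the pair symmetrically about the channel midpoint along x
      half <- channels$sds_mm[i] / 2
      sp <- c(channels$mid_x_mm[i] - half, channels$mid_y_mm[i], 0)
      dp <- c(channels$mid_x_mm[i] + half, channels$mid_y_mm[i], 0)
    }
    ker <- voxel_sensitivity_tpsf(medium, sp, dp, tgrid,
                                  parameters = parameters)
    N0 <- sum(ker$tpsf)
    t <- time_centers(tgrid)
    m1 <- sum(t * ker$tpsf) / N0
    V <- sum((t - m1)^2 * ker$tpsf) / N0
    m4c <- sum((t - m1)^4 * ker$tpsf) / N0
    mm[[i]] <- c(N = N0, m1 = m1, V = V, m4c = m4c)
    per_par <- lapply(parameters, function(p) {
      Jt <- if (p == "mua") ker$J_mua else ker$J_musp
      dtv <- map_jacobian_to_datatypes(Jt, ker$tpsf, tgrid)
      dtv$intensity <- dtv$intensity / N0   # relative intensity rows
      dtv
    })
    names(per_par) <- parameters
    blocks[[i]] <- per_par
  }

  npar <- length(parameters)
  J <- matrix(0, nrow = length(data_types) * nch, ncol = nvox * npar)
  row_meta <- data.frame(row = seq_len(nrow(J)),
                         data_type = rep(data_types, each = nch),
                         channel = rep(seq_len(nch), length(data_types)))
  col_meta <- data.frame(col = seq_len(ncol(J)),
                         parameter = rep(parameters, each = nvox),
                         voxel = rep(seq_len(nvox), npar))
  for (di in seq_along(data_types)) {
    for (i in seq_len(nch)) {
      r <- (di - 1) * nch + i
      for (pi in seq_along(parameters)) {
        cols <- (pi - 1) * nvox + seq_len(nvox)
        J[r, cols] <- blocks[[i]][[parameters[pi]]][[data_types[di]]]
      }
    }
  }
  norm_factors <- setNames(numeric(length(data_types)), data_types)
  for (di in seq_along(data_types)) {
    rows <- which(row_meta$data_type == data_types[di])
    f <- max(abs(J[rows, ]))
    if (f == 0) f <- 1
    norm_factors[di] <- f
    J[rows, ] <- J[rows, ] / f
  }
  structure(list(J = J, row_meta = row_meta, col_meta = col_meta,
                 norm_factors = norm_factors, grid = medium$grid,
                 channels = channels,
                 model_moments = do.call(rbind, mm),
                 data_types = data_types, parameters = parameters,
                 tgrid = tgrid),
            class = "jacobian_stack")
}

#' @export
print.jacobian_stack <- function(x, ...) {
  cat(sprintf("<jacobian_stack> %d rows (%s x %d channels) x %d cols (%d voxels x {%s})\n",
              nrow(x$J), paste(x$data_types, collapse = "+"),
              nrow(x$channels) , ncol(x$J), nrow(x$grid$voxels),
              paste(x$parameters, collapse = ",")))
  invisible(x)
}

#' Restrict a Jacobian stack to a subset of data types
#'
#' Extracts the rows of the given data types and re-applies the [-1, 1]
#' normalization within the subset (factors are recomputed and recorded).
#'
#' @param jstack a `jacobian_stack`
#' @param data_types data types to keep (e.g. `"intensity"` for the
#'   CW-like comparison mode)
#' @export
subset_jacobian <- function(jstack, data_types) {
  stopifnot(inherits(jstack, "jacobian_stack"),
            all(data_types %in% jstack$data_types))
  rows <- which(jstack$row_meta$data_type %in% data_types)
  out <- jstack
  # undo old normalization, keep selected rows, renormalize
  J <- jstack$J[rows, , drop = FALSE] *
    jstack$norm_factors[jstack$row_meta$data_type[rows]]
  rm2 <- jstack$row_meta[rows, , drop = FALSE]
  nf <- setNames(numeric(length(data_types)), data_types)
  for (dt in data_types) {
    rr <- which(rm2$data_type == dt)
    f <- max(abs(J[rr, ])); if (f == 0) f <- 1
    nf[dt] <- f
    J[rr, ] <- J[rr, ] / f
  }
  rm2$row <- seq_len(nrow(rm2))
  out$J <- J; out$row_meta <- rm2; out$norm_factors <- nf
  out$data_types <- data_types
  out
}

#' Apply the stack's data normalization to measured features
#'
#' @param jstack a `jacobian_stack`
#' @param Y vector (rows) or matrix `[rows x time]` of feature data in
#'   absolute units, ordered like `jstack$row_meta`
#' @export
normalize_data <- function(jstack, Y) {
  f <- jstack$norm_factors[jstack$row_meta$data_type]
  if (is.null(dim(Y))) Y / f else sweep(Y, 1, f, "/")
}

#' Tikhonov-regularized Moore-Penrose inversion
#'
#' Solves `J X = Y` for underdetermined `J` via the wide form
#' `X = J' (J J' + lambda I)^{-1} Y`, using a Cholesky factorization (never
#' an explicit inverse). `lambda = "auto"` uses `0.1 * ||J J'||_F`.
#'
#' @param J matrix (or a `jacobian_stack`, whose normalized `J` is used)
#' @param Y right-hand side: vector of length `nrow(J)` or matrix
#'   `[nrow(J) x k]`
#' @param lambda regularization parameter (> 0) or `"auto"`
#' @return solution vector/matrix with attribute `lambda`
#' @export
tikhonov_invert <- function(J, Y, lambda = "auto") {
  if (inherits(J, "jacobian_stack")) J <- J$J
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == nrow(J))
  JJt <- tcrossprod(J)
  if (identical(lambda, "auto")) lambda <- 0.1 * norm(JJt, "F")
  if (!is.numeric(lambda) || lambda < 0)
    stop("lambda must be >= 0 or \"auto\"", call. = FALSE)
  A <- JJt + diag(lambda, nrow(JJt))
  ch <- tryCatch(chol(A), error = function(e)
    stop("J J' + lambda I is singular; increase lambda", call. = FALSE))
  X <- crossprod(J, backsolve(ch, forwardsolve(t(ch), Y)))
  attr(X, "lambda") <- lambda
  X
}

#' Differential reconstruction of a feature time series
#'
#' Features are expected at the (downsampled, e.g. 1 Hz) reconstruction
#' rate in absolute units (relative intensity, ps, ps^2), ordered like the
#' stack's rows. Each time sample is reconstructed against the previous
#' sample as baseline (small-change linearization); the increments are
#' cumulatively summed so the returned time courses are relative to the
#' first frame. Missing samples (NA) are skipped and logged.
#'
#' @param features matrix `[time x rows]`
#' @param jstack a `jacobian_stack`
#' @param lambda Tikhonov parameter or `"auto"` (evaluated once per call)
#' @param cumulative integrate sample-to-sample increments (default TRUE)
#' @return list of class `recon_timeseries`: per parameter a matrix
#'   `[voxels x time]` (`dmua`, and `dmusp` when present), `t_index`,
#'   `skipped`, `lambda`, `grid`
#' @export
reconstruct_timeseries <- function(features, jstack, lambda = "auto",
                                   cumulative = TRUE) {
  stopifnot(inherits(jstack, "jacobian_stack"))
  features <- as.matrix(features)
  if (ncol(features) != nrow(jstack$J))
    stop("feature columns must match Jacobian rows", call. = FALSE)
  nt <- nrow(features)
  dY <- t(features[-1, , drop = FALSE] - features[-nt, , drop = FALSE])
  ok <- which(colSums(is.na(dY)) == 0)
  skipped <- setdiff(seq_len(nt - 1), ok)
  if (length(skipped) > 0)
    message(length(skipped), " frame increment(s) skipped (missing data)")
  dYn <- normalize_data(jstack, dY[, ok, drop = FALSE])
  Xinc <- tikhonov_invert(jstack, dYn, lambda)
  lambda_used <- attr(Xinc, "lambda")

  nvox <- nrow(jstack$grid$voxels)
  out <- list()
  for (p in jstack$parameters) {
    rows <- which(jstack$col_meta$parameter == p)
    inc_full <- matrix(0, nvox, nt - 1)
    inc_full[, ok] <- Xinc[rows, , drop = FALSE]
    acc <- if (cumulative && ncol(inc_full) > 1)
      t(apply(inc_full, 1, cumsum))
    else inc_full
    ts <- cbind(0, acc)
    out[[paste0("d", p)]] <- ts
  }
  structure(c(out, list(t_index = seq_len(nt), skipped = skipped,
                        lambda = lambda_used, grid = jstack$grid)),
            class = "recon_timeseries")
}

#' Mean time course of a spherical region of interest
#'
#' Unweighted mean over voxels within `radius_mm` of the center.
#'
#' @param voxel_ts matrix `[voxels x time]` (e.g. `$dmua` of
#'   [reconstruct_timeseries()])
#' @param grid the [voxel_grid()] of the reconstruction
#' @param center_mm length-3 center position
#' @param radius_mm sphere radius (default 10 mm)
#' @export
roi_timecourse <- function(voxel_ts, grid, center_mm, radius_mm = 10) {
  stopifnot(inherits(grid, "voxel_grid"),
            nrow(voxel_ts) == nrow(grid$voxels))
  v <- grid$voxels
  d2 <- (v$x_mm - center_mm[1])^2 + (v$y_mm - center_mm[2])^2 +
    (v$z_mm - center_mm[3])^2
  sel <- which(d2 <= radius_mm^2)
  if (length(sel) == 0) stop("empty ROI sphere", call. = FALSE)
  colMeans(voxel_ts[sel, , drop = FALSE])
}

#' Simulate a feature time series from a voxel-space truth field
#'
#' Maps a time-varying absorption perturbation field through the
#' (unnormalized) Jacobian stack into feature space and adds
#' photon-counting noise appropriate for the per-histogram count level
#' (variance of total counts N; variance `V/N` for the mean; variance
#' `(m4c - V^2)/N` for the variance moment). Part of the synthetic-data
#' surface: reconstruction tests run on its output with recorded truth.
#'
#' @param jstack a `jacobian_stack`
#' @param dmua_voxels matrix `[voxels x time]` of true absorption changes
#'   (1/mm) relative to baseline
#' @param counts_per_histogram counts driving the noise level
#' @param seed RNG seed
#' @return list: `features` matrix `[time x rows]` in absolute units,
#'   `truth` (the input field and seed)
#' @export
simulate_feature_timeseries <- function(jstack, dmua_voxels,
                                        counts_per_histogram = 1e6,
                                        seed = 1) {
  stopifnot(inherits(jstack, "jacobian_stack"))
  nvox <- nrow(jstack$grid$voxels)
  stopifnot(nrow(dmua_voxels) == nvox)
  set.seed(seed)
  cols <- which(jstack$col_meta$parameter == "mua")
  Jmua <- sweep(jstack$J[, cols, drop = FALSE], 1,
                jstack$norm_factors[jstack$row_meta$data_type], "*")
  clean <- t(Jmua %*% dmua_voxels)      # time x rows
  nch <- nrow(jstack$channels)
  mmnt <- jstack$model_moments
  Nc <- counts_per_histogram
  sigma_row <- numeric(nrow(jstack$J))
  for (i in seq_len(nrow(jstack$row_meta))) {
    ch <- jstack$row_meta$channel[i]
    sigma_row[i] <- switch(jstack$row_meta$data_type[i],
      intensity = 1 / sqrt(Nc),
      meantime = sqrt(mmnt[ch, "V"] / Nc),
      variance = sqrt(max(mmnt[ch, "m4c"] - mmnt[ch, "V"]^2, 0) / Nc))
  }
  noise <- matrix(rnorm(length(clean)), nrow(clean), ncol(clean))
  noise <- sweep(noise, 2, sigma_row, "*")
  # absolute baselines: relative intensity 1, model m1 and V per channel
  base <- numeric(nrow(jstack$J))
  for (i in seq_len(nrow(jstack$row_meta))) {
    ch <- jstack$row_meta$channel[i]
    base[i] <- switch(jstack$row_meta$data_type[i],
                      intensity = 1,
                      meantime = mmnt[ch, "m1"],
                      variance = mmnt[ch, "V"])
  }
  features <- sweep(clean + noise, 2, base, "+")
  list(features = features,
       truth = list(dmua_voxels = dmua_voxels, seed = seed,
                    counts_per_histogram = counts_per_histogram))
}
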