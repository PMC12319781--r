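# Analytical time-resolved diffusion forward model and voxel-level Born
# sensitivity kernels for a semi-infinite turbid medium.
#
# Conventions:
#   * distances in mm, times in ps, mua / musp in 1/mm
#   * photon speed v = c / n with the medium's own refractive index
#   * diffusion coefficient D = 1/(3 musp), independent of mua
#   * extrapolated-boundary realization of the Robin boundary condition:
#     isotropic point source at depth z0 = 1/musp, zero-fluence plane at
#     z = -zb with zb = 2 A D, internal-reflection parameter A derived from
#     the refractive index (Groenhuis polynomial)
#   * time origin at source pulse emission.

#' Optical properties of a turbid medium at one wavelength
#'
#' @param mua_per_mm absorption coefficient (>= 0, 1/mm)
#' @param musp_per_mm reduced scattering coefficient (> 0, 1/mm)
#' @param n_refractive refractive index (>= 1)
#' @export
optical_properties <- function(mua_per_mm, musp_per_mm, n_refractive = 1.4) {
  .check_num(mua_per_mm, "mua_per_mm", lower = 0)
  .check_num(musp_per_mm, "musp_per_mm", lower = 1e-9)
  .check_num(n_refractive, "n_refractive", lower = 1)
  structure(list(mua = mua_per_mm, musp = musp_per_mm, n = n_refractive),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("<optical_properties> mua = %.4g /mm, musp = %.4g /mm, n = %.3g\n",
              x$mua, x$musp, x$n))
  invisible(x)
}

#' Uniform time grid for time-resolved curves
#'
#' Bin centers are at `origin_ps + (i - 1/2) * bin_width_ps`.
#'
#' @param bin_width_ps bin width (> 0)
#' @param n_bins number of bins
#' @param origin_ps left edge of the first bin
#' @export
time_grid <- function(bin_width_ps = 10, n_bins = 500, origin_ps = 0) {
  .check_num(bin_width_ps, "bin_width_ps", lower = 1e-12)
  stopifnot(n_bins >= 1)
  structure(list(bin_width_ps = bin_width_ps, n_bins = as.integer(n_bins),
                 origin_ps = origin_ps),
            class = "time_grid")
}

#' Bin centers of a time grid (ps)
#' @param tgrid a [time_grid()]
#' @export
time_centers <- function(tgrid) {
  tgrid$origin_ps + (seq_len(tgrid$n_bins) - 0.5) * tgrid$bin_width_ps
}

#' Internal-reflection parameter A(n) of the extrapolated boundary
#'
#' Groenhuis approximation of the effective internal reflection coefficient
#' for a tissue-air interface; `A = (1 + r_d) / (1 - r_d)`.
#'
#' @param n_refractive refractive index of the medium (outside medium: air)
#' @export
boundary_reflection_A <- function(n_refractive) {
  n <- n_refractive
  rd <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 + rd) / (1 - rd)
}

.diffusion_D <- function(props) 1 / (3 * props$musp)

#' Time-resolved reflectance of a semi-infinite medium
#'
#' Extrapolated-boundary solution of the diffusion equation for an
#' instantaneous pencil source: the detected photon flux per unit area and
#' time at source-detector separation `sds_mm` on the surface,
#' \deqn{R(\rho,t) = \frac{\exp(-\mu_a v t - \rho^2/(4 D v t))}
#'   {2 (4\pi D v)^{3/2} t^{5/2}}
#'   \left[z_0 e^{-z_0^2/(4Dvt)} + (z_0+2z_b) e^{-(z_0+2z_b)^2/(4Dvt)}\right].}
#'
#' Obeys the absorption scaling \eqn{R(t;\mu_a+\delta)=R(t;\mu_a)e^{-\delta v t}}.
#'
#' @param props [optical_properties()]
#' @param sds_mm source-detector separation in mm
#' @param tgrid [time_grid()] covering the decay
#' @return numeric vector of reflectance density (1/mm^2/ps) at bin centers,
#'   with attribute `diffusion_valid` set to `FALSE` (and a warning raised)
#'   when `sds_mm` is below ~3 transport mean free paths.
#' @export
tpsf_semi_infinite <- function(props, sds_mm, tgrid) {
  stopifnot(inherits(props, "optical_properties"), inherits(tgrid, "time_grid"))
  .check_num(sds_mm, "sds_mm", lower = 0)
  v <- tissue_speed(props$n)
  D <- .diffusion_D(props)
  z0 <- 1 / props$musp
  zb <- 2 * boundary_reflection_A(props$n) * D
  t <- time_centers(tgrid)
  pos <- t > 0
  R <- numeric(length(t))
  tt <- t[pos]
  fourDvt <- 4 * D * v * tt
  R[pos] <- exp(-props$mua * v * tt - sds_mm^2 / fourDvt) /
    (2 * (4 * pi * D * v)^1.5 * tt^2.5) *
    (z0 * exp(-z0^2 / fourDvt) +
       (z0 + 2 * zb) * exp(-(z0 + 2 * zb)^2 / fourDvt))
  valid <- sds_mm > 3 / props$musp
  if (!valid)
    warning("source-detector separation below diffusion validity (~3/musp)")
  attr(R, "diffusion_valid") <- valid
  R
}

#' Continuous-wave reflectance of a semi-infinite medium (closed form)
#'
#' Steady-state counterpart (time integral) of [tpsf_semi_infinite()];
#' used as an independent cross-check of the time-resolved curve.
#'
#' @inheritParams tpsf_semi_infinite
#' @return reflectance (1/mm^2)
#' @export
cw_reflectance_semi_infinite <- function(props, sds_mm) {
  D <- .diffusion_D(props)
  z0 <- 1 / props$musp
  zb <- 2 * boundary_reflection_A(props$n) * D
  mueff <- sqrt(props$mua / D)
  r1 <- sqrt(z0^2 + sds_mm^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + sds_mm^2)
  (1 / (4 * pi)) * (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
    (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2)
}

# ---------------------------------------------------------------------------
# Media

#' Semi-infinite homogeneous medium
#' @param props [optical_properties()]
#' @export
medium_semi_infinite <- function(props) {
  stopifnot(inherits(props, "optical_properties"))
  structure(list(kind = "semi_infinite", props = props),
            class = "medium")
}

#' Two-layer medium (superficial layer over a deep half-space)
#'
#' @param props_superficial,props_deep [optical_properties()] per layer
#' @param layer_thickness_mm superficial layer thickness (default 12 mm)
#' @export
medium_two_layer <- function(props_superficial, props_deep,
                             layer_thickness_mm = 12) {
  stopifnot(inherits(props_superficial, "optical_properties"),
            inherits(props_deep, "optical_properties"))
  .check_num(layer_thickness_mm, "layer_thickness_mm", lower = 1e-9)
  structure(list(kind = "two_layer",
                 props_superficial = props_superficial,
                 props_deep = props_deep,
                 layer_thickness_mm = layer_thickness_mm),
            class = "medium")
}

#' Uniform voxel grid (reconstruction basis)
#'
#' Axis-aligned grid of cubic voxels; `z >= 0` points into the medium and the
#' optode plane is `z = 0`.
#'
#' @param spacing_mm voxel edge length (default 4 mm)
#' @param xlim,ylim,zlim extents in mm (voxels tile the box)
#' @return `voxel_grid` object with a `voxels` data frame of centers.
#' @export
voxel_grid <- function(spacing_mm = 4, xlim = c(-32, 32), ylim = c(-32, 32),
                       zlim = c(0, 32)) {
  .check_num(spacing_mm, "spacing_mm", lower = 1e-9)
  ax <- function(lim) {
    n <- max(1L, round(diff(lim) / spacing_mm))
    lim[1] + (seq_len(n) - 0.5) * spacing_mm
  }
  xs <- ax(xlim); ys <- ax(ylim); zs <- ax(zlim)
  vox <- expand.grid(x_mm = xs, y_mm = ys, z_mm = zs,
                     KEEP.OUT.ATTRS = FALSE)
  structure(list(spacing_mm = spacing_mm, xlim = xlim, ylim = ylim,
                 zlim = zlim, nx = length(xs), ny = length(ys),
                 nz = length(zs), voxels = vox),
            class = "voxel_grid")
}

#' Voxelized slab medium over a reference background
#'
#' Baseline optical properties are defined per voxel (optionally layered);
#' Born sensitivity kernels are computed against the homogeneous
#' `reference_props` background.
#'
#' @param grid [voxel_grid()]
#' @param reference_props [optical_properties()] of the homogeneous background
#' @param superficial_props optional [optical_properties()] for voxels with
#'   `z < layer_thickness_mm` (two-layer baseline)
#' @param layer_thickness_mm superficial layer thickness (default 12 mm)
#' @export
medium_voxel_slab <- function(grid, reference_props,
                              superficial_props = NULL,
                              layer_thickness_mm = 12) {
  stopifnot(inherits(grid, "voxel_grid"),
            inherits(reference_props, "optical_properties"))
  nvox <- nrow(grid$voxels)
  mua <- rep(reference_props$mua, nvox)
  musp <- rep(reference_props$musp, nvox)
  if (!is.null(superficial_props)) {
    sup <- grid$voxels$z_mm < layer_thickness_mm
    mua[sup] <- superficial_props$mua
    musp[sup] <- superficial_props$musp
  }
  structure(list(kind = "voxel_slab", grid = grid,
                 reference_props = reference_props,
                 layer_thickness_mm = layer_thickness_mm,
                 mua = mua, musp = musp),
            class = "medium")
}

# ---------------------------------------------------------------------------
# Green's functions and Born kernels

# Semi-infinite fluence Green's function (source at depth z0, extrapolated
# boundary at z = -zb) evaluated at many field points x many times.
# Returns matrix [n_points x n_times]; pts is n x 3, src is length-3 with the
# physical source already placed at its depth.
.green_semi_matrix <- function(pts, src, D, v, mua, zb, t) {
  img <- c(src[1], src[2], -src[3] - 2 * zb)
  d1sq <- (pts[, 1] - src[1])^2 + (pts[, 2] - src[2])^2 + (pts[, 3] - src[3])^2
  d2sq <- (pts[, 1] - img[1])^2 + (pts[, 2] - img[2])^2 + (pts[, 3] - img[3])^2
  fourDvt <- 4 * D * v * t
  amp <- v * (pi * fourDvt)^(-1.5) * exp(-mua * v * t)   # length n_times
  G <- exp(-outer(d1sq, 1 / fourDvt)) - exp(-outer(d2sq, 1 / fourDvt))
  sweep(G, 2, amp, "*")
}

# Cartesian gradient components of the same Green's function:
# list of three [n_points x n_times] matrices.
.green_semi_grad <- function(pts, src, D, v, mua, zb, t) {
  img <- c(src[1], src[2], -src[3] - 2 * zb)
  d1sq <- (pts[, 1] - src[1])^2 + (pts[, 2] - src[2])^2 + (pts[, 3] - src[3])^2
  d2sq <- (pts[, 1] - img[1])^2 + (pts[, 2] - img[2])^2 + (pts[, 3] - img[3])^2
  fourDvt <- 4 * D * v * t
  amp <- v * (pi * fourDvt)^(-1.5) * exp(-mua * v * t)
  E1 <- sweep(exp(-outer(d1sq, 1 / fourDvt)), 2, amp, "*")
  E2 <- sweep(exp(-outer(d2sq, 1 / fourDvt)), 2, amp, "*")
  lapply(1:3, function(a) {
    # d/dr_a exp(-|r-r'|^2 / 4Dvt) -> -(2 (r_a - r'_a) / 4Dvt) * (...)
    t1 <- sweep(E1 * (-(pts[, a] - src[a])), 2, 2 / fourDvt, "*")
    t2 <- sweep(E2 * (-(pts[, a] - img[a])), 2, 2 / fourDvt, "*")
    t1 - t2
  })
}

# row-wise linear convolution of two [n x m] matrices via FFT, scaled by dt;
# returns the first m columns (same support as the inputs).
.rowconv <- function(A, B, dt) {
  m <- ncol(A)
  nfft <- nextn(2L * m, 2)
  pad <- function(M) cbind(M, matrix(0, nrow(M), nfft - m))
  fa <- mvfft(t(pad(A)))
  fb <- mvfft(t(pad(B)))
  out <- Re(mvfft(fa * fb, inverse = TRUE)) / nfft
  t(out)[, seq_len(m), drop = FALSE] * dt
}

#' Time-resolved voxel sensitivity kernels (Born approximation)
#'
#' Builds, for one source-detector channel over a voxelized slab, the
#' first-order (Born) sensitivity of the measured time-resolved reflectance
#' to a change of absorption (and optionally reduced scattering) in every
#' voxel: the time convolution of the source-to-voxel and voxel-to-detector
#' Green's functions of the homogeneous reference medium (adjoint
#' construction; by reciprocity the kernel is symmetric under exchange of
#' source and detector).
#'
#' The measurement convention is fluence-based: the reference curve returned
#' in `$tpsf` is \eqn{G(r_s\to r_d,t)/(2A)} with both optodes represented as
#' isotropic points at depth \eqn{z_0 = 1/\mu_s'}. Absorption kernels are
#' non-positive in intensity terms; the sum over all voxels approaches the
#' bulk-absorption derivative \eqn{-v\,t\,R(t)} of the reference curve.
#'
#' @param medium a `voxel_slab` medium from [medium_voxel_slab()]
#' @param source_pos,det_pos length-3 optode positions on the surface
#'   (`z = 0`; the z component is ignored and replaced by the source depth)
#' @param tgrid [time_grid()]
#' @param parameters which kernels to compute: subset of `c("mua","musp")`
#' @return list with `J_mua` (and optionally `J_musp`): matrices
#'   `[n_voxels x n_bins]` of dR/d(parameter) per voxel, `tpsf` the reference
#'   measurement curve, `tgrid`, and `voxels`.
#' @export
voxel_sensitivity_tpsf <- function(medium, source_pos, det_pos, tgrid,
                                   parameters = c("mua", "musp")) {
  stopifnot(inherits(medium, "medium"), medium$kind == "voxel_slab",
            inherits(tgrid, "time_grid"))
  parameters <- match.arg(parameters, several.ok = TRUE)
  props <- medium$reference_props
  v <- tissue_speed(props$n)
  D <- .diffusion_D(props)
  z0 <- 1 / props$musp
  zb <- 2 * boundary_reflection_A(props$n) * D
  A2 <- 2 * boundary_reflection_A(props$n)
  t <- time_centers(tgrid)
  if (any(t <= 0)) stop("time grid must be strictly positive", call. = FALSE)
  dt <- tgrid$bin_width_ps

  grid <- medium$grid
  pts <- as.matrix(grid$voxels)
  # sensitive region coverage check: banana between the optodes
  mid <- (source_pos[1:2] + det_pos[1:2]) / 2
  if (min(pts[, 3]) > z0 + grid$spacing_mm ||
      mid[1] < grid$xlim[1] || mid[1] > grid$xlim[2] ||
      mid[2] < grid$ylim[1] || mid[2] > grid$ylim[2])
    stop("voxel grid does not cover the sensitive volume of this channel",
         call. = FALSE)

  src <- c(source_pos[1], source_pos[2], z0)
  det <- c(det_pos[1], det_pos[2], z0)
  vol <- grid$spacing_mm^3

  Gs <- .green_semi_matrix(pts, src, D, v, props$mua, zb, t)
  Gd <- .green_semi_matrix(pts, det, D, v, props$mua, zb, t)
  out <- list(tgrid = tgrid, voxels = grid$voxels)
  if ("mua" %in% parameters)
    # the Green's-function product is nonnegative; clamp FFT ringing
    out$J_mua <- -vol / A2 * pmax(.rowconv(Gs, Gd, dt), 0)
  if ("musp" %in% parameters) {
    gs <- .green_semi_grad(pts, src, D, v, props$mua, zb, t)
    gd <- .green_semi_grad(pts, det, D, v, props$mua, zb, t)
    acc <- .rowconv(gs[[1]], gd[[1]], dt) +
      .rowconv(gs[[2]], gd[[2]], dt) +
      .rowconv(gs[[3]], gd[[3]], dt)
    # dD/dmusp = -3 D^2 ; dR/dD = -grad term  =>  dR/dmusp = +3 D^2 * grad
    out$J_musp <- 3 * D^2 * vol / A2 * acc
  }
  # reference measurement curve, same convention
  dsd <- sqrt(sum((src - det)^2))
  fourDvt <- 4 * D * v * t
  dim_sq <- sum((src - c(det[1], det[2], -det[3] - 2 * zb))^2)
  out$tpsf <- (v * (pi * fourDvt)^(-1.5) * exp(-props$mua * v * t) *
                 (exp(-dsd^2 / fourDvt) - exp(-dim_sq / fourDvt))) / A2
  out
}

#' Map a time-resolved Jacobian to moment data types
#'
#' Propagates a time-resolved sensitivity kernel J(t) through the moment
#' featurization of the curve it perturbs: for total counts N, mean
#' time-of-flight m1 and variance V of the reference curve,
#' \deqn{J_N = \sum_t J(t),\quad
#'       J_{m_1} = (\sum_t t J(t) - m_1 J_N)/N,\quad
#'       J_V = (\sum_t (t-m_1)^2 J(t) - V J_N)/N.}
#'
#' @param jac time-resolved kernel: vector of length `n_bins` or matrix
#'   `[n_voxels x n_bins]`
#' @param tpsf reference curve on the same grid
#' @param tgrid [time_grid()]
#' @return list with vectors `intensity`, `meantime`, `variance` (one entry
#'   per row of `jac`).
#' @export
map_jacobian_to_datatypes <- function(jac, tpsf, tgrid) {
  stopifnot(inherits(tgrid, "time_grid"))
  if (is.null(dim(jac))) jac <- matrix(jac, nrow = 1)
  if (ncol(jac) != tgrid$n_bins || length(tpsf) != tgrid$n_bins)
    stop("jacobian and tpsf must share the time grid", call. = FALSE)
  t <- time_centers(tgrid)
  N <- sum(tpsf)
  if (N <= 0) stop("zero total counts: moment Jacobians undefined", call. = FALSE)
  m1 <- sum(t * tpsf) / N
  V <- sum((t - m1)^2 * tpsf) / N
  JN <- rowSums(jac)
  Jt <- as.numeric(jac %*% t)
  Jt2 <- as.numeric(jac %*% (t - m1)^2)
  list(intensity = JN,
       meantime = (Jt - m1 * JN) / N,
       variance = (Jt2 - V * JN) / N)
}
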