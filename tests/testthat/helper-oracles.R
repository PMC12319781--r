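# Independent numerical oracles used across tests.

# 1-D finite-difference diffusion solver for a laterally homogeneous medium
# with depth-dependent absorption mua(z) and constant musp. Solves
#   dphi/dt = D v phi_zz - mua(z) v phi
# with a zero-fluence (extrapolated) boundary below z = 0 and an
# instantaneous plane source at the reduced-scattering depth z0 = 1/musp.
# Returns phi and its z-gradient at requested times, sampled at z = 0 and
# z = z0, on a grid aligned so that both depths are mesh points.
fd_diffusion_1d <- function(mua_fun, musp, n_ref, t_out, zmax = 80,
                            dz = 0.25, dt = 0.4) {
  v <- tissue_speed(n_ref)
  D <- 1 / (3 * musp)
  Dv <- D * v
  stopifnot(Dv * dt / dz^2 < 0.5)      # explicit-scheme stability
  zb <- 2 * boundary_reflection_A(n_ref) * D
  nb <- ceiling(zb / dz)
  z <- dz * seq(-nb, round(zmax / dz))
  nz <- length(z)
  z0 <- 1 / musp
  mua <- mua_fun(pmax(z, 0))
  phi <- numeric(nz)
  isrc <- which.min(abs(z - z0))
  phi[isrc] <- 1 / dz
  i0 <- which.min(abs(z))
  t_idx <- pmax(1L, round(t_out / dt))
  nsteps <- max(t_idx)
  phi0 <- grad0 <- phi_src <- numeric(length(t_out))
  for (it in seq_len(nsteps)) {
    lap <- c(0, (phi[1:(nz - 2)] - 2 * phi[2:(nz - 1)] + phi[3:nz]) / dz^2, 0)
    phi <- phi + dt * (Dv * lap - mua * v * phi)
    phi[1] <- 0
    phi[nz] <- 0
    hit <- which(t_idx == it)
    if (length(hit) > 0) {
      phi0[hit] <- phi[i0]
      grad0[hit] <- (phi[i0 + 1] - phi[i0 - 1]) / (2 * dz)
      phi_src[hit] <- phi[isrc]
    }
  }
  list(phi0 = phi0, grad0 = grad0, phi_src = phi_src,
       D = D, v = v, z0 = z0, zb = zb)
}

# Surface flux reflectance from the 1-D solution (independent realization of
# the semi-infinite time-resolved reflectance): R = D v G2(rho, t) dphi/dz|0
fd_reflectance <- function(mua, musp, n_ref, sds_mm, tgrid, ...) {
  t <- time_centers(tgrid)
  sol <- fd_diffusion_1d(function(z) rep(mua, length(z)), musp, n_ref, t, ...)
  G2 <- exp(-sds_mm^2 / (4 * sol$D * sol$v * t)) / (4 * pi * sol$D * sol$v * t)
  sol$D * sol$v * G2 * sol$grad0
}

# Moment features (relative intensity baseline, mean, variance) of the
# fluence measured at the source/detector depth for a layered mua(z):
# matches the measurement convention of the Born kernels.
fd_layered_features <- function(mua_fun, musp, n_ref, sds_mm, tgrid, ...) {
  t <- time_centers(tgrid)
  sol <- fd_diffusion_1d(mua_fun, musp, n_ref, t, ...)
  G2 <- exp(-sds_mm^2 / (4 * sol$D * sol$v * t)) / (4 * pi * sol$D * sol$v * t)
  M <- sol$v * G2 * sol$phi_src
  N <- sum(M)
  m1 <- sum(t * M) / N
  V <- sum((t - m1)^2 * M) / N
  c(N = N, m1 = m1, V = V)
}

# brute-force moments of a histogram at bin centers
brute_moments <- function(counts, t) {
  N <- sum(counts)
  m1 <- sum(t * counts) / N
  V <- sum((t - m1)^2 * counts) / N
  list(N = N, m1 = m1, V = V)
}
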