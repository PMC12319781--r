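# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

# single-module, single-wavelength Jacobian stack on a 16 x 16 x 8 slab
fixture_jstack <- function() {
  if (is.null(.fixtures$jstack)) {
    grid <- voxel_grid(4, xlim = c(-32, 32), ylim = c(-32, 32),
                       zlim = c(0, 32))
    med <- medium_voxel_slab(grid, optical_properties(0.0125, 0.95, 1.4))
    ch <- enumerate_channels(optical_module(), max_sds_mm = 30)
    ch <- ch[ch$wavelength_nm == 905, ]
    .fixtures$jstack <- assemble_jacobian(ch, med, time_grid(20, 256))
  }
  .fixtures$jstack
}

fixture_irf <- function(wavelength_nm = 905, tgrid = time_grid(25, 400)) {
  key <- paste0("irf", wavelength_nm, tgrid$bin_width_ps, tgrid$n_bins)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- irf_curve(irf_model(), wavelength_nm, tgrid)
  .fixtures[[key]]
}
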