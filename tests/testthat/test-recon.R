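# Jacobian assembly, Tikhonov inversion, differential reconstruction, ROI
# extraction.

test_that("assembled stacks are normalized per data type with recorded factors", {
  js <- fixture_jstack()
  for (dt in js$data_types) {
    rows <- which(js$row_meta$data_type == dt)
    expect_equal(max(abs(js$J[rows, ])), 1)
  }
  expect_true(all(js$norm_factors > 0))
  expect_equal(nrow(js$J), 3 * nrow(js$channels))
  expect_equal(ncol(js$J), 2 * nrow(js$grid$voxels))

  # intensity-only subset: one row per channel, renormalized
  ji <- subset_jacobian(js, "intensity")
  expect_equal(nrow(ji$J), nrow(js$channels))
  expect_equal(max(abs(ji$J)), 1)
})

test_that("the stack predicts layered perturbations measured by the FD forward", {
  # fine basis (3 mm voxels, 10 ps bins) so quadrature bias stays small
  grid <- voxel_grid(3, xlim = c(-27, 27), ylim = c(-27, 27), zlim = c(0, 33))
  med <- medium_voxel_slab(grid, optical_properties(0.0125, 0.95, 1.4))
  ch <- data.frame(src_x = c(-4.25, -13.25), src_y = 0,
                   det_x = c(4.25, 13.25), det_y = 0,
                   sds_mm = c(8.5, 26.5))
  tg <- time_grid(10, 512)
  js <- assemble_jacobian(ch, med, tg, parameters = "mua")
  v <- grid$voxels
  delta <- 2e-4
  Jabs <- sweep(js$J, 1, js$norm_factors[js$row_meta$data_type], "*")
  # FD perturbations restricted to the reconstruction basis (z <= 33 mm)
  zmax <- max(v$z_mm) + grid$spacing_mm / 2
  fields <- list(
    deep = list(vox = ifelse(v$z_mm >= 12, delta, 0),
                fun = function(z) 0.0125 +
                  delta * (z >= 12 & z <= zmax)),
    superficial = list(vox = ifelse(v$z_mm < 12, delta, 0),
                       fun = function(z) 0.0125 + delta * (z < 12)))
  for (fl in fields) {
    pred <- as.numeric(Jabs %*% fl$vox)
    for (ci in c(1L, 2L)) {                     # the short and long channel
      sds <- js$channels$sds_mm[ci]
      f0 <- fd_layered_features(function(z) rep(0.0125, length(z)), 0.95,
                                1.4, sds, tg)
      f1 <- fd_layered_features(fl$fun, 0.95, 1.4, sds, tg)
      truth <- c((f1["N"] - f0["N"]) / f0["N"], f1["m1"] - f0["m1"],
                 f1["V"] - f0["V"])
      rows <- vapply(c("intensity", "meantime", "variance"), function(dt)
        which(js$row_meta$data_type == dt & js$row_meta$channel == ci),
        integer(1))
      expect_lt(max(abs(pred[rows] / truth - 1)), 0.10)
    }
  }
})

test_that("Tikhonov inversion satisfies the algebraic identities", {
  set.seed(6)
  J <- matrix(rnorm(30 * 150), 30, 150)
  Y <- rnorm(30)
  lam <- 0.7
  X_wide <- tikhonov_invert(J, Y, lam)
  X_narrow <- solve(crossprod(J) + diag(lam, 150), crossprod(J, Y))
  expect_lt(max(abs(X_wide - X_narrow)) / max(abs(X_narrow)), 1e-8)
  # identity system, lambda -> 0
  Xi <- tikhonov_invert(diag(4), c(4, 3, 2, 1), 1e-12)
  expect_equal(as.numeric(Xi), c(4, 3, 2, 1), tolerance = 1e-9)
  # linearity: doubling Y doubles X
  X2 <- tikhonov_invert(J, 2 * Y, lam)
  expect_equal(as.numeric(X2), 2 * as.numeric(X_wide), tolerance = 1e-12)
  expect_error(tikhonov_invert(J, Y, -1), "lambda")
  # auto lambda rule
  Xa <- tikhonov_invert(J, Y)
  expect_equal(attr(Xa, "lambda"), 0.1 * norm(tcrossprod(J), "F"))
})

test_that("a deep single-voxel inclusion is localized within two voxels", {
  js <- fixture_jstack()
  v <- js$grid$voxels
  tvox <- which.min((v$x_mm - 6)^2 + (v$y_mm - 2)^2 + (v$z_mm - 14)^2)
  dm <- matrix(0, nrow(v), 2)
  dm[tvox, 2] <- 0.001
  cols <- which(js$col_meta$parameter == "mua")
  Jabs <- sweep(js$J[, cols], 1, js$norm_factors[js$row_meta$data_type], "*")
  feat <- t(Jabs %*% dm)
  rec <- reconstruct_timeseries(feat, js)
  pk <- which.max(abs(rec$dmua[, 2]))
  dist <- sqrt(sum((unlist(v[pk, ]) - unlist(v[tvox, ]))^2))
  expect_lte(dist, 8)
})

test_that("adding moment rows does not worsen localization (10 seeds)", {
  js <- fixture_jstack()
  v <- js$grid$voxels
  ji <- subset_jacobian(js, "intensity")
  rows_int <- which(js$row_meta$data_type == "intensity")
  tpos <- c(6, 2, 14)
  sel <- which((v$x_mm - tpos[1])^2 + (v$y_mm - tpos[2])^2 +
                 (v$z_mm - tpos[3])^2 <= 6.1^2)
  locerr <- function(r) {
    avg <- rowMeans(r$dmua[, 10:30])
    pk <- which.max(abs(avg))
    sqrt(sum((unlist(v[pk, ]) - tpos)^2))
  }
  errs <- vapply(1:10, function(s) {
    dm <- matrix(0, nrow(v), 30)
    dm[sel, 6:30] <- 0.002
    sim <- simulate_feature_timeseries(js, dm, 1e6, seed = 300 + s)
    c(all = locerr(reconstruct_timeseries(sim$features, js)),
      int = locerr(reconstruct_timeseries(
        sim$features[, rows_int, drop = FALSE], ji)))
  }, numeric(2))
  expect_true(all(errs["all", ] <= errs["int", ] + 1e-9))
})

test_that("differential reconstruction integrates and reverses cleanly", {
  js <- fixture_jstack()
  v <- js$grid$voxels
  sel <- which((v$x_mm - 6)^2 + (v$y_mm - 2)^2 + (v$z_mm - 14)^2 <= 6.1^2)
  # constant features -> all-zero frames
  cols <- which(js$col_meta$parameter == "mua")
  Jabs <- sweep(js$J[, cols], 1, js$norm_factors[js$row_meta$data_type], "*")
  feat0 <- matrix(rep(Jabs %*% rep(0, nrow(v)), 5), nrow = 5, byrow = TRUE)
  rec0 <- reconstruct_timeseries(feat0 + 1, js)    # constant offset features
  expect_equal(max(abs(rec0$dmua)), 0)
  # on-off step returns to baseline (noiseless, linear)
  dm <- matrix(0, nrow(v), 30)
  dm[sel, 10:20] <- 0.002
  feat <- t(Jabs %*% dm)
  rec <- reconstruct_timeseries(feat, js)
  expect_gt(max(abs(rec$dmua[, 15])), 0)
  expect_equal(max(abs(rec$dmua[, 30])), 0, tolerance = 1e-12)
  # missing samples are skipped and logged
  featNA <- feat; featNA[4, ] <- NA
  expect_message(recNA <- reconstruct_timeseries(featNA, js), "skipped")
  expect_equal(recNA$skipped, c(3, 4))
})

test_that("block-design sessions reconstruct the seeded time course", {
  js <- fixture_jstack()
  v <- js$grid$voxels
  tpos <- c(6, 2, 14)
  sel <- which((v$x_mm - tpos[1])^2 + (v$y_mm - tpos[2])^2 +
                 (v$z_mm - tpos[3])^2 <= 6.1^2)
  nt <- 120
  wave <- 0.002 * (sin(2 * pi * seq_len(nt) / 40) > 0)
  dm <- matrix(0, nrow(v), nt)
  dm[sel, ] <- matrix(wave, length(sel), nt, byrow = TRUE)
  sim <- simulate_feature_timeseries(js, dm, 1e6, seed = 77)
  rec <- reconstruct_timeseries(sim$features, js)
  roi <- roi_timecourse(rec$dmua, js$grid, tpos, 10)
  expect_gt(cor(roi, wave), 0.8)
})

test_that("ROI extraction averages exactly over the sphere", {
  js <- fixture_jstack()
  v <- js$grid$voxels
  M <- matrix(seq_len(nrow(v)), nrow(v), 2)
  # radius below the spacing: single-voxel trace
  center <- unlist(v[500, ])
  expect_equal(roi_timecourse(M, js$grid, center, 2), unname(M[500, ]))
  # uniform field: ROI mean equals the field value
  U <- matrix(3.5, nrow(v), 4)
  expect_equal(roi_timecourse(U, js$grid, center, 10), rep(3.5, 4))
  # hand-built sphere: direct arithmetic
  d2 <- (v$x_mm - center[1])^2 + (v$y_mm - center[2])^2 +
    (v$z_mm - center[3])^2
  sel <- which(d2 <= 5^2)
  expect_equal(roi_timecourse(M, js$grid, center, 5),
               unname(colMeans(M[sel, , drop = FALSE])))
  expect_error(roi_timecourse(M, js$grid, c(500, 500, 500), 5), "empty")
})
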