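# textured blob pair for controlled registration cases: the texture is
# attached to material coordinates, as in real parenchyma
textured_blob <- function(shift = 0, dims = c(48, 48, 48)) {
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  xm <- g$x - shift
  r2 <- ((xm - 24) / 12)^2 + ((g$y - 24) / 14)^2 + ((g$z - 24) / 16)^2
  tex <- 1 + 0.3 * (sin(2 * pi * xm / 11) * sin(2 * pi * g$y / 13) *
                      sin(2 * pi * g$z / 15) +
                    sin(2 * pi * xm / 17) * sin(2 * pi * g$y / 19) *
                      sin(2 * pi * g$z / 23)) / 2
  array(ifelse(r2 <= 1, -600 * tex, 0), dims)
}

blob_mask <- function(vol) {
  manual_mask(array(as.integer(vol < -300), dim(vol)))
}

test_that("registering an image to itself returns a near-zero field", {
  v <- ct_volume(textured_blob(), spacing = c(1, 1, 1), pressure = 0)
  mask <- blob_mask(v$data)
  reg <- register(v, v, mask, iterations = c(20, 15, 10))
  mag <- sqrt(reg$u[, , , 1]^2 + reg$u[, , , 2]^2 + reg$u[, , , 3]^2)
  expect_lt(mean(mag[mask$label > 0]), 0.05)
})

test_that("a known uniform translation is recovered", {
  f <- ct_volume(textured_blob(0), spacing = c(1, 1, 1), pressure = 0)
  m <- ct_volume(textured_blob(2), spacing = c(1, 1, 1), pressure = 5)
  mask <- blob_mask(f$data)
  reg <- register(f, m, mask)
  inl <- mask$label > 0
  err <- sqrt((reg$u[, , , 1] - 2)^2 + reg$u[, , , 2]^2 + reg$u[, , , 3]^2)
  expect_lt(mean(err[inl]), 0.2)
  expect_error(register(f, ct_volume(array(0, c(8, 8, 8)))), "share one grid")
})

test_that("specific volume maps Jacobians exactly on analytic fields", {
  dims <- c(24, 24, 24)
  mask <- manual_mask(array(1L, dims))
  zero <- disp_field(array(0, c(dims, 3)), spacing = c(1, 1, 1))
  sv0 <- specific_volume(zero, mask)
  expect_true(all(abs(sv0$svol) < 1e-12))
  # uniform isotropic scaling x1.1 about the center: J = 1.1^3
  g <- expand.grid(x = 1:24, y = 1:24, z = 1:24)
  u <- array(0, c(dims, 3))
  for (d in 1:3) u[, , , d] <- array(0.1 * (g[[d]] - 12.5), dims)
  sc <- disp_field(u, spacing = c(1, 1, 1))
  sv <- specific_volume(sc, mask)
  interior <- array(FALSE, dims)
  interior[2:23, 2:23, 2:23] <- TRUE
  expect_equal(unname(sv$svol[interior]),
               rep(1.1^3 - 1, sum(interior)), tolerance = 1e-9)
  # conservation on the analytic case: sVol integral vs exact volume change
  vol_low <- prod(dims) / 1000
  vol_high <- vol_low * 1.1^3
  rep_ <- validate_conservation(sv, vol_low, vol_high)
  expect_lt(abs(rep_$rel_discrepancy), 0.01)
  # identity case: both sides ~0
  rep0 <- validate_conservation(sv0, vol_low, vol_low)
  expect_true(rep0$pass)
  expect_equal(rep0$delta_svol_ml, 0, tolerance = 1e-9)
})

test_that("anisotropic voxel spacing is honoured by the Jacobian", {
  dims <- c(20, 20, 20)
  mask <- manual_mask(array(1L, dims), spacing = c(1, 1, 2))
  # displacement growing only along z, in mm: u_z = 0.2 * z_mm
  u <- array(0, c(dims, 3))
  zmm <- array(rep((1:20 - 0.5) * 2, each = 400), dims)
  u[, , , 3] <- 0.2 * (zmm - 20)
  fld <- disp_field(u, spacing = c(1, 1, 2))
  sv <- specific_volume(fld, mask)
  interior <- array(FALSE, dims)
  interior[, , 2:19] <- TRUE
  expect_equal(mean(sv$svol[interior]), 0.2, tolerance = 1e-9)
})

test_that("regional analysis summarises uniform and graded sVol fields", {
  dims <- c(20, 30, 20)
  lab <- array(0L, dims)
  lab[3:8, 4:27, 3:18] <- 2L    # right lung
  lab[12:17, 4:27, 3:18] <- 1L  # left lung
  mask <- manual_mask(lab)
  # uniform expansion: all bins equal, ratios 1
  sv_arr <- array(0.25, dims)
  sv_arr[lab == 0L] <- NA
  sv <- structure(list(svol = sv_arr, jacobian = sv_arr + 1, mask = mask,
                       fixed_pressure = 0, moving_pressure = 5,
                       n_nonpositive = 0L), class = "svol_map")
  r <- regional_analysis(sv, n_bins = 8)
  expect_equal(r$posterior_to_anterior_ratio, 1, tolerance = 1e-9)
  expect_equal(r$left_to_right_ratio, 1, tolerance = 1e-9)
  expect_true(all(abs(r$bins$mean_svol - 0.25) < 1e-12))
  expect_equal(unname(r$apex_base["apex"]), 0.25)
  # posterior half expanding twice the anterior half
  ymid <- 15.5
  g <- expand.grid(x = 1:20, y = 1:30, z = 1:20)
  sv2_arr <- array(ifelse(g$y > ymid, 0.4, 0.2), dims)
  sv2_arr[lab == 0L] <- NA
  sv2 <- sv
  sv2$svol <- sv2_arr
  r2 <- regional_analysis(sv2, n_bins = 8)
  expect_equal(r2$posterior_to_anterior_ratio, 2, tolerance = 0.05)
  # left/right asymmetry
  sv3_arr <- array(ifelse(g$x > 10, 0.92 * 0.25, 0.25), dims)
  sv3_arr[lab == 0L] <- NA
  sv3 <- sv
  sv3$svol <- sv3_arr
  r3 <- regional_analysis(sv3, n_bins = 8)
  expect_equal(unname(r3$left_to_right_ratio), 0.92, tolerance = 1e-9)
})

test_that("regional ratios are stable under bin refinement", {
  ph <- generate_phantom(small_spec(seed = 31, hu_noise_sd = 0),
                         pressures = c(0, 5))
  gt <- ph$truth$step_fields[["0->5"]]
  mask <- segment_lungs(ph$volumes[["0"]])
  sv <- specific_volume(gt$field, mask)
  ratios <- sapply(c(5, 10, 20), function(nb)
    regional_analysis(sv, n_bins = nb)$posterior_to_anterior_ratio)
  expect_lt(diff(range(ratios)) / mean(ratios), 0.03)
})

test_that("ground-truth phantom fields carry the calibrated asymmetry", {
  # left lung expanding at 92% of the right on the first inflation step
  sp <- disease_phantom_spec(seed = 2, svol_lr_ratio = 0.92,
                             grid_shape = c(40, 40, 60), spacing = c(2, 2, 2),
                             hu_noise_sd = 0)
  ph <- generate_phantom(sp, pressures = c(0, 5))
  st <- ph$truth$step_fields[["0->5"]]
  lab <- ph$truth$labels[["0"]]
  lr <- mean(st$jacobian[lab == 1L] - 1) / mean(st$jacobian[lab == 2L] - 1)
  expect_equal(lr, 0.92, tolerance = 0.02)
})
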