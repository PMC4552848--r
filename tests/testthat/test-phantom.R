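test_that("fixed seeds reproduce phantoms bit-identically", {
  a <- generate_phantom(small_spec(seed = 21), pressures = c(0, 25))
  b <- generate_phantom(small_spec(seed = 21), pressures = c(0, 25))
  expect_identical(a$volumes[["0"]]$data, b$volumes[["0"]]$data)
  expect_identical(a$volumes[["25"]]$data, b$volumes[["25"]]$data)
  c <- generate_phantom(small_spec(seed = 22), pressures = 25)
  expect_false(identical(a$volumes[["25"]]$data, c$volumes[["25"]]$data))
  # cohorts and signals too
  expect_identical(generate_cohort(cohort_spec(n_per_group = 4, seed = 5)),
                   generate_cohort(cohort_spec(n_per_group = 4, seed = 5)))
  expect_identical(
    generate_ventilation_signal(0.5, 0.03, seed = 7)$pressure,
    generate_ventilation_signal(0.5, 0.03, seed = 7)$pressure)
})

test_that("phantom specs are validated", {
  lp <- list(right = lung_param("right"), left = lung_param("left"))
  lp$right$air_fraction_at_pressure <- c("0" = 0.6, "5" = 0.5, "15" = 0.7,
                                         "25" = 0.8)
  expect_error(phantom_spec(lung_params = lp), "strictly increase")
  expect_error(phantom_spec(theta_S_true = 160), "0, 150")
  # a spine too curved for a small grid names the offending parameter
  expect_error(
    generate_phantom(phantom_spec(grid_shape = c(20, 20, 24),
                                  spacing = c(1, 1, 1),
                                  theta_S_true = 150), pressures = 25),
    "theta_S_true")
})

test_that("uniform air fraction renders uniform lung HU", {
  lp <- list(
    right = lung_param("right", air_fraction_at_pressure = c("25" = 0.5)),
    left = lung_param("left", air_fraction_at_pressure = c("25" = 0.5)))
  sp <- small_spec(seed = 2, lung_params = lp, tissue_texture_amp = 0,
                   hu_noise_sd = 0)
  ph <- generate_phantom(sp, pressures = 25)
  hu <- ph$volumes[["25"]]$data[ph$truth$labels[["25"]] > 0]
  expect_equal(unname(stats::median(hu)), -500, tolerance = 1e-6)
  expect_lt(stats::sd(hu), 1e-6)
})

test_that("ground-truth masses equal the integrated tissue field exactly", {
  ph <- generate_phantom(small_spec(seed = 13, hu_noise_sd = 0),
                         pressures = 25)
  vol <- ph$volumes[["25"]]
  lab <- ph$truth$labels[["25"]]
  vpix <- prod(vol$spacing) / 1000
  for (k in c("right", "left")) {
    want <- if (k == "right") 2L else 1L
    mu <- 1 + vol$data[lab == want] / 1000
    expect_equal(sum(mu * vpix), unname(ph$truth$true_masses[k]),
                 tolerance = 1e-6)
  }
})

test_that("analytic step Jacobians are positive and invertible on lungs", {
  ph <- generate_phantom(small_spec(seed = 4, hu_noise_sd = 0),
                         pressures = c(0, 5, 15, 25))
  for (s in names(ph$truth$step_fields)) {
    st <- ph$truth$step_fields[[s]]
    low <- sub("->.*", "", s)
    inl <- ph$truth$labels[[low]] > 0
    expect_true(all(st$jacobian[inl] > 0.1), label = s)
    # inflation: volumes grow at every step
    expect_gt(mean(st$jacobian[inl]), 1)
  }
})

test_that("ground-truth step fields map the lower image onto the higher", {
  ph <- generate_phantom(small_spec(seed = 4, hu_noise_sd = 0),
                         pressures = c(0, 5))
  st <- ph$truth$step_fields[["0->5"]]
  f <- ph$volumes[["0"]]$data
  m <- ph$volumes[["5"]]$data
  inl <- ph$truth$labels[["0"]] > 0
  sp <- ph$volumes[["0"]]$spacing
  mw <- thoraciq:::warp_volume(m, st$field$u[, , , 1] / sp[1],
                               st$field$u[, , , 2] / sp[2],
                               st$field$u[, , , 3] / sp[3])
  # after mass-conservation compensation the correspondence must explain
  # the image pair far better than the identity does
  rho_f <- 1 + f / 1000
  rho_w <- (1 + mw / 1000) * st$jacobian
  res_gt <- mean(abs(rho_f - rho_w)[inl])
  res_id <- mean(abs(rho_f - (1 + m / 1000))[inl])
  expect_lt(res_gt, 0.5 * res_id)
})

test_that("per-animal cohort phantoms inherit the animal's physiology", {
  tab <- generate_cohort(cohort_spec(n_per_group = 3, seed = 77))
  row <- tab[tab$week == 28 & tab$group == "Severe", ][1, ]
  sp <- phantom_spec_from_animal(row, grid_shape = c(40, 40, 60),
                                 spacing = c(2, 2, 2), hu_noise_sd = 0,
                                 seed = 1)
  ph <- generate_phantom(sp, pressures = 25)
  vol <- ph$volumes[["25"]]
  meas <- suppressMessages(measure_lungs(vol, segment_lungs(vol)))
  expect_equal(unname(meas$mass["right"]), row$mass_right, tolerance = 0.04)
  expect_equal(unname(meas$air_volume["right"]), row$tlc_right,
               tolerance = 0.06)
})

test_that("volumes survive a NIfTI round trip with spacing metadata", {
  ph <- generate_phantom(small_spec(seed = 1), pressures = 25)
  vol <- ph$volumes[["25"]]
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path, pressure = 25)
  expect_equal(back$data, vol$data, ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
})
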