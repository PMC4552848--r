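test_that("composite deformity angle reduces exactly in single planes and is symmetric", {
  expect_equal(maximal_deformity_angle(60, 0), 60)
  expect_equal(maximal_deformity_angle(0, 45), 45)
  expect_equal(maximal_deformity_angle(0, 0), 0)
  expect_equal(maximal_deformity_angle(90, 90), 2 * atan(sqrt(2)) * 180 / pi,
               tolerance = 1e-10)
  grid <- expand.grid(s = c(10, 40, 80, 120), k = c(5, 35, 75, 110))
  for (i in seq_len(nrow(grid))) {
    expect_equal(maximal_deformity_angle(grid$s[i], grid$k[i]),
                 maximal_deformity_angle(grid$k[i], grid$s[i]),
                 tolerance = 1e-12)
  }
  # monotone nondecreasing in each argument
  s <- seq(0, 140, by = 10)
  expect_true(all(diff(maximal_deformity_angle(s, 30)) > 0))
  expect_true(all(diff(maximal_deformity_angle(20, s)) > 0))
  expect_error(maximal_deformity_angle(180, 0), "180")
})

test_that("composite angle matches the brute-force projection oracle", {
  for (s in c(0, 25, 60, 100)) {
    for (k in c(0, 40, 85)) {
      expect_lt(abs(maximal_deformity_angle(s, k) - projected_max_angle(s, k)),
                2)
    }
  }
})

test_that("centerline Cobb angle recovers planar arcs and straight spines", {
  expect_equal(cobb_angle(arc_annotation(60), "coronal"), 60, tolerance = 0.02)
  expect_equal(cobb_angle(arc_annotation(35), "coronal"), 35, tolerance = 0.03)
  # arc lies in the coronal plane; sagittal projection is straight
  expect_equal(cobb_angle(arc_annotation(60), "sagittal"), 0)
  straight <- spine_annotation(cbind(40, 40, seq(10, 110, length.out = 10)))
  expect_equal(cobb_angle(straight, "coronal"), 0)
  expect_error(spine_annotation(cbind(40, 40, c(1, 2, 3))), "at least 4")
  expect_error(spine_annotation(cbind(40, 40, c(3, 2, 1, 4))), "ordered")
})

test_that("Cobb angle is stable under small in-plane rigid rotation", {
  ann <- arc_annotation(50)
  base <- cobb_angle(ann, "coronal")
  for (rot in c(-8, 5, 9)) {
    r <- deg2rad(rot)
    cen <- ann$centroids
    cen2 <- cen
    cen2[, 1] <- 40 + cos(r) * (cen[, 1] - 40) + sin(r) * (cen[, 3] - 60)
    cen2[, 3] <- 60 - sin(r) * (cen[, 1] - 40) + cos(r) * (cen[, 3] - 60)
    cen2 <- cen2[order(cen2[, 3]), ]
    expect_equal(cobb_angle(spine_annotation(cen2), "coronal"), base,
                 tolerance = 2 / base, label = sprintf("rotation %g deg", rot))
  }
})

test_that("thoracic rotation angle is apex-relative and ignores uniform rotation", {
  n <- 13
  # sinusoidal bulge: curvature peaks at mid-curve, so the apex is defined
  bulge <- function(rotation = NULL) {
    t <- seq(0, 1, length.out = n)
    spine_annotation(cbind(40 + 15 * sin(pi * t), 40, 20 + 80 * t),
                     axial_rotation = rotation)
  }
  expect_equal(thoracic_rotation_angle(bulge(rep(0, n)))$tra, 0)
  expect_equal(thoracic_rotation_angle(bulge(rep(10, n)))$tra, 0)
  rot <- 20 * sin(pi * seq(0, 1, length.out = n))
  res <- thoracic_rotation_angle(bulge(rot))
  expect_equal(res$tra, 20, tolerance = 0.05)
  expect_equal(res$apex_index, 7)
  expect_error(thoracic_rotation_angle(bulge()), "rotation")
})

test_that("severity classification follows the 55-degree rule", {
  expect_equal(as.character(classify_severity(56)), "Severe")
  expect_equal(as.character(classify_severity(55)), "Moderate")
  expect_equal(as.character(classify_severity(16)), "Moderate")
  expect_equal(as.character(classify_severity(15)), "Normal-range")
  expect_equal(as.character(classify_severity(0)), "Normal-range")
  expect_error(classify_severity(-1), "non-negative")
})

test_that("phantom landmarks round-trip the generative deformity angles", {
  ph <- generate_phantom(small_spec(seed = 3, theta_S_true = 40,
                                    theta_K_true = 0,
                                    apical_rotation_true = 20,
                                    hu_noise_sd = 0),
                         pressures = 25)
  d <- deformity_measures(ph$truth$landmarks)
  expect_equal(d$theta_S, 40, tolerance = 1 / 40)
  expect_lt(d$theta_K, 0.5)
  expect_equal(d$TRA, 20, tolerance = 1 / 20)

  ph2 <- generate_phantom(small_spec(seed = 3, theta_S_true = 70,
                                     theta_K_true = 30, hu_noise_sd = 0),
                          pressures = 25)
  d2 <- deformity_measures(ph2$truth$landmarks)
  expect_equal(d2$theta_M, maximal_deformity_angle(70, 30), tolerance = 0.02)
  expect_equal(as.character(d2$severity), "Severe")
})

test_that("spine annotations survive a JSON round trip", {
  ann <- arc_annotation(45, rotation = seq(0, 12, length.out = 13))
  path <- tempfile(fileext = ".json")
  write_spine_annotation(ann, path)
  back <- read_spine_annotation(path)
  expect_equal(back$centroids, ann$centroids, ignore_attr = TRUE)
  expect_equal(back$axial_rotation, ann$axial_rotation)
  expect_equal(cobb_angle(back, "coronal"), cobb_angle(ann, "coronal"))
})
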