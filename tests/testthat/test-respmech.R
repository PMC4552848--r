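test_that("noiseless single-compartment signals are inverted almost exactly", {
  truth <- c(E = 0.45, R = 0.03, P0 = 2)
  sig <- generate_ventilation_signal(E = truth["E"], R = truth["R"],
                                     P0 = truth["P0"], noise_sd = 0)
  fit <- fit_single_compartment(sig)
  expect_true(all(abs(coef(fit) - truth) / truth < 1e-3))
  expect_false(fit$gated)
  expect_equal(fit$MIP, 13, tolerance = 0.01)
})

test_that("recursive estimator with forgetting 1 matches batch least squares", {
  sig <- generate_ventilation_signal(E = 0.6, R = 0.05, P0 = 1.5,
                                     noise_sd = 0.2, seed = 10)
  fit <- fit_single_compartment(sig, forgetting = 1)
  s <- summary(fit)
  final <- fit$trace[nrow(fit$trace), ]
  expect_equal(unname(final), unname(s$ols), tolerance = 1e-6)
  # reported (final-cycle mean) estimate stays within 2% of batch OLS
  expect_true(all(abs(coef(fit) - s$ols) / abs(s$ols) < 0.02))
})

test_that("estimates are invariant to a pressure offset except through P0", {
  sig <- generate_ventilation_signal(E = 0.5, R = 0.04, P0 = 2,
                                     noise_sd = 0.1, seed = 4)
  fit1 <- fit_single_compartment(sig)
  sig2 <- sig
  sig2$pressure <- sig$pressure + 3
  fit2 <- fit_single_compartment(sig2)
  expect_equal(coef(fit2)["E"], coef(fit1)["E"], tolerance = 1e-6)
  expect_equal(coef(fit2)["R"], coef(fit1)["R"], tolerance = 1e-6)
  expect_equal(unname(coef(fit2)["P0"] - coef(fit1)["P0"]), 3,
               tolerance = 1e-6)
})

test_that("elastance is stable under a small constant flow offset", {
  sig <- generate_ventilation_signal(E = 0.5, R = 0.04, P0 = 2,
                                     noise_sd = 0, seed = 4)
  fit1 <- fit_single_compartment(sig)
  sig2 <- sig
  sig2$flow <- sig$flow + 0.01 * max(sig$flow)  # 1% of peak drift
  fit2 <- fit_single_compartment(sig2)
  expect_lt(abs(coef(fit2)["E"] - coef(fit1)["E"]) / coef(fit1)["E"], 0.02)
})

test_that("records above the MIP limit are gated", {
  hi <- generate_ventilation_signal(E = 0.45, R = 0.03, mip = 15,
                                    noise_sd = 0.05, seed = 1)
  expect_true(fit_single_compartment(hi)$gated)
  lo <- generate_ventilation_signal(E = 0.45, R = 0.03, mip = 13,
                                    noise_sd = 0.05, seed = 1)
  expect_false(fit_single_compartment(lo)$gated)
  short <- generate_ventilation_signal(E = 0.45, R = 0.03, n_cycles = 2)
  expect_error(fit_single_compartment(short), "3 complete breath cycles")
})

test_that("noisy replicates are unbiased and recursive matches batch", {
  truth <- c(E = 0.5, R = 0.035, P0 = 2)
  ests <- t(vapply(1:40, function(i) {
    sig <- generate_ventilation_signal(E = truth["E"], R = truth["R"],
                                       P0 = truth["P0"], noise_sd = 0.3,
                                       seed = 100 + i)
    coef(fit_single_compartment(sig))
  }, numeric(3)))
  se <- apply(ests, 2, stats::sd) / sqrt(nrow(ests))
  bias <- abs(colMeans(ests) - truth)
  expect_true(all(bias < 3 * se + 1e-8))
  # two seeds give different samples
  s1 <- generate_ventilation_signal(E = 0.5, R = 0.035, noise_sd = 0.3,
                                    seed = 1)
  s2 <- generate_ventilation_signal(E = 0.5, R = 0.035, noise_sd = 0.3,
                                    seed = 2)
  expect_false(identical(s1$pressure, s2$pressure))
})

test_that("resp_fit behaves like a model object", {
  sig <- generate_ventilation_signal(E = 0.5, R = 0.04, P0 = 2,
                                     noise_sd = 0.1, seed = 9)
  fit <- fit_single_compartment(sig)
  expect_named(coef(fit), c("E", "R", "P0"))
  expect_equal(length(residuals(fit)), length(sig$pressure))
  expect_equal(fitted(fit) + residuals(fit), sig$pressure)
  expect_equal(predict(fit), fitted(fit))
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "pressure_flow_signal")
  expect_output(print(summary(fit)), "batch OLS")
})

test_that("forced vital capacity applies the repeatability rule", {
  mans <- lapply(c(60, 58, 59), function(v)
    generate_fvc_maneuver(v, noise_sd = 0))
  res <- forced_vital_capacity(mans)
  # highest expired volume, up to the 2% flow-cessation truncation
  expect_equal(res$FVC, 60, tolerance = 0.025)
  expect_equal(which.max(res$volumes_ml), 1)
  expect_equal(res$reason, "accepted")

  bad <- forced_vital_capacity(lapply(c(60, 50), generate_fvc_maneuver,
                                      noise_sd = 0))
  expect_true(is.na(bad$FVC))
  expect_match(bad$reason, "repeatability failure")

  single <- forced_vital_capacity(list(generate_fvc_maneuver(60)))
  expect_true(is.na(single$FVC))
  expect_match(single$reason, "fewer than 2")
})

test_that("maneuver integration is faithful and resampling-invariant", {
  m <- generate_fvc_maneuver(60, noise_sd = 0, fs = 1000)
  full <- sum((m$flow[-1] + m$flow[-length(m$flow)]) / 2 * diff(m$time))
  expect_equal(full, 60, tolerance = 1e-4)
  v1 <- forced_vital_capacity(list(m, m))$FVC
  m2 <- generate_fvc_maneuver(60, noise_sd = 0, fs = 2000)
  v2 <- forced_vital_capacity(list(m2, m2))$FVC
  expect_lt(abs(v1 - v2) / v1, 0.005)
})

test_that("non-monotone expirations are flagged invalid", {
  m <- generate_fvc_maneuver(60, noise_sd = 0)
  bad <- m
  n <- length(bad$flow)
  bad$flow[seq(n %/% 4, n %/% 2)] <- -80   # large inspiratory swing
  res <- forced_vital_capacity(list(m, bad))
  expect_false(res$valid[2])
  expect_true(is.na(res$FVC))  # only one valid maneuver remains
})
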