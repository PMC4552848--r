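test_that("percent of normal is exact on constructed groups and scale-invariant", {
  tab <- data.frame(
    animal = sprintf("A%02d", 1:30),
    group = factor(rep(c("Normal", "Moderate", "Severe"), each = 10),
                   levels = c("Normal", "Moderate", "Severe")),
    week = 28,
    y = c(rep(10, 10), rep(10, 10), rep(5.9, 10)))
  p <- percent_of_normal(tab, "y")
  expect_equal(p$mean_pct[p$group == "Moderate"], 100)
  expect_equal(p$mean_pct[p$group == "Severe"], 59)
  tab2 <- tab
  tab2$y <- tab$y * 7.3
  expect_equal(percent_of_normal(tab2, "y")$mean_pct, p$mean_pct)
  tab$y <- tab$y + rnorm(30, 0, 0.1)
  expect_error(percent_of_normal(tab[tab$group != "Normal", ], "y"),
               "Normal group")
})

test_that("regression matches closed-form expectations and a numeric oracle", {
  tab <- data.frame(animal = sprintf("A%02d", 1:10),
                    group = factor(rep("Severe", 10),
                                   levels = c("Normal", "Moderate", "Severe")),
                    week = 28,
                    x = 1:10, y = 2 * (1:10))
  fit <- regress(tab, c("x", 28), c("y", 28))
  expect_equal(fit$slope, 2)
  expect_equal(fit$pearson_r, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$r_squared, fit$pearson_r^2, tolerance = 1e-10)

  set.seed(3)
  tab$y <- rnorm(10) * 3 + 0.8 * tab$x
  fit2 <- regress(tab, c("x", 28), c("y", 28))
  # brute-force: numeric minimisation of squared error
  sse <- function(b) sum((tab$y - b[1] - b[2] * tab$x)^2)
  opt <- optim(c(0, 0), sse, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  expect_equal(fit2$intercept, opt$par[1], tolerance = 1e-4)
  expect_equal(fit2$slope, opt$par[2], tolerance = 1e-4)
  expect_equal(fit2$p_value,
               summary(lm(y ~ x, tab))$coefficients[2, 4], tolerance = 1e-8)

  # independent x and y: R^2 near zero
  set.seed(4)
  big <- data.frame(animal = sprintf("B%04d", 1:1000),
                    group = factor(rep("Severe", 1000),
                                   levels = c("Normal", "Moderate", "Severe")),
                    week = 28, x = rnorm(1000), y = rnorm(1000))
  expect_lt(regress(big, c("x", 28), c("y", 28))$r_squared, 0.01)
  expect_error(regress(big[1:2, ], c("x", 28), c("y", 28)), "at least 3")
})

test_that("slope-vs-unity test detects progressive deformity", {
  set.seed(9)
  reject <- replicate(120, {
    x <- runif(10, 25, 75)
    y <- 1.4 * x + rnorm(10, 0, 5)
    tab <- data.frame(animal = sprintf("C%02d", 1:10),
                      group = factor(rep("Severe", 10),
                                     levels = c("Normal", "Moderate",
                                                "Severe")),
                      week = 28, x = x, y = y)
    slope_vs_unity_test(regress(tab, c("x", 28), c("y", 28)))$p_value < 0.05
  })
  expect_gt(mean(reject), 0.8)
  # null: slope exactly 1 with noise rejects at ~alpha
  null_rej <- replicate(120, {
    x <- runif(10, 25, 75)
    y <- x + rnorm(10, 0, 6)
    tab <- data.frame(animal = sprintf("C%02d", 1:10),
                      group = factor(rep("Severe", 10),
                                     levels = c("Normal", "Moderate",
                                                "Severe")),
                      week = 28, x = x, y = y)
    slope_vs_unity_test(regress(tab, c("x", 28), c("y", 28)))$p_value < 0.05
  })
  expect_lt(mean(null_rej), 0.2)
  # degenerate: zero residual variance
  tab <- data.frame(animal = sprintf("D%02d", 1:5),
                    group = factor(rep("Severe", 5),
                                   levels = c("Normal", "Moderate", "Severe")),
                    week = 28, x = 1:5, y = 1:5)
  expect_error(slope_vs_unity_test(regress(tab, c("x", 28), c("y", 28))),
               "degenerate")
})

test_that("cohort sample statistics converge to the calibrated targets", {
  tab <- generate_cohort(cohort_spec(n_per_group = 500, seed = 42))
  d28 <- tab[tab$week == 28, ]
  # Severe right-lung mass fraction of Normal
  sev <- mean(d28$mass_right[d28$group == "Severe"])
  nor <- mean(d28$mass_right[d28$group == "Normal"])
  se <- stats::sd(d28$mass_right[d28$group == "Severe"]) / sqrt(500) / nor
  expect_lt(abs(sev / nor - 0.59), 3 * se + 0.015)
  # progression R^2 between 6 and 28 weeks over Disease animals
  fit <- regress(tab, c("theta_m", 6), c("theta_m", 28))
  expect_equal(fit$r_squared, 0.88, tolerance = 0.035)
  expect_gt(fit$slope, 1)
  # severity assignment obeys the 10-week threshold
  t10 <- tab[tab$week == 10 & d28$group[match(tab$animal[tab$week == 10],
                                              d28$animal)] != "Normal", ]
  expect_true(all((t10$theta_m > 55) == (t10$group == "Severe")))
})

test_that("a null cohort shows no group differences or correlations", {
  ge <- default_group_effects()
  ge$moderate_frac[] <- 1
  ge$severe_frac[] <- 1
  cs <- cohort_spec(n_per_group = 200, group_effects = ge,
                    correlation_targets =
                      default_correlation_targets()[1, , drop = FALSE],
                    seed = 11)
  tab <- generate_cohort(cs)
  p <- percent_of_normal(tab, "mass_right")
  expect_equal(p$mean_pct[p$group == "Severe"], 100, tolerance = 0.03)
  t2 <- suppressMessages(build_table2(tab))
  expect_lt(t2$r2_28wk[t2$outcome == "mass_right"], 0.05)
})

test_that("calibrated cohorts recover the deformity-outcome R^2 matrix", {
  tab <- generate_cohort(cohort_spec(n_per_group = 200, seed = 7))
  t2 <- suppressMessages(build_table2(tab))
  get <- function(o, col) t2[t2$outcome == o, col]
  expect_equal(get("elastance", "r2_28wk"), 0.92, tolerance = 0.045)
  expect_equal(get("elastance", "sign_28wk"), "+")
  expect_equal(get("mass_right", "r2_28wk"), 0.95, tolerance = 0.045)
  expect_equal(get("mass_right", "sign_28wk"), "-")
  expect_equal(get("tlc_right", "r2_28wk"), 0.76, tolerance = 0.06)
  expect_equal(get("fvc", "sign_28wk"), "-")
  expect_equal(get("tra", "sign_28wk"), "+")
})

test_that("infeasible correlation targets are rejected with the pair named", {
  ct <- default_correlation_targets()
  ct$r2[ct$outcome == "fvc"] <- 0
  expect_error(cohort_spec(correlation_targets = ct), "fvc")
  ge <- default_group_effects()
  ge$moderate_frac[ge$outcome == "elastance"] <- 1
  ge$severe_frac[ge$outcome == "elastance"] <- 1
  expect_error(generate_cohort(cohort_spec(group_effects = ge, seed = 1)),
               "elastance")
})
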