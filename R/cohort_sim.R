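#' Default group effects for the synthetic cohort
#'
#' Healthy-adult (28-week) outcome means with Moderate and Severe group
#' effects expressed as fractions of Normal, and a relative SD used where no
#' correlation target applies.  Units: grams for masses and body mass, mL
#' for volumes and FVC, cmH2O/mL for elastance, cmH2O.s/mL for resistance,
#' counts for the radial alveolar count (RAC) covariate.
#'
#' @return data.frame with columns `outcome`, `normal_mean`,
#'   `moderate_frac`, `severe_frac`, `sd_frac`.
#' @export
default_group_effects <- function() {
  tab <- rbind(
    c("body_mass",  4000,  0.97, 0.89, 0.05),
    c("mass_right", 9.3,   0.87, 0.59, 0.12),
    c("mass_left",  6.7,   1.00, 0.86, 0.12),
    c("tlc_right",  32.0,  0.79, 0.60, 0.10),
    c("tlc_left",   23.2,  1.08, 1.05, 0.14),
    c("frc_right",  10.4,  0.68, 0.63, 0.28),
    c("frc_left",   7.5,   1.37, 1.50, 0.45),
    c("fvc",        60.0,  1.00, 0.75, 0.12),
    c("elastance",  0.45,  1.15, 1.45, 0.12),
    c("resistance", 0.030, 1.00, 1.00, 0.10),
    c("rac_right",  12.2,  0.96, 0.74, 0.15),
    c("rac_left",   11.8,  0.90, 0.69, 0.12))
  data.frame(outcome = tab[, 1],
             normal_mean = as.numeric(tab[, 2]),
             moderate_frac = as.numeric(tab[, 3]),
             severe_frac = as.numeric(tab[, 4]),
             sd_frac = as.numeric(tab[, 5]),
             stringsAsFactors = FALSE)
}

#' Default deformity-outcome correlation targets
#'
#' Coefficients of determination targeted between the 28-week maximal
#' deformity angle and each outcome over the pooled Disease animals, plus
#' the 6-to-28-week deformity progression R^2.  Outcomes absent from this
#' table get their dispersion from `sd_frac` in [default_group_effects()]
#' instead.
#'
#' @return data.frame with columns `predictor`, `outcome`, `r2`.
#' @export
default_correlation_targets <- function() {
  tab <- rbind(
    c("theta_m_6",  "theta_m_28", 0.88),
    c("theta_m_28", "body_mass",  0.46),
    c("theta_m_28", "tra",        0.75),
    c("theta_m_28", "mass_right", 0.95),
    c("theta_m_28", "mass_left",  0.49),
    c("theta_m_28", "tlc_right",  0.76),
    c("theta_m_28", "frc_right",  0.17),
    c("theta_m_28", "frc_left",   0.26),
    c("theta_m_28", "fvc",        0.64),
    c("theta_m_28", "elastance",  0.92),
    c("theta_m_28", "rac_right",  0.69),
    c("theta_m_28", "rac_left",   0.78))
  data.frame(predictor = tab[, 1], outcome = tab[, 2],
             r2 = as.numeric(tab[, 3]), stringsAsFactors = FALSE)
}

#' Specification of a synthetic cohort
#'
#' @param n_per_group animals per group (Normal, Moderate, Severe).
#' @param group_effects data.frame as [default_group_effects()].
#' @param correlation_targets data.frame as
#'   [default_correlation_targets()]; R^2 values must lie in (0, 1].
#' @param deformity_slope true slope of the 6-to-28-week deformity
#'   progression (greater than unity: deformity worsens with growth).
#' @param normal_sd_frac relative SD of outcomes within the Normal group.
#' @param seed integer RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 8,
                        group_effects = default_group_effects(),
                        correlation_targets = default_correlation_targets(),
                        deformity_slope = 1.45,
                        normal_sd_frac = 0.08,
                        seed = 1L) {
  stopifnot(n_per_group >= 2)
  if (any(group_effects$moderate_frac <= 0) ||
      any(group_effects$severe_frac <= 0))
    stop("fraction-of-normal effects must be positive")
  if (any(group_effects$sd_frac < 0)) stop("SD fractions must be non-negative")
  bad <- correlation_targets$r2 <= 0 | correlation_targets$r2 > 1
  if (any(bad))
    stop(sprintf("infeasible R^2 target for (%s, %s): must lie in (0, 1]",
                 correlation_targets$predictor[which(bad)[1]],
                 correlation_targets$outcome[which(bad)[1]]))
  structure(list(n_per_group = as.integer(n_per_group),
                 group_effects = group_effects,
                 correlation_targets = correlation_targets,
                 deformity_slope = deformity_slope,
                 normal_sd_frac = normal_sd_frac,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a calibrated synthetic cohort
#'
#' Draws Normal animals around healthy means and Disease animals along a
#' deformity continuum: the 6-week maximal deformity angle is uniform on
#' 25-75 degrees, progresses to 28 weeks with slope `deformity_slope` and
#' Gaussian noise sized so the 6-to-28-week R^2 meets its target, and
#' animals are classified Severe when the interpolated 10-week angle
#' exceeds 55 degrees (batches are drawn until both Disease groups reach
#' `n_per_group`).  Each 28-week outcome is an affine function of the
#' 28-week angle whose two coefficients are solved from the Moderate and
#' Severe group-mean targets, with Gaussian noise sized in closed form so
#' the pooled-Disease R^2 meets its correlation target
#' (`sd = |slope| * sd(theta) * sqrt(1/R^2 - 1)`); outcomes without a
#' correlation target use `sd_frac` of the Normal mean instead.
#'
#' @param cspec a [cohort_spec()].
#' @return data.frame of class `cohort_table`, one row per animal-week
#'   (weeks 6, 10, 14, 28): `animal`, `group`, `week`, `theta_m`, `tra`,
#'   and 28-week outcome columns (NA at earlier weeks) including derived
#'   `ic_*`, `ftv_*`, totals and `rl_vol_ratio`.
#' @export
generate_cohort <- function(cspec) {
  stopifnot(inherits(cspec, "cohort_spec"))
  ge <- cspec$group_effects
  ct <- cspec$correlation_targets
  n <- cspec$n_per_group
  with_seed(cspec$seed, {
    # --- deformity trajectories ------------------------------------------
    prog <- ct[ct$predictor == "theta_m_6" & ct$outcome == "theta_m_28", ]
    r2_prog <- if (nrow(prog)) prog$r2[1] else 0.88
    slope <- cspec$deformity_slope
    sd6 <- 50 / sqrt(12)                       # SD of U(25, 75)
    sigma28 <- slope * sd6 * sqrt(1 / r2_prog - 1)
    draw_disease <- function(m) {
      t6 <- stats::runif(m, 25, 75)
      t28 <- slope * t6 + stats::rnorm(m, 0, sigma28)
      t28 <- pmax(t28, t6)                     # deformity does not regress
      t10 <- t6 + (t28 - t6) * (10 - 6) / (28 - 6) + stats::rnorm(m, 0, 2)
      t14 <- t6 + (t28 - t6) * (14 - 6) / (28 - 6) + stats::rnorm(m, 0, 2)
      data.frame(t6 = t6, t10 = t10, t14 = t14, t28 = t28,
                 group = ifelse(t10 > 55, "Severe", "Moderate"))
    }
    dis <- draw_disease(4 * n)
    while (sum(dis$group == "Severe") < n || sum(dis$group == "Moderate") < n)
      dis <- rbind(dis, draw_disease(2 * n))
    dis <- rbind(head(dis[dis$group == "Moderate", ], n),
                 head(dis[dis$group == "Severe", ], n))

    nor <- data.frame(t6 = pmax(stats::rnorm(n, 7, 2), 0))
    nor$t28 <- pmax(nor$t6 + stats::rnorm(n, 1, 1.5), 0)
    nor$t10 <- pmax(nor$t6 + stats::rnorm(n, 0.3, 1), 0)
    nor$t14 <- pmax(nor$t6 + stats::rnorm(n, 0.6, 1), 0)
    nor$group <- "Normal"

    # --- 28-week outcomes -------------------------------------------------
    th28 <- dis$t28
    sd_th <- stats::sd(th28)
    mean_m <- mean(th28[dis$group == "Moderate"])
    mean_s <- mean(th28[dis$group == "Severe"])
    n_dis <- nrow(dis)
    out_dis <- list()
    out_nor <- list()
    for (i in seq_len(nrow(ge))) {
      o <- ge$outcome[i]
      mn <- ge$normal_mean[i]
      c1 <- mn * (ge$severe_frac[i] - ge$moderate_frac[i]) / (mean_s - mean_m)
      c0 <- mn * ge$moderate_frac[i] - c1 * mean_m
      tgt <- ct[ct$predictor == "theta_m_28" & ct$outcome == o, ]
      if (nrow(tgt)) {
        if (abs(c1) < 1e-12)
          stop(sprintf(paste0("infeasible R^2 target for (theta_m_28, %s): ",
                              "group effects imply no deformity dependence"), o))
        sig <- abs(c1) * sd_th * sqrt(1 / tgt$r2[1] - 1)
      } else {
        sig <- ge$sd_frac[i] * mn
      }
      y <- c0 + c1 * th28 + stats::rnorm(n_dis, 0, sig)
      out_dis[[o]] <- pmax(y, 0.05 * mn)
      out_nor[[o]] <- pmax(mn * (1 + stats::rnorm(n, 0, cspec$normal_sd_frac)),
                           0.05 * mn)
    }
    # thoracic rotation angle: proportional to deformity in Disease
    tgt_tra <- ct[ct$predictor == "theta_m_28" & ct$outcome == "tra", ]
    tra_gain <- 0.4
    sig_tra <- if (nrow(tgt_tra))
      tra_gain * sd_th * sqrt(1 / tgt_tra$r2[1] - 1) else 3
    tra28_dis <- tra_gain * th28 + stats::rnorm(n_dis, 0, sig_tra)
    tra28_nor <- stats::rnorm(n, 2, 1)

    assemble <- function(traj, out, tra28, ids) {
      wk <- c(6, 10, 14, 28)
      do.call(rbind, lapply(seq_along(wk), function(wi) {
        w <- wk[wi]
        th <- traj[[c("t6", "t10", "t14", "t28")[wi]]]
        d <- data.frame(animal = ids, group = traj$group, week = w,
                        theta_m = th,
                        tra = tra28 * th / pmax(traj$t28, 1e-6))
        for (o in names(out))
          d[[o]] <- if (w == 28) out[[o]] else NA_real_
        d
      }))
    }
    ids_d <- sprintf("D%03d", seq_len(n_dis))
    ids_n <- sprintf("N%03d", seq_len(n))
    tab <- rbind(assemble(dis, out_dis, tra28_dis, ids_d),
                 assemble(nor, out_nor, tra28_nor, ids_n))
  })
  # derived quantities at 28 weeks
  at28 <- tab$week == 28
  tab$mass_total <- tab$mass_right + tab$mass_left
  tab$tlc_total <- tab$tlc_right + tab$tlc_left
  tab$frc_total <- tab$frc_right + tab$frc_left
  tab$ic_right <- tab$tlc_right - tab$frc_right
  tab$ic_left <- tab$tlc_left - tab$frc_left
  tab$ic_total <- tab$tlc_total - tab$frc_total
  tab$ftv_right <- tab$mass_right / (tab$mass_right + tab$tlc_right)
  tab$ftv_left <- tab$mass_left / (tab$mass_left + tab$tlc_left)
  tab$rl_vol_ratio <- tab$tlc_right / tab$tlc_left
  tab$rac_total <- (tab$rac_right + tab$rac_left) / 2
  tab$group <- factor(tab$group, levels = c("Normal", "Moderate", "Severe"))
  rownames(tab) <- NULL
  class(tab) <- c("cohort_table", "data.frame")
  attr(tab, "spec") <- cspec
  stopifnot(any(at28))
  tab
}

#' @export
print.cohort_table <- function(x, ...) {
  n_by <- table(x$group[x$week == 28])
  cat(sprintf("<cohort_table> %d animals (%s), weeks %s\n",
              sum(n_by), paste(names(n_by), n_by, sep = "=", collapse = ", "),
              paste(sort(unique(x$week)), collapse = "/")))
  invisible(x)
}

#' Phantom specification for one cohort animal
#'
#' Maps a 28-week cohort row onto a [phantom_spec()]: per-lung region
#' volumes are scaled so the geometric lung volume at total lung capacity
#' equals `tlc + mass`, the tissue field is scaled to the animal's lung
#' mass exactly, and the per-pressure air fractions follow the animal's
#' FRC/TLC with the saturating pressure-volume relation.
#'
#' @param row single-row subset of a `cohort_table` at week 28.
#' @param grid_shape,spacing,hu_noise_sd,seed passed to [phantom_spec()].
#' @param render_deformity if `TRUE`, the animal's deformity angle is split
#'   between the coronal and sagittal planes and rendered into the spine.
#' @return a [phantom_spec()].
#' @export
phantom_spec_from_animal <- function(row, grid_shape = c(64, 64, 96),
                                     spacing = c(1.25, 1.25, 1.25),
                                     hu_noise_sd = 20, seed = 1L,
                                     render_deformity = TRUE) {
  stopifnot(nrow(row) == 1, row$week == 28)
  L <- grid_shape * spacing
  base_semi <- list(
    right = c(0.175 * L[1], 0.225 * L[2], 0.31 * L[3]),
    left  = c(0.1625 * L[1], 0.2125 * L[2], 0.2667 * L[3]))
  lp <- list()
  for (k in c("right", "left")) {
    mass <- row[[paste0("mass_", k)]]
    frc <- row[[paste0("frc_", k)]]
    tlc <- row[[paste0("tlc_", k)]]
    frc <- min(frc, 0.9 * tlc)      # guard against extreme FRC draws
    g_base <- 4 / 3 * pi * prod(base_semi[[k]]) / 1000
    lp[[k]] <- lung_param(k, volume_scale = (tlc + mass) / g_base,
                          mass_g = mass, frc_ml = frc, tlc_ml = tlc)
  }
  th <- if (render_deformity && !is.na(row$theta_m)) row$theta_m else 0
  # split the composite angle ~2:1 between scoliosis and kyphosis
  ts <- rad2deg(2 * atan(tan(deg2rad(th) / 2) * 0.894))
  tk <- rad2deg(2 * atan(tan(deg2rad(th) / 2) * 0.447))
  phantom_spec(grid_shape = grid_shape, spacing = spacing,
               theta_S_true = ts, theta_K_true = tk,
               apical_rotation_true = if (!is.na(row$tra)) row$tra else 0,
               lung_params = lp, hu_noise_sd = hu_noise_sd, seed = seed)
}

#' Disease phantom with a prescribed left/right expansion asymmetry
#'
#' Builds a [phantom_spec()] with Severe-deformity lung physiology in which
#' the left lung's mean volumetric expansion over the 0-to-5 cmH2O step is
#' a fixed fraction of the right lung's (default 0.92).  The left lung's
#' 5 cmH2O air volume is solved from the ratio; all other pressures follow
#' the saturating pressure-volume relation.
#'
#' @param seed integer RNG seed (also jitters the physiology).
#' @param svol_lr_ratio target left/right mean specific-volume ratio on the
#'   0-to-5 cmH2O step.
#' @param jitter_sd lognormal-type relative jitter of the per-animal
#'   physiology.
#' @param grid_shape,spacing,hu_noise_sd passed to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
disease_phantom_spec <- function(seed = 1L, svol_lr_ratio = 0.92,
                                 jitter_sd = 0.05,
                                 grid_shape = c(64, 64, 96),
                                 spacing = c(1.25, 1.25, 1.25),
                                 hu_noise_sd = 20) {
  base <- list(mass_r = 5.49, frc_r = 6.55, tlc_r = 19.2,
               mass_l = 5.76, frc_l = 11.25, tlc_l = 24.36)
  ph <- with_seed(seed, lapply(base, function(v)
    v * exp(stats::rnorm(1, 0, jitter_sd))))
  pr <- c(0, 5, 15, 25)
  vcurve <- function(frc, tlc)
    frc + (tlc - frc) * (1 - exp(-pr / 8)) / (1 - exp(-25 / 8))
  v_r <- vcurve(ph$frc_r, ph$tlc_r)
  e_r <- (v_r[2] + ph$mass_r) / (v_r[1] + ph$mass_r) - 1
  v_l <- vcurve(ph$frc_l, ph$tlc_l)
  # left 5 cmH2O air volume solved so mean step expansion is ratio * right
  v_l[2] <- (v_l[1] + ph$mass_l) * (1 + svol_lr_ratio * e_r) - ph$mass_l
  if (any(diff(v_l) <= 0))
    stop("svol_lr_ratio target produced a non-monotone left pressure-volume curve")
  fa_r <- stats::setNames(v_r / (v_r + ph$mass_r), as.character(pr))
  fa_l <- stats::setNames(v_l / (v_l + ph$mass_l), as.character(pr))
  L <- grid_shape * spacing
  g_base <- list(
    right = 4 / 3 * pi * prod(c(0.175 * L[1], 0.225 * L[2], 0.31 * L[3])) / 1000,
    left = 4 / 3 * pi * prod(c(0.1625 * L[1], 0.2125 * L[2],
                               0.2667 * L[3])) / 1000)
  lp <- list(
    right = lung_param("right",
                       volume_scale = (ph$tlc_r + ph$mass_r) / g_base$right,
                       mass_g = ph$mass_r, frc_ml = ph$frc_r,
                       tlc_ml = ph$tlc_r, air_fraction_at_pressure = fa_r),
    left = lung_param("left",
                      volume_scale = (ph$tlc_l + ph$mass_l) / g_base$left,
                      mass_g = ph$mass_l, frc_ml = ph$frc_l,
                      tlc_ml = ph$tlc_l, air_fraction_at_pressure = fa_l))
  phantom_spec(grid_shape = grid_shape, spacing = spacing,
               theta_S_true = 55, theta_K_true = 40,
               apical_rotation_true = 20, lung_params = lp,
               hu_noise_sd = hu_noise_sd, seed = seed)
}

#' Render cohort animals and measure them densitometrically
#'
#' For each 28-week cohort row, renders the phantom at the requested
#' breath-hold pressure, segments the lungs and applies HU densitometry,
#' returning measured per-lung masses and aerated volumes alongside the
#' animal identifiers.  This is the image-based measurement arm used to
#' recover group statistics through the full pipeline.
#'
#' @param rows `cohort_table` rows at week 28.
#' @param pressure breath-hold pressure to render and measure, cmH2O.
#' @param grid_shape,spacing,hu_noise_sd phantom rendering parameters.
#' @param seed base RNG seed; animal `i` uses `seed + i`.
#' @param render_deformity passed to [phantom_spec_from_animal()].
#' @return data.frame with measured `mass_right/left/total` (g) and
#'   `air_right/left/total` (mL) per animal, plus `group` and `week`.
#' @export
densitometry_for_cohort <- function(rows, pressure = 25,
                                    grid_shape = c(64, 64, 96),
                                    spacing = c(1.25, 1.25, 1.25),
                                    hu_noise_sd = 20, seed = 1L,
                                    render_deformity = TRUE) {
  stopifnot(all(rows$week == 28))
  res <- lapply(seq_len(nrow(rows)), function(i) {
    sp <- phantom_spec_from_animal(rows[i, , drop = FALSE],
                                   grid_shape = grid_shape, spacing = spacing,
                                   hu_noise_sd = hu_noise_sd,
                                   seed = seed + i,
                                   render_deformity = render_deformity)
    ph <- generate_phantom(sp, pressures = pressure)
    vol <- ph$volumes[[as.character(pressure)]]
    mask <- segment_lungs(vol)
    m <- suppressMessages(measure_lungs(vol, mask))
    data.frame(animal = rows$animal[i], group = rows$group[i], week = 28,
               mass_right = m$mass[["right"]], mass_left = m$mass[["left"]],
               mass_total = m$mass[["total"]],
               air_right = m$air_volume[["right"]],
               air_left = m$air_volume[["left"]],
               air_total = m$air_volume[["total"]])
  })
  do.call(rbind, res)
}
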