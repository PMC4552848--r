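#' Air-fraction schedule across breath-hold pressures
#'
#' Converts a lung's functional residual capacity, total lung capacity and
#' tissue mass into mean air fractions at a set of breath-hold pressures,
#' assuming a saturating-exponential pressure-volume relation
#' `V(P) = FRC + (TLC - FRC) * (1 - exp(-P/lambda)) / (1 - exp(-Pmax/lambda))`.
#'
#' @param frc_ml aerated volume at 0 cmH2O, mL.
#' @param tlc_ml aerated volume at the maximum pressure, mL.
#' @param mass_g tissue mass, g (1 g of tissue occupies 1 mL).
#' @param pressures breath-hold pressures, cmH2O.
#' @param lambda pressure-volume curvature constant, cmH2O.
#' @return named numeric vector of mean air fractions in `[0, 1)`.
#' @export
lung_air_fractions <- function(frc_ml, tlc_ml, mass_g,
                               pressures = c(0, 5, 15, 25), lambda = 8) {
  stopifnot(frc_ml > 0, tlc_ml > frc_ml, mass_g > 0, lambda > 0)
  pmax_ <- max(pressures)
  v <- frc_ml + (tlc_ml - frc_ml) *
    (1 - exp(-pressures / lambda)) / (1 - exp(-pmax_ / lambda))
  stats::setNames(v / (v + mass_g), as.character(pressures))
}

# Baseline healthy-adult (28-week) lung physiology used for generator
# defaults: right/left TLC ratio 1.38, FRC about a third of TLC, tissue
# masses giving ~78% air fraction at TLC.
.normal_lung_physio <- list(
  right = list(mass_g = 9.3, frc_ml = 10.4, tlc_ml = 32.0),
  left  = list(mass_g = 6.7, frc_ml = 7.5,  tlc_ml = 23.2)
)

#' Per-lung generator parameters
#'
#' Builds the `lung_params` entry of a [phantom_spec()] from physiological
#' targets.  `volume_scale` and `tissue_density_scale` rescale the rendered
#' lung region and its tissue-fraction field relative to the healthy-adult
#' baseline; explicit `mass_g`/`frc_ml`/`tlc_ml` targets override the
#' baseline values.
#'
#' @param side `"right"` or `"left"`.
#' @param volume_scale dimensionless scaling of the lung region volume.
#' @param tissue_density_scale dimensionless scaling of the tissue fraction.
#' @param mass_g,frc_ml,tlc_ml physiological targets (defaults: healthy
#'   adult).
#' @param lambda pressure-volume curvature constant, cmH2O.
#' @param air_fraction_at_pressure optional named vector of mean air
#'   fractions per pressure; computed from the targets when `NULL`.
#' @return list suitable for `phantom_spec(lung_params = list(right=, left=))`.
#' @export
lung_param <- function(side = c("right", "left"), volume_scale = 1,
                       tissue_density_scale = 1, mass_g = NULL,
                       frc_ml = NULL, tlc_ml = NULL, lambda = 8,
                       air_fraction_at_pressure = NULL) {
  side <- match.arg(side)
  base <- .normal_lung_physio[[side]]
  mass_supplied <- !is.null(mass_g)
  mass_g <- if (is.null(mass_g)) base$mass_g else mass_g
  frc_ml <- if (is.null(frc_ml)) base$frc_ml else frc_ml
  tlc_ml <- if (is.null(tlc_ml)) base$tlc_ml else tlc_ml
  if (is.null(air_fraction_at_pressure))
    air_fraction_at_pressure <-
      lung_air_fractions(frc_ml, tlc_ml, mass_g, lambda = lambda)
  list(side = side, volume_scale = volume_scale,
       tissue_density_scale = tissue_density_scale, mass_g = mass_g,
       mass_supplied = mass_supplied,
       frc_ml = frc_ml, tlc_ml = tlc_ml,
       air_fraction_at_pressure = air_fraction_at_pressure)
}

#' Specification of a synthetic thorax phantom
#'
#' Describes a voxel thorax at four breath-hold pressures: grid geometry, the
#' true spine deformity (coronal and sagittal curvature plus apical axial
#' rotation), per-lung size/density/air-fraction parameters, the
#' anterior-posterior gradient of inflation, texture and noise levels, and
#' the RNG seed.  [generate_phantom()] renders the volumes and returns them
#' together with the exact ground truth.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing numeric length-3, mm per voxel.
#' @param theta_S_true,theta_K_true true coronal/sagittal Cobb angles of the
#'   rendered spine, degrees, in `[0, 150]`.
#' @param apical_rotation_true true trans-axial rotation at the curve apex,
#'   degrees.
#' @param lung_params list with `right` and `left` entries from
#'   [lung_param()].
#' @param ap_gradient anterior-posterior modulation of the inflation field:
#'   scalar, or named per-pressure vector; positive values make the
#'   posterior lung contract (hence, between pressures, expand) more.
#' @param tissue_texture_amp relative amplitude of the smooth parenchymal
#'   texture (0 disables it; the lungs are then homogeneous).
#' @param hu_noise_sd additive Gaussian CT noise, HU.
#' @param n_vertebrae number of vertebral landmarks generated.
#' @param seed integer RNG seed.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 96),
                         spacing = c(1.25, 1.25, 1.25),
                         theta_S_true = 0, theta_K_true = 0,
                         apical_rotation_true = 0,
                         lung_params = list(right = lung_param("right"),
                                            left = lung_param("left")),
                         ap_gradient = 0.2,
                         tissue_texture_amp = 0.2,
                         hu_noise_sd = 20,
                         n_vertebrae = 13,
                         seed = 1L) {
  spec <- structure(list(grid_shape = as.integer(grid_shape),
                         spacing = as.numeric(spacing),
                         theta_S_true = theta_S_true,
                         theta_K_true = theta_K_true,
                         apical_rotation_true = apical_rotation_true,
                         lung_params = lung_params,
                         ap_gradient = ap_gradient,
                         tissue_texture_amp = tissue_texture_amp,
                         hu_noise_sd = hu_noise_sd,
                         n_vertebrae = as.integer(n_vertebrae),
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$grid_shape < 16))
    stop("grid_shape must be at least 16 voxels per axis")
  for (nm in c("theta_S_true", "theta_K_true")) {
    v <- spec[[nm]]
    if (v < 0 || v > 150)
      stop(sprintf("%s must lie in [0, 150] degrees (got %.1f)", nm, v))
  }
  for (k in c("right", "left")) {
    lp <- spec$lung_params[[k]]
    fa <- lp$air_fraction_at_pressure
    p <- as.numeric(names(fa))
    if (any(diff(fa[order(p)]) <= 0))
      stop(sprintf("air fractions of the %s lung must strictly increase with pressure", k))
    if (any(fa <= 0) || any(fa >= 1))
      stop("air fractions must lie in (0, 1)")
    if (lp$volume_scale <= 0 || lp$tissue_density_scale <= 0)
      stop("volume_scale and tissue_density_scale must be positive")
  }
  invisible(spec)
}

# --- internal geometry ----------------------------------------------------

# Domain-proportional geometry: body envelope, spine curve with closed-form
# Cobb-matched sinusoidal amplitudes, and the two lung ellipsoids.
build_geometry <- function(spec) {
  dims <- spec$grid_shape
  sp <- spec$spacing
  L <- dims * sp
  cx0 <- L[1] / 2; cy0 <- L[2] / 2
  r_spine <- 0.05 * L[1]
  margin <- 0.0125 * L[1]
  a_max <- L[1] / 2 - r_spine - 3 * margin
  # curved-segment length shrinks for large angles so the sinusoidal arc
  # stays inside the grid (Cobb depends only on A*pi/L, not on A alone)
  amp_for <- function(theta, lseg) lseg / pi * tan(deg2rad(theta) / 2)
  l_seg <- 0.8 * L[3]
  a_s <- amp_for(spec$theta_S_true, l_seg)
  a_k <- amp_for(spec$theta_K_true, l_seg)
  if (max(a_s, a_k) > a_max) {
    l_seg <- l_seg * a_max / max(a_s, a_k)
    a_s <- amp_for(spec$theta_S_true, l_seg)
    a_k <- amp_for(spec$theta_K_true, l_seg)
  }
  if (l_seg < max(6 * r_spine, 0.3 * L[3]))
    stop(sprintf(paste0("spine curve cannot be accommodated by the grid: ",
                        "theta_S_true=%.1f / theta_K_true=%.1f too large for ",
                        "grid_shape %s"),
                 spec$theta_S_true, spec$theta_K_true,
                 paste(dims, collapse = "x")))
  if (a_s + r_spine + margin > L[1] / 2 - margin)
    stop("spine curve exits the grid laterally: theta_S_true too large")
  if (a_k + r_spine + margin > L[2] / 2 - margin)
    stop("spine curve exits the grid in the sagittal plane: theta_K_true too large")
  z0 <- (L[3] - l_seg) / 2
  z1 <- z0 + l_seg
  spine_xy <- function(z) {
    t <- pmin(pmax((z - z0) / (z1 - z0), 0), 1)
    cbind(cx0 + a_s * sinpi(t), cy0 + a_k * sinpi(t))
  }
  lungs <- list(
    right = list(center = c(0.3125 * L[1], 0.5 * L[2], 0.5 * L[3]),
                 semi = c(0.175 * L[1], 0.225 * L[2], 0.31 * L[3]),
                 side = "right"),
    left  = list(center = c(0.6875 * L[1], 0.5 * L[2], 0.5 * L[3]),
                 semi = c(0.1625 * L[1], 0.2125 * L[2], 0.2667 * L[3]),
                 side = "left"))
  for (k in names(lungs)) {
    vs <- spec$lung_params[[k]]$volume_scale
    lungs[[k]]$semi <- lungs[[k]]$semi * vs^(1 / 3)
  }
  list(dims = dims, spacing = sp, L = L,
       xs = (seq_len(dims[1]) - 0.5) * sp[1],
       ys = (seq_len(dims[2]) - 0.5) * sp[2],
       zs = (seq_len(dims[3]) - 0.5) * sp[3],
       body_center = c(cx0, cy0), body_semi = c(0.45 * L[1], 0.425 * L[2]),
       spine = list(z0 = z0, z1 = z1, a_s = a_s, a_k = a_k, r = r_spine,
                    xy = spine_xy, carve_pad = 2),
       midline = cx0, lungs = lungs)
}

# analytic ellipsoid volume of a lung region, mL
lung_analytic_volume_ml <- function(geom, k) {
  s <- geom$lungs[[k]]$semi
  4 / 3 * pi * prod(s) / 1000
}

# squared in-plane distance from every voxel to the spine axis, full grid
spine_dist2_array <- function(geom) {
  sxy <- geom$spine$xy(geom$zs)
  dx2 <- outer(geom$xs, sxy[, 1], function(a, b) (a - b)^2)  # nx x nz
  dy2 <- outer(geom$ys, sxy[, 2], function(a, b) (a - b)^2)  # ny x nz
  dims <- geom$dims
  out <- array(0, dims)
  for (k in seq_len(dims[3]))
    out[, , k] <- outer(dx2[, k], dy2[, k], "+")
  out
}

# ellipsoid "radius^2" field for one lung over the full grid
ellipsoid_field <- function(geom, k) {
  lg <- geom$lungs[[k]]
  ex <- ((geom$xs - lg$center[1]) / lg$semi[1])^2
  ey <- ((geom$ys - lg$center[2]) / lg$semi[2])^2
  ez <- ((geom$zs - lg$center[3]) / lg$semi[3])^2
  dims <- geom$dims
  out <- array(0, dims)
  eyz <- outer(ey, ez, "+")
  for (k3 in seq_len(dims[3]))
    out[, , k3] <- outer(ex, eyz[, k3], "+")
  out
}

# deterministic smooth parenchymal texture (vessel-like modulation) tied to
# material coordinates; phases drawn once per phantom.  Two incommensurate
# sinusoidal products so the gradient has no common nodal sheets: local
# image structure is available everywhere for registration.
texture_at <- function(pts, amp, phases, periods = c(14, 17, 20)) {
  if (amp == 0) return(rep(1, nrow(pts)))
  p2 <- periods * c(1.62, 1.38, 1.51)
  1 + amp * (sin(2 * pi * pts[, 1] / periods[1] + phases[1]) *
             sin(2 * pi * pts[, 2] / periods[2] + phases[2]) *
             sin(2 * pi * pts[, 3] / periods[3] + phases[3]) +
             sin(2 * pi * pts[, 1] / p2[1] + phases[2]) *
             sin(2 * pi * pts[, 2] / p2[2] + phases[3]) *
             sin(2 * pi * pts[, 3] / p2[3] + phases[1])) / 2
}

# --- analytic displacement fields ----------------------------------------

# Per-lung radial contraction about the lung centroid with a logistic
# left/right spatial weight (function of x only) and a linear
# anterior-posterior gain (function of y only).  This structure keeps the
# Jacobian determinant closed-form:
#   u(x) = sum_k a_k * w_k(x) * g_k(y) * (x - c_k)
# with dw/dz = dg/dz = 0, so column z of I + grad(u) is (0, 0, 1 + du_z/dz).
field_params <- function(geom, amplitudes, gammas) {
  tau <- 2.4 * geom$spacing[1]
  lapply(names(geom$lungs), function(k) {
    lg <- geom$lungs[[k]]
    list(c = lg$center, by = lg$semi[2], a = amplitudes[[k]],
         gamma = gammas[[k]], sgn = if (k == "right") 1 else -1,
         xm = geom$midline, tau = tau)
  })
}

# evaluate u (mm) and analytic Jacobian determinant at point matrix (N x 3)
eval_field <- function(pts, params, want_jac = TRUE) {
  n <- nrow(pts)
  ux <- uy <- uz <- numeric(n)
  if (want_jac) uxx <- uxy <- uyx <- uyy <- uzz <- numeric(n)
  for (p in params) {
    if (p$a == 0) next
    w <- stats::plogis(p$sgn * (p$xm - pts[, 1]) / p$tau)
    dw <- -p$sgn * w * (1 - w) / p$tau
    graw <- 1 + p$gamma * (pts[, 2] - p$c[2]) / p$by
    clampd <- graw < 0.2 | graw > 2
    g <- pmin(pmax(graw, 0.2), 2)
    dg <- ifelse(clampd, 0, p$gamma / p$by)
    awg <- p$a * w * g
    dxc <- pts[, 1] - p$c[1]
    dyc <- pts[, 2] - p$c[2]
    dzc <- pts[, 3] - p$c[3]
    ux <- ux + awg * dxc
    uy <- uy + awg * dyc
    uz <- uz + awg * dzc
    if (want_jac) {
      uxx <- uxx + p$a * (dw * g * dxc + w * g)
      uxy <- uxy + p$a * w * dg * dxc
      uyx <- uyx + p$a * dw * g * dyc
      uyy <- uyy + p$a * (w * dg * dyc + w * g)
      uzz <- uzz + awg
    }
  }
  out <- list(u = cbind(ux, uy, uz))
  if (want_jac)
    out$jac <- (1 + uzz) * ((1 + uxx) * (1 + uyy) - uxy * uyx)
  out
}

# invert y = x + u(x) by fixed-point iteration (the fields are contractive)
invert_field <- function(pts, params, iters = 14) {
  x <- pts
  for (i in seq_len(iters)) {
    u <- eval_field(x, params, want_jac = FALSE)$u
    x <- pts - u
  }
  x
}

# Calibrate per-lung contraction amplitudes so the mean analytic Jacobian
# over each (reference, TLC-frame) lung equals the target volume ratio
# G(P)/G(TLC).  Lungs are nearly decoupled (the logistic weight of the
# contralateral field is ~0 inside a lung); two relaxation sweeps suffice.
calibrate_amplitudes <- function(geom, refpts, ratios, gammas) {
  amps <- list(right = 0, left = 0)
  for (sweep in 1:2) {
    for (k in names(amps)) {
      target <- ratios[[k]]
      f <- function(a) {
        amps_try <- amps
        amps_try[[k]] <- a
        pars <- field_params(geom, amps_try, gammas)
        mean(eval_field(refpts[[k]], pars)$jac) - target
      }
      amps[[k]] <- stats::uniroot(f, c(-0.45, 0.05), tol = 1e-10)$root
    }
  }
  amps
}

# --- phantom generation ---------------------------------------------------

#' Generate a synthetic thorax phantom with ground truth
#'
#' Renders HU volumes at the requested breath-hold pressures.  The reference
#' configuration is total lung capacity (25 cmH2O); lower-pressure volumes
#' are produced by analytically contracting the lungs about their centroids
#' with an anterior-posterior gain, conserving tissue: the local density is
#' the reference tissue fraction divided by the (closed-form) Jacobian of
#' the contraction.  Lung voxels carry `HU = -1000 * air_fraction`, soft
#' tissue 0 HU, vertebral bone +700 HU, and optional additive Gaussian
#' noise.
#'
#' The returned ground truth stores exact per-lung masses and aerated
#' volumes, per-pressure lung label maps, vertebral landmarks, and for each
#' consecutive requested pressure pair a dense displacement field (defined
#' on the lower-pressure grid, mapping onto the higher-pressure image) with
#' its analytic Jacobian.
#'
#' @param spec a [phantom_spec()].
#' @param pressures subset of `c(0, 5, 15, 25)` to render (25 is the
#'   reference and costs least).
#' @return list of class `thorax_phantom` with elements `volumes` (named
#'   list of [ct_volume()]), `truth` (ground-truth list) and `spec`.
#' @export
generate_phantom <- function(spec, pressures = c(0, 5, 15, 25)) {
  validate_phantom_spec(spec)
  stopifnot(all(pressures %in% c(0, 5, 15, 25)), length(pressures) >= 1)
  pressures <- sort(unique(pressures))
  geom <- build_geometry(spec)
  dims <- geom$dims
  vpix <- prod(geom$spacing) / 1000  # mL

  with_seed(spec$seed, {
    phases <- stats::runif(3, 0, 2 * pi)
    noise <- if (spec$hu_noise_sd > 0)
      lapply(pressures, function(p)
        array(stats::rnorm(prod(dims), 0, spec$hu_noise_sd), dims))
    else NULL
  })

  # reference-frame (TLC) structures.  The spine corridor is carved out of
  # the lung regions, which would silently shrink them below the volume
  # implied by volume_scale (and asymmetrically: the spine bulges towards
  # the left lung), so the semi-axes are re-calibrated once against the
  # carved, discretised region volume.
  spine_d2 <- spine_dist2_array(geom)
  carve_r2 <- (geom$spine$r + geom$spine$carve_pad)^2
  spine_mask <- spine_d2 <= geom$spine$r^2
  build_labels <- function() {
    lab <- array(0L, dims)
    for (k in c("left", "right")) {
      inside <- ellipsoid_field(geom, k) <= 1 & spine_d2 > carve_r2
      lab[inside] <- if (k == "left") 1L else 2L
    }
    lab
  }
  targets <- lapply(geom$lungs, function(lg) 4 / 3 * pi * prod(lg$semi) / 1000)
  ref_label <- build_labels()
  for (it in 1:3) {
    for (k in c("left", "right")) {
      actual <- sum(ref_label == (if (k == "left") 1L else 2L)) * vpix
      geom$lungs[[k]]$semi <- geom$lungs[[k]]$semi *
        (targets[[k]] / actual)^(1 / 3)
    }
    ref_label <- build_labels()
  }
  # per-lung reference voxel coordinates, texture integrals, exact masses
  grid_pts <- function(idx) {
    ijk <- arrayInd(idx, dims)
    cbind(geom$xs[ijk[, 1]], geom$ys[ijk[, 2]], geom$zs[ijk[, 3]])
  }
  ref <- list()
  for (k in c("right", "left")) {
    lab <- if (k == "left") 1L else 2L
    idx <- which(ref_label == lab)
    pts <- grid_pts(idx)
    tex <- texture_at(pts, spec$tissue_texture_amp, phases)
    g25 <- length(idx) * vpix
    lp <- spec$lung_params[[k]]
    fa <- lp$air_fraction_at_pressure
    fa25 <- fa[["25"]]
    mass <- if (isTRUE(lp$mass_supplied))
      lp$mass_g * lp$tissue_density_scale
    else (1 - fa25) * g25 * lp$tissue_density_scale
    # exact scaling: sum(ft * vpix) == mass
    ft_scale <- mass / (sum(tex) * vpix)
    # implied density scale folds the mass target into the air-fraction
    # schedule so G(P) = mass / (1 - fa_eff(P))
    tds_eff <- mass / ((1 - fa25) * g25)
    fa_eff <- 1 - tds_eff * (1 - fa)
    if (any(fa_eff <= 0) || any(fa_eff >= 1))
      stop(sprintf("infeasible air-fraction/mass combination for %s lung", k))
    gP <- mass / (1 - fa_eff)
    ref[[k]] <- list(idx = idx, pts = pts, tex = tex, g25 = g25,
                     mass = mass, ft_scale = ft_scale,
                     gP = gP, ratios = gP / g25)
  }
  if (max(ref$right$ft_scale * (1 + spec$tissue_texture_amp),
          ref$left$ft_scale * (1 + spec$tissue_texture_amp)) >= 0.95)
    stop("tissue fraction approaches 1; reduce mass or texture amplitude")

  gammas_for <- function(p) {
    g <- spec$ap_gradient
    if (length(g) > 1) g <- unname(g[[as.character(p)]])
    list(right = g, left = g)
  }

  lower <- setdiff(pressures, 25)
  amps <- list()  # per pressure, per lung
  for (p in lower) {
    ratios <- list(right = ref$right$ratios[[as.character(p)]],
                   left = ref$left$ratios[[as.character(p)]])
    amps[[as.character(p)]] <- calibrate_amplitudes(
      geom, list(right = ref$right$pts, left = ref$left$pts),
      ratios, gammas_for(p))
  }

  # candidate voxels for rendering deformed lungs: lung bounding box
  # dilated by the maximum displacement
  ref_idx_all <- c(ref$right$idx, ref$left$idx)
  ijk_all <- arrayInd(ref_idx_all, dims)
  maxdisp <- 0
  for (p in lower) {
    pars <- field_params(geom, amps[[as.character(p)]], gammas_for(p))
    u <- eval_field(rbind(ref$right$pts, ref$left$pts), pars,
                    want_jac = FALSE)$u
    maxdisp <- max(maxdisp, max(abs(u)))
  }
  pad <- ceiling(maxdisp / geom$spacing) + 2
  lo <- pmax(apply(ijk_all, 2, min) - pad, 1)
  hi <- pmin(apply(ijk_all, 2, max) + pad, dims)
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                k = lo[3]:hi[3]))
  cand_idx <- cand[, 1] + dims[1] * (cand[, 2] - 1 + dims[2] * (cand[, 3] - 1))
  cand_pts <- cbind(geom$xs[cand[, 1]], geom$ys[cand[, 2]], geom$zs[cand[, 3]])

  body <- outer(((geom$xs - geom$body_center[1]) / geom$body_semi[1])^2,
                ((geom$ys - geom$body_center[2]) / geom$body_semi[2])^2,
                "+") <= 1
  body3 <- array(body, dims)  # recycled along z

  ell <- list(right = geom$lungs$right, left = geom$lungs$left)
  in_lung_ref <- function(x, k) {
    lg <- ell[[k]]
    e <- ((x[, 1] - lg$center[1]) / lg$semi[1])^2 +
         ((x[, 2] - lg$center[2]) / lg$semi[2])^2 +
         ((x[, 3] - lg$center[3]) / lg$semi[3])^2
    sxy <- geom$spine$xy(x[, 3])
    d2 <- (x[, 1] - sxy[, 1])^2 + (x[, 2] - sxy[, 2])^2
    e <= 1 & d2 > carve_r2
  }
  ft_at <- function(x, k)
    ref[[k]]$ft_scale * texture_at(x, spec$tissue_texture_amp, phases)

  volumes <- list()
  labels <- list()
  xref_store <- list()   # material coordinates per candidate voxel
  jac_store <- list()
  for (p in pressures) {
    key <- as.character(p)
    if (p == 25) {
      xr <- cand_pts
      jc <- rep(1, nrow(cand_pts))
    } else {
      pars <- field_params(geom, amps[[key]], gammas_for(p))
      xr <- invert_field(cand_pts, pars)
      jc <- eval_field(xr, pars)$jac
    }
    hu <- array(-1000, dims)
    hu[body3] <- 0
    lab <- array(0L, dims)
    for (k in c("left", "right")) {
      sel <- in_lung_ref(xr, k)
      mu <- pmin(ft_at(xr[sel, , drop = FALSE], k) / jc[sel], 1)
      hu[cand_idx[sel]] <- -1000 * (1 - mu)
      lab[cand_idx[sel]] <- if (k == "left") 1L else 2L
    }
    hu[spine_mask] <- 700
    lab[spine_mask] <- 0L
    if (!is.null(noise)) hu <- hu + noise[[match(p, pressures)]]
    volumes[[key]] <- ct_volume(hu, geom$spacing, pressure = p)
    labels[[key]] <- lab
    xref_store[[key]] <- xr
    jac_store[[key]] <- jc
  }

  # ground-truth step fields between consecutive rendered pressures
  steps <- list()
  all_p <- pressures
  for (i in seq_len(length(all_p) - 1)) {
    pl <- all_p[i]; ph <- all_p[i + 1]
    kl <- as.character(pl); kh <- as.character(ph)
    xr <- xref_store[[kl]]            # material coords on the lower grid
    if (ph == 25) {
      uh <- matrix(0, nrow(xr), 3)
      jh <- rep(1, nrow(xr))
    } else {
      parsh <- field_params(geom, amps[[kh]], gammas_for(ph))
      fh <- eval_field(xr, parsh)
      uh <- fh$u; jh <- fh$jac
    }
    ustep <- xr + uh - cand_pts       # mm, lower grid -> higher image
    jstep <- jh / jac_store[[kl]]
    u4 <- array(0, c(dims, 3))
    j3 <- array(1, dims)
    nvox <- prod(dims)
    in_lung <- labels[[kl]][cand_idx] > 0L
    for (d in 1:3)
      u4[cand_idx[in_lung] + (d - 1) * nvox] <- ustep[in_lung, d]
    j3[cand_idx[in_lung]] <- jstep[in_lung]
    if (any(jstep[in_lung] <= 0.1))
      warning("ground-truth step Jacobian fell below 0.1 inside a lung")
    steps[[paste0(pl, "->", ph)]] <- list(
      field = disp_field(u4, geom$spacing, fixed_pressure = pl,
                         moving_pressure = ph),
      jacobian = j3)
  }

  # vertebral landmarks on the spine curve
  nv <- spec$n_vertebrae
  tt <- seq(0, 1, length.out = nv)
  zv <- geom$spine$z0 + tt * (geom$spine$z1 - geom$spine$z0)
  sxy <- geom$spine$xy(zv)
  landmarks <- spine_annotation(
    cbind(sxy[, 1], sxy[, 2], zv),
    axial_rotation = spec$apical_rotation_true * sinpi(tt))

  air <- sapply(c("right", "left"), function(k)
    ref[[k]]$gP[as.character(pressures)] - ref[[k]]$mass)
  air <- matrix(air, nrow = length(pressures),
                dimnames = list(as.character(pressures), c("right", "left")))
  truth <- list(
    true_masses = c(right = ref$right$mass, left = ref$left$mass),
    true_air_volumes_ml = air,
    geometric_volumes_ml = sapply(ref, function(r) r$gP[as.character(pressures)]),
    ref_label = ref_label,
    labels = labels,
    step_fields = steps,
    landmarks = landmarks,
    amplitudes = amps)
  structure(list(volumes = volumes, truth = truth, spec = spec,
                 geometry = geom),
            class = "thorax_phantom")
}

#' @export
print.thorax_phantom <- function(x, ...) {
  cat(sprintf(
    "<thorax_phantom> pressures %s cmH2O, grid %s, theta_S %.0f / theta_K %.0f deg\n",
    paste(names(x$volumes), collapse = "/"),
    paste(dim(x$volumes[[1]]$data), collapse = "x"),
    x$spec$theta_S_true, x$spec$theta_K_true))
  cat(sprintf("  true masses: right %.2f g, left %.2f g\n",
              x$truth$true_masses["right"], x$truth$true_masses["left"]))
  invisible(x)
}
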