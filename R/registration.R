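#' Deformable registration between breath-hold volumes
#'
#' Multi-resolution intensity-driven (demons-type) deformable registration
#' with Gaussian fluid/diffusion regularisation.  The fixed image is the
#' lower-pressure volume; the returned displacement field lives on its grid
#' and maps each fixed voxel onto the corresponding tissue position in the
#' moving (higher-pressure) image.  Because lung attenuation drops as the
#' lung inflates, moving-image intensities are first linearly rescaled so
#' that the aerated-voxel intensity distribution matches the fixed image;
#' the demons forces then act on the (mass-advected) parenchymal texture.
#'
#' @param fixed,moving [ct_volume()]s on the same grid, `fixed` at the lower
#'   pressure.
#' @param mask optional [segment_lungs()] mask on the fixed grid; used for
#'   the convergence metric (registration itself is dense).
#' @param levels number of resolution levels.
#' @param iterations iterations per level, coarse to fine.
#' @param sigma_fluid,sigma_diff Gaussian SD (voxels) applied to the update
#'   and to the accumulated field.
#' @param max_step largest update per iteration, voxels.
#' @param tol early-stop threshold on the relative improvement of the mean
#'   absolute intensity residual.
#' @param diff_weight blending weight of the field-diffusion step: 1
#'   applies full Gaussian smoothing of the accumulated field each
#'   iteration, smaller values damp the smoothing and preserve large-scale
#'   deformation.
#' @param compositive if `TRUE` (default), updates are composed into the
#'   field (`u <- u o (id+dv) + dv`) rather than added, which transports
#'   the accumulated field correctly under large expansions.
#' @param mass_preserving if `TRUE` (default), images are compared in
#'   tissue-density units with the warped moving density multiplied by the
#'   Jacobian of the current field, so that inflation-induced attenuation
#'   change is explained by the deformation itself rather than fought as an
#'   intensity mismatch.  If `FALSE`, a global linear intensity match over
#'   aerated voxels is used instead.
#' @param min_iter minimum iterations per level before early stopping may
#'   trigger.
#' @param rim_weight strength (0-1) of the suppression of demons forces in
#'   the partial-volume shell at the lung boundary (0 disables it).
#' @param metric `"lncc"` (default) computes demons forces on locally
#'   mean-removed, variance-normalised images, which makes the match
#'   invariant to the smooth intensity gain that lung inflation induces;
#'   `"ssd"` uses the raw (density or intensity) images.
#' @param lncc_sigma Gaussian window SD (voxels) of the local
#'   normalisation.
#' @param final_smooth Gaussian SD (voxels) of a single smoothing of the
#'   converged field before it is returned (0 disables it).
#' @param init `"similarity"` (default) seeds the field with a per-lung
#'   similarity transform matching each lung's centroid and spread between
#'   the two segmentations before the intensity-driven stage; `"none"`
#'   starts from zero.
#' @param moving_mask optional [segment_lungs()] mask of the moving image
#'   for the initialisation; segmented on the fly when omitted.
#' @return a [disp_field()]; `$info` carries the residual trace and a
#'   `converged` flag.
#' @export
register <- function(fixed, moving, mask = NULL, levels = 3,
                     iterations = c(200, 150, 120), sigma_fluid = 2,
                     sigma_diff = 1.2, max_step = 2, tol = 1e-4,
                     mass_preserving = TRUE, compositive = TRUE,
                     diff_weight = 1, init = c("similarity", "none"),
                     moving_mask = NULL, min_iter = 120,
                     rim_weight = 0, metric = c("lncc", "ssd"),
                     lncc_sigma = 2, final_smooth = 0) {
  metric <- match.arg(metric)
  init <- match.arg(init)
  # Jacobian compensation applies to raw densities only; the locally
  # normalised images are already gain-invariant
  compensate <- mass_preserving && metric == "ssd"
  stopifnot(inherits(fixed, "ct_volume"), inherits(moving, "ct_volume"))
  if (!all(dim(fixed$data) == dim(moving$data)))
    stop("fixed and moving volumes must share one grid")
  if (!isTRUE(all.equal(fixed$spacing, moving$spacing)))
    stop("fixed and moving volumes must share voxel spacing")
  if (length(iterations) == 1) iterations <- rep(iterations, levels)
  stopifnot(length(iterations) == levels)

  if (mass_preserving) {
    # work on tissue density mu = 1 + HU/1000 (air 0, water 1)
    f <- pmax(1 + fixed$data / 1000, 0)
    m <- pmax(1 + moving$data / 1000, 0)
  } else {
    f <- fixed$data
    m <- moving$data
    # linear intensity normalisation over aerated voxels
    af <- f[f < -300]; am <- m[m < -300]
    if (length(af) > 100 && length(am) > 100 && stats::sd(am) > 0) {
      m <- (m - mean(am)) / stats::sd(am) * stats::sd(af) + mean(af)
    }
    iscale <- diff(range(f))
    if (iscale > 0) { f <- f / iscale; m <- m / iscale }
  }

  dims <- dim(f)
  # resolution pyramid (coarsest first)
  pyr_dims <- lapply(rev(seq_len(levels) - 1), function(l)
    pmax(dims %/% (2^l), 8))
  metric_mask <- if (!is.null(mask)) mask$label > 0L else fixed$data < -300

  # per-structure similarity initialisation from the two segmentations:
  # match each lung's centroid and per-axis spread, blend the per-lung
  # affine displacements with smoothed membership weights so the field
  # decays to zero outside the lungs.  Leaves the intensity-driven stage
  # only the sub-voxel residual deformation.
  u_init <- NULL
  if (init == "similarity" && !is.null(mask)) {
    mmask <- moving_mask
    if (is.null(mmask))
      mmask <- tryCatch(segment_lungs(moving), error = function(e) NULL)
    if (!is.null(mmask)) {
      u_init <- list(x = array(0, dims), y = array(0, dims),
                     z = array(0, dims))
      wsum <- array(1e-6, dims)
      ijk_all <- arrayInd(seq_len(prod(dims)), dims)
      for (k in c(1L, 2L)) {
        if_ <- which(mask$label == k)
        im_ <- which(mmask$label == k)
        if (length(if_) < 50 || length(im_) < 50) next
        pf <- arrayInd(if_, dims)
        pm <- arrayInd(im_, dims)
        cf <- colMeans(pf); cm <- colMeans(pm)
        s <- apply(pm, 2, stats::sd) / pmax(apply(pf, 2, stats::sd), 1e-6)
        w <- array(0, dims)
        w[if_] <- 1
        w <- gauss_smooth(w, 3)
        for (d in 1:3) {
          ud <- (cm[d] + s[d] * (ijk_all[, d] - cf[d])) - ijk_all[, d]
          u_init[[d]] <- u_init[[d]] + w * array(ud, dims)
        }
        wsum <- wsum + w
      }
      # full affine displacement inside each lung, smooth decay outside
      envelope <- pmin(2 * wsum, 1)
      for (d in 1:3) u_init[[d]] <- u_init[[d]] / wsum * envelope
    }
  }

  u <- NULL  # components in voxels, list(x=,y=,z=)
  trace <- numeric(0)
  converged <- TRUE
  for (li in seq_len(levels)) {
    d <- pyr_dims[[li]]
    fl <- if (all(d == dims)) f else resample_volume(f, d)
    ml <- if (all(d == dims)) m else resample_volume(m, d)
    mm <- if (all(d == dims)) metric_mask else
      resample_volume(metric_mask * 1, d) > 0.5
    if (metric == "lncc") {
      # locally zero-mean, unit-variance images; the variance floor keeps
      # featureless (noise-only) regions from being amplified
      mu_f <- gauss_smooth(fl, lncc_sigma)
      vf <- pmax(gauss_smooth(fl^2, lncc_sigma) - mu_f^2, 0)
      tau2 <- (0.5 * sqrt(stats::median(vf[mm])))^2
      fl <- (fl - mu_f) / sqrt(vf + tau2)
      mu_m <- gauss_smooth(ml, lncc_sigma)
      vm <- pmax(gauss_smooth(ml^2, lncc_sigma) - mu_m^2, 0)
      ml <- (ml - mu_m) / sqrt(vm + tau2)
    }
    if (is.null(u)) {
      u <- if (is.null(u_init))
        list(x = array(0, d), y = array(0, d), z = array(0, d))
      else
        stats::setNames(lapply(1:3, function(i)
          resample_volume(u_init[[i]], d) * (d[i] / dims[i])),
          c("x", "y", "z"))
    } else {
      prev <- dim(u$x)
      u <- lapply(seq_along(u), function(i)
        resample_volume(u[[i]], d) * (d[i] / prev[i]))
      names(u) <- c("x", "y", "z")
    }
    gf <- gradient3(fl)
    # down-weight demons forces in the partial-volume shell at the lung
    # edge: the density model (and its Jacobian compensation) is invalid
    # across the tissue/air jump, and boundary alignment is already driven
    # by the initialisation and the coarse levels
    edge <- gauss_smooth(mm * 1, 1.5)
    w_force <- 1 - 4 * edge * (1 - edge) * rim_weight
    best <- Inf
    stall <- 0L
    patience <- 15L
    for (it in seq_len(iterations[li])) {
      mw <- warp_volume(ml, u$x, u$y, u$z)
      if (compensate)
        mw <- mw * pmax(jacobian_det_vox(u$x, u$y, u$z), 0)
      diffim <- fl - mw
      gm <- gradient3(mw)
      gx <- 0.5 * (gf$x + gm$x); gy <- 0.5 * (gf$y + gm$y)
      gz <- 0.5 * (gf$z + gm$z)
      g2 <- gx^2 + gy^2 + gz^2
      denom <- g2 + diffim^2
      denom[denom < 1e-8] <- Inf
      fac <- w_force * diffim / denom
      dvx <- fac * gx; dvy <- fac * gy; dvz <- fac * gz
      mag <- sqrt(dvx^2 + dvy^2 + dvz^2)
      sc <- pmin(1, max_step / pmax(mag, 1e-12))
      dvx <- dvx * sc; dvy <- dvy * sc; dvz <- dvz * sc
      if (sigma_fluid > 0) {
        dvx <- gauss_smooth(dvx, sigma_fluid)
        dvy <- gauss_smooth(dvy, sigma_fluid)
        dvz <- gauss_smooth(dvz, sigma_fluid)
      }
      if (compositive) {
        # u <- u o (id + dv) + dv : update composed into the field
        u <- list(x = warp_volume(u$x, dvx, dvy, dvz) + dvx,
                  y = warp_volume(u$y, dvx, dvy, dvz) + dvy,
                  z = warp_volume(u$z, dvx, dvy, dvz) + dvz)
      } else {
        u$x <- u$x + dvx; u$y <- u$y + dvy; u$z <- u$z + dvz
      }
      if (sigma_diff > 0) {
        # damped diffusion: blend toward the smoothed field instead of
        # replacing it, so repeated regularisation suppresses high-frequency
        # noise without eroding the large-scale deformation
        u$x <- (1 - diff_weight) * u$x +
          diff_weight * gauss_smooth(u$x, sigma_diff)
        u$y <- (1 - diff_weight) * u$y +
          diff_weight * gauss_smooth(u$y, sigma_diff)
        u$z <- (1 - diff_weight) * u$z +
          diff_weight * gauss_smooth(u$z, sigma_diff)
      }
      res <- mean(abs(diffim[mm]))
      trace <- c(trace, res)
      if (res < best * (1 - tol)) {
        best <- res
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience && it >= min_iter) break
      }
    }
    if (li == levels && stall < patience && iterations[li] > 0)
      converged <- FALSE
  }
  # one-shot smoothing of the converged field: suppresses texture-scale
  # estimation noise while leaving the lung-scale deformation (and hence
  # the recovered volume change) essentially untouched
  if (final_smooth > 0)
    for (i in 1:3) u[[i]] <- gauss_smooth(u[[i]], final_smooth)
  # to mm on the full grid
  u4 <- array(0, c(dims, 3))
  for (i in 1:3) {
    ui <- if (all(dim(u[[i]]) == dims)) u[[i]] else {
      prev <- dim(u$x)
      resample_volume(u[[i]], dims) * (dims[i] / prev[i])
    }
    u4[, , , i] <- ui * fixed$spacing[i]
  }
  disp_field(u4, fixed$spacing, fixed_pressure = fixed$pressure,
             moving_pressure = moving$pressure,
             info = list(residual_trace = trace, converged = converged))
}

#' Local specific volume (sVol) from a displacement field
#'
#' The Jacobian determinant `J` of the mapping `phi(x) = x + u(x)` is
#' evaluated by central finite differences on the fixed (lower-pressure)
#' grid, one-sided at the volume faces.  The local specific volume is
#' `sVol = J - 1`: the fractional volume expansion of the tissue in each
#' fixed-grid voxel between the two breath-hold pressures.  Voxels with
#' non-positive Jacobian (folding) are set to `NA` and counted.
#'
#' @param field a [disp_field()].
#' @param mask a [segment_lungs()] mask on the fixed grid.
#' @return object of class `svol_map`: `svol` array (`NA` outside the lung
#'   mask and at folded voxels), `jacobian`, `mask`, pressures, and
#'   `n_nonpositive`.
#' @export
specific_volume <- function(field, mask) {
  stopifnot(inherits(field, "disp_field"), inherits(mask, "lung_mask"))
  dims <- dim(field$u)[1:3]
  if (!all(dims == dim(mask$label)))
    stop("mask is not aligned to the displacement field")
  jac <- jacobian_det_vox(field$u[, , , 1] / field$spacing[1],
                          field$u[, , , 2] / field$spacing[2],
                          field$u[, , , 3] / field$spacing[3],
                          mask = mask$label > 0L)
  sv <- jac - 1
  inlung <- mask$label > 0L
  bad <- inlung & jac <= 0
  n_bad <- sum(bad)
  if (n_bad > 0)
    message(sprintf("%d lung voxels with non-positive Jacobian set to NA", n_bad))
  sv[!inlung] <- NA_real_
  sv[bad] <- NA_real_
  structure(list(svol = sv, jacobian = jac, mask = mask,
                 fixed_pressure = field$fixed_pressure,
                 moving_pressure = field$moving_pressure,
                 n_nonpositive = n_bad),
            class = "svol_map")
}

#' @export
print.svol_map <- function(x, ...) {
  cat(sprintf("<svol_map> %s -> %s cmH2O, mean sVol %.3f (lung)\n",
              format(x$fixed_pressure), format(x$moving_pressure),
              mean(x$svol, na.rm = TRUE)))
  invisible(x)
}

#' Mass-conservation check of a registration
#'
#' Compares the total lung volume change implied by the sVol map
#' (`sum(sVol * V_voxel)` over the lower-pressure lung) with the change
#' measured independently from the segmented images.  Lung volumes may be
#' passed as [segment_lungs()] masks (geometric volume = voxel count) or as
#' numbers in mL (e.g. tissue + air from densitometry).
#'
#' @param svol an [specific_volume()] map.
#' @param vol_low,vol_high lung volumes at the two pressures: `lung_mask`
#'   objects or numeric mL.
#' @param tol relative discrepancy regarded as passing.
#' @return list of class `conservation_report`.
#' @export
validate_conservation <- function(svol, vol_low, vol_high, tol = 0.05) {
  stopifnot(inherits(svol, "svol_map"))
  as_ml <- function(v)
    if (inherits(v, "lung_mask")) sum(v$label > 0L) * v$voxel_volume_ml
    else as.numeric(v)
  v_lo <- as_ml(vol_low); v_hi <- as_ml(vol_high)
  vpix <- svol$mask$voxel_volume_ml
  delta_svol <- sum(svol$svol, na.rm = TRUE) * vpix
  delta_seg <- v_hi - v_lo
  abs_disc <- delta_svol - delta_seg
  rel_disc <- if (delta_seg != 0) abs_disc / delta_seg else
    ifelse(abs(abs_disc) < 1e-9, 0, Inf)
  structure(list(delta_svol_ml = delta_svol, delta_seg_ml = delta_seg,
                 abs_discrepancy_ml = abs_disc,
                 rel_discrepancy = rel_disc,
                 pass = abs(rel_disc) <= tol, tol = tol),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf(
    "<conservation_report> sVol integral %.2f mL vs segmented dV %.2f mL (%.1f%%) -> %s\n",
    x$delta_svol_ml, x$delta_seg_ml, 100 * x$rel_discrepancy,
    if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Regional specific-volume analysis
#'
#' Bins the sVol map into equal-thickness slabs along the anterior-posterior
#' (gravity) axis and summarises per-lung and apex/base means.  The
#' anterior/posterior halves split at the lung mask's volumetric median
#' along y, apex/base at the volumetric median along z (apex cranial).  The
#' posterior-to-anterior ratio is the mean sVol over the posterior-half
#' voxels over that of the anterior half (computed over voxels, not bin
#' means, so it is independent of the bin count); the left-to-right ratio
#' is the ratio of whole-lung mean sVol.
#'
#' @param svol an [specific_volume()] map.
#' @param n_bins number of anterior-posterior bins.
#' @return object of class `regional_svol` with `bins` (data.frame),
#'   `lung_means`, `apex_base`, `posterior_to_anterior_ratio`,
#'   `left_to_right_ratio`.
#' @export
regional_analysis <- function(svol, n_bins = 10) {
  stopifnot(inherits(svol, "svol_map"))
  mask <- svol$mask
  dims <- dim(mask$label)
  idx <- which(mask$label > 0L & !is.na(svol$svol))
  if (length(idx) == 0) stop("no usable lung voxels in the sVol map")
  ijk <- arrayInd(idx, dims)
  vals <- svol$svol[idx]
  ymm <- (ijk[, 2] - 0.5) * mask$spacing[2]
  zmm <- (ijk[, 3] - 0.5) * mask$spacing[3]
  yr <- range(ymm)
  edges <- seq(yr[1] - 1e-9, yr[2] + 1e-9, length.out = n_bins + 1)
  bin <- cut(ymm, edges, labels = FALSE)
  bin_mean <- tapply(vals, factor(bin, levels = seq_len(n_bins)), mean)
  bin_n <- tapply(vals, factor(bin, levels = seq_len(n_bins)), length)
  bin_n[is.na(bin_n)] <- 0
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  y_med <- stats::median(ymm)
  z_med <- stats::median(zmm)
  # half means over voxels (not over bin means) so the ratio does not
  # depend on the bin count
  pa_ratio <- mean(vals[ymm > y_med]) / mean(vals[ymm <= y_med])
  lung_means <- c(left = mean(vals[mask$label[idx] == 1L]),
                  right = mean(vals[mask$label[idx] == 2L]))
  apex_base <- c(apex = mean(vals[zmm > z_med]),
                 base = mean(vals[zmm <= z_med]))
  structure(list(
    bins = data.frame(bin = seq_len(n_bins), y_center_mm = centers,
                      mean_svol = as.numeric(bin_mean),
                      n_voxels = as.integer(bin_n)),
    lung_means = lung_means, apex_base = apex_base,
    posterior_to_anterior_ratio = unname(pa_ratio),
    left_to_right_ratio = unname(lung_means["left"] / lung_means["right"]),
    n_bins = n_bins),
    class = "regional_svol")
}

#' @export
print.regional_svol <- function(x, ...) {
  cat(sprintf(
    "<regional_svol> %d bins; P:A ratio %.2f; L:R ratio %.2f; apex %.3f / base %.3f\n",
    x$n_bins, x$posterior_to_anterior_ratio, x$left_to_right_ratio,
    x$apex_base["apex"], x$apex_base["base"]))
  invisible(x)
}

#' Crop a volume pair to the lung bounding box
#'
#' Restricts a fixed/moving volume pair and the fixed-grid lung mask to the
#' bounding box of the lungs plus a padding margin.  Registration cost
#' scales with voxel count, and everything outside the thorax is static, so
#' cropping substantially speeds up [register()] without changing its
#' result inside the lungs.
#'
#' @param fixed,moving [ct_volume()]s on one grid.
#' @param mask a [segment_lungs()] mask on the fixed grid.
#' @param pad margin in voxels around the lung bounding box.
#' @return list with cropped `fixed`, `moving`, `mask` and the `bbox`
#'   (2 x 3 matrix of index ranges into the original grid).
#' @export
crop_to_lungs <- function(fixed, moving, mask, pad = 8) {
  stopifnot(inherits(mask, "lung_mask"))
  dims <- dim(mask$label)
  idx <- which(mask$label > 0L)
  ijk <- arrayInd(idx, dims)
  lo <- pmax(apply(ijk, 2, min) - pad, 1)
  hi <- pmin(apply(ijk, 2, max) + pad, dims)
  sl <- lapply(1:3, function(d) lo[d]:hi[d])
  crop <- function(a) a[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
  list(fixed = ct_volume(crop(fixed$data), fixed$spacing, fixed$pressure),
       moving = ct_volume(crop(moving$data), moving$spacing,
                          moving$pressure),
       mask = structure(list(label = crop(mask$label),
                             voxel_volume_ml = mask$voxel_volume_ml,
                             spacing = mask$spacing, flag = mask$flag),
                        class = "lung_mask"),
       bbox = rbind(lo, hi))
}
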