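#' Lung segmentation by HU thresholding
#'
#' Segments aerated lung from an HU volume: voxels below `threshold` inside
#' the body envelope (the largest connected non-air region) are lung
#' candidates; connected components smaller than `min_volume_ml` are
#' discarded; the remainder is split into right and left lungs by the
#' mid-sagittal surface through the spine centroid line (estimated from
#' bone voxels per slice, falling back to the volume midline).
#'
#' @param image a [ct_volume()].
#' @param threshold lung HU threshold (voxels strictly below are aerated).
#' @param min_volume_ml minimum connected-component volume retained, mL.
#' @param bone_hu HU above which voxels are treated as bone for the spine
#'   centroid estimate.
#' @return object of class `lung_mask`: integer label array (0 background,
#'   1 left, 2 right) plus `voxel_volume_ml` and `spacing`.
#' @export
segment_lungs <- function(image, threshold = -300, min_volume_ml = 0.1,
                          bone_hu = 300) {
  stopifnot(inherits(image, "ct_volume"))
  hu <- image$data
  dims <- dim(hu)
  vpix <- voxel_volume_ml(image)
  # filled body envelope: everything that is not exterior air (air-range
  # components touching the volume boundary); the lungs are interior holes
  airish <- hu < -500
  lab_air <- label_components(airish)
  edge_labs <- unique(c(lab_air[c(1, dims[1]), , ], lab_air[, c(1, dims[2]), ],
                        lab_air[, , c(1, dims[3])]))
  edge_labs <- setdiff(edge_labs, 0L)
  body <- !(airish & array(lab_air %in% edge_labs, dims))
  cand <- hu < threshold & body
  if (!any(cand))
    stop("no aerated lung found (no voxels below threshold inside the body)")
  lab <- label_components(cand)
  keep <- which(tabulate(lab[lab > 0L]) * vpix >= min_volume_ml)
  if (length(keep) == 0L)
    stop("no aerated lung found (all candidate components below minimum volume)")
  lung <- array(lab %in% keep, dims)
  label <- array(0L, dims)
  if (length(keep) >= 2) {
    # the lungs are disjoint components separated by the mediastinum:
    # assign each component to the side of its centroid (x runs right to
    # left)
    comp_x <- vapply(keep, function(cc)
      mean(arrayInd(which(lab == cc), dims)[, 1]), numeric(1))
    # the divide sits between the two dominant components' centroids
    two <- keep[order(-vapply(keep, function(cc) sum(lab == cc),
                              numeric(1)))[1:2]]
    divide <- mean(comp_x[match(two, keep)])
    for (ci in seq_along(keep)) {
      side <- if (comp_x[ci] < divide) 2L else 1L
      label[lab == keep[ci]] <- side
    }
  } else {
    # single connected region: split by the mid-sagittal surface through
    # the spine centroid line (bone voxels per slice)
    xs <- seq_len(dims[1])
    split_x <- rep(dims[1] / 2 + 0.5, dims[3])
    bone <- hu > bone_hu
    if (any(bone)) {
      for (k in seq_len(dims[3])) {
        sl <- bone[, , k]
        if (any(sl)) split_x[k] <- mean(xs[row(sl)[sl]])
      }
    }
    ksl <- slice.index(lung, 3)
    isl <- slice.index(lung, 1)
    right <- lung & (isl < array(split_x[ksl], dims))
    label[lung] <- 1L
    label[right] <- 2L
  }
  n_right <- sum(label == 2L)
  n_left <- sum(label == 1L)
  flag <- NULL
  if (n_right == 0L) flag <- "right lung empty"
  if (n_left == 0L) flag <- c(flag, "left lung empty")
  structure(list(label = label, voxel_volume_ml = vpix,
                 spacing = image$spacing, flag = flag),
            class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask> left %.1f mL, right %.1f mL%s\n",
              sum(x$label == 1L) * x$voxel_volume_ml,
              sum(x$label == 2L) * x$voxel_volume_ml,
              if (is.null(x$flag)) "" else
                paste0(" [", paste(x$flag, collapse = "; "), "]")))
  invisible(x)
}

# clamp HU inside lung masks before densitometric sums; voxels below
# -1000 HU (non-physical density) would otherwise corrupt the mass sum
clamp_hu <- function(hu, lo = -1000, hi = 100) {
  n <- sum(hu < lo | hu > hi)
  if (n > 0)
    message(sprintf("clamped %d lung voxels to HU range [%g, %g]", n, lo, hi))
  pmin(pmax(hu, lo), hi)
}

.per_lung <- function(image, mask, fun) {
  stopifnot(inherits(image, "ct_volume"), inherits(mask, "lung_mask"))
  if (!all(dim(image$data) == dim(mask$label)))
    stop("mask is not aligned to the image grid")
  vpix <- mask$voxel_volume_ml
  out <- c(left = 0, right = 0, total = 0)
  for (k in c("left", "right")) {
    lab <- if (k == "left") 1L else 2L
    hu <- clamp_hu(image$data[mask$label == lab])
    out[k] <- fun(hu, vpix)
  }
  out["total"] <- out["left"] + out["right"]
  out
}

#' Lung mass from HU densitometry
#'
#' Tissue density is calibrated to attenuation as `mu = 1 + HU/1000` g/mL
#' (water 0 HU, air -1000 HU), so the tissue mass of a segmented lung is
#' `sum((1 + HU/1000) * V_voxel)` over its voxels.
#'
#' @param image a [ct_volume()].
#' @param mask a [segment_lungs()] mask aligned to `image`.
#' @return named vector, grams, for `left`, `right`, `total`.
#' @export
lung_mass <- function(image, mask) {
  .per_lung(image, mask, function(hu, vpix) sum((1 + hu / 1000) * vpix))
}

#' Aerated lung volume from HU densitometry
#'
#' The air content of a voxel is `-HU/1000` of its volume, so the aerated
#' volume of a segmented lung is `sum((-HU/1000) * V_voxel)`.
#'
#' @inheritParams lung_mass
#' @return named vector, mL, for `left`, `right`, `total`.
#' @export
aerated_volume <- function(image, mask) {
  .per_lung(image, mask, function(hu, vpix) sum((-hu / 1000) * vpix))
}

#' Fractional tissue volume
#'
#' `FTV = V_tissue / (V_tissue + V_air)` with tissue volume numerically
#' equal to tissue mass (1 g = 1 mL).
#'
#' @param mass tissue mass, g.
#' @param air aerated volume, mL.
#' @return dimensionless FTV in `(0, 1]`.
#' @export
fractional_tissue_volume <- function(mass, air) {
  if (any(mass < 0) || any(air < 0)) stop("mass and air must be non-negative")
  if (any(mass + air == 0)) stop("FTV undefined: mass and air both zero")
  mass / (mass + air)
}

#' Densitometric measurements for one volume
#'
#' Convenience wrapper: per-lung mass, aerated volume and FTV at one
#' breath-hold pressure.
#'
#' @inheritParams lung_mass
#' @return list of class `lung_measurement`.
#' @export
measure_lungs <- function(image, mask) {
  m <- lung_mass(image, mask)
  a <- aerated_volume(image, mask)
  structure(list(pressure = image$pressure, mass = m, air_volume = a,
                 ftv = fractional_tissue_volume(m, a)),
            class = "lung_measurement")
}

#' @export
print.lung_measurement <- function(x, ...) {
  cat(sprintf(
    "<lung_measurement> P=%s cmH2O: mass R %.2f / L %.2f g, air R %.1f / L %.1f mL\n",
    format(x$pressure), x$mass["right"], x$mass["left"],
    x$air_volume["right"], x$air_volume["left"]))
  invisible(x)
}

#' Lung capacities from a breath-hold pressure series
#'
#' The aerated volume at 0 cmH2O estimates functional residual capacity
#' (FRC), the aerated volume at 25 cmH2O estimates total lung capacity
#' (TLC), and inspiratory capacity is their difference (IC = TLC - FRC).
#' Right-to-left ratios of aerated volume and FTV are evaluated at TLC.
#'
#' @param measurements list of [measure_lungs()] results including pressures
#'   0 and 25 cmH2O.
#' @return list of class `capacity_set` with `FRC`, `TLC`, `IC` (each a
#'   left/right/total vector, mL), `rl_volume_ratio`, `rl_ftv_ratio`.
#' @export
capacities <- function(measurements) {
  ps <- vapply(measurements, function(m) m$pressure, numeric(1))
  for (need in c(0, 25))
    if (!need %in% ps)
      stop(sprintf("missing breath-hold pressure %g cmH2O", need))
  m0 <- measurements[[match(0, ps)]]
  m25 <- measurements[[match(25, ps)]]
  structure(list(FRC = m0$air_volume, TLC = m25$air_volume,
                 IC = m25$air_volume - m0$air_volume,
                 rl_volume_ratio = unname(m25$air_volume["right"] /
                                          m25$air_volume["left"]),
                 rl_ftv_ratio = unname(m25$ftv["right"] / m25$ftv["left"])),
            class = "capacity_set")
}

#' @export
print.capacity_set <- function(x, ...) {
  cat(sprintf(
    "<capacity_set> FRC %.1f, TLC %.1f, IC %.1f mL (total); R:L at TLC %.2f\n",
    x$FRC["total"], x$TLC["total"], x$IC["total"], x$rl_volume_ratio))
  invisible(x)
}
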