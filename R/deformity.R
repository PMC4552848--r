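#' Ordered vertebral landmark annotation
#'
#' Vertebral centroids (mm, in the package axis convention) ordered caudal to
#' cranial, with an optional trans-axial rotation per vertebra (degrees about
#' the cranio-caudal axis).  All deformity measurements operate on these
#' landmark chains; vertebrae are never detected from images.
#'
#' @param centroids numeric matrix `n x 3` (columns x, y, z in mm), n >= 4,
#'   with strictly increasing z.
#' @param axial_rotation optional numeric vector of length n, degrees.
#' @param labels optional character vector of vertebral level labels.
#' @return An object of class `spine_annotation`.
#' @export
spine_annotation <- function(centroids, axial_rotation = NULL, labels = NULL) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 4L)
    stop("at least 4 vertebral landmarks are required")
  if (ncol(centroids) != 3L)
    stop("centroids must be an n x 3 matrix (x, y, z in mm)")
  if (any(diff(centroids[, 3]) <= 0))
    stop("centroids must be strictly ordered along the cranio-caudal (z) axis")
  if (!is.null(axial_rotation) && length(axial_rotation) != nrow(centroids))
    stop("axial_rotation must have one entry per vertebra")
  structure(list(centroids = centroids,
                 axial_rotation = axial_rotation,
                 labels = labels),
            class = "spine_annotation")
}

#' @export
print.spine_annotation <- function(x, ...) {
  cat(sprintf("<spine_annotation> %d vertebrae, z span %.1f mm%s\n",
              nrow(x$centroids), diff(range(x$centroids[, 3])),
              if (is.null(x$axial_rotation)) "" else ", with axial rotations"))
  invisible(x)
}

#' Read/write spine annotations as JSON
#'
#' The JSON schema is a list of vertebra records, each with `centroid_mm`
#' (length-3) and optionally `axial_rotation_deg` and `label`, ordered caudal
#' to cranial.
#'
#' @param x a [spine_annotation()].
#' @param path file path.
#' @return `read_spine_annotation` returns a [spine_annotation()].
#' @export
write_spine_annotation <- function(x, path) {
  recs <- lapply(seq_len(nrow(x$centroids)), function(i) {
    r <- list(centroid_mm = unname(x$centroids[i, ]))
    if (!is.null(x$axial_rotation)) r$axial_rotation_deg <- x$axial_rotation[i]
    if (!is.null(x$labels)) r$label <- x$labels[i]
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spine_annotation
#' @export
read_spine_annotation <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  cen <- t(vapply(recs, function(r) as.numeric(unlist(r$centroid_mm)),
                  numeric(3)))
  rot <- if (!is.null(recs[[1]]$axial_rotation_deg))
    vapply(recs, function(r) as.numeric(r$axial_rotation_deg), numeric(1))
  lab <- if (!is.null(recs[[1]]$label))
    vapply(recs, function(r) as.character(r$label), character(1))
  spine_annotation(cen, axial_rotation = rot, labels = lab)
}

# Fit a cubic spline centerline through projected centroids and return
# tangent angles (radians, relative to the z axis) and second derivatives on
# a fine grid.  `lateral` is the in-plane coordinate (x coronal, y sagittal).
# Landmarks are treated as exact by default (interpolating spline); a
# smoothing spline is used instead when `spar` is supplied, for noisy
# annotations.
centerline_tangents <- function(lateral, z, spar = NULL, n_eval = 400) {
  zz <- seq(min(z), max(z), length.out = n_eval)
  if (is.null(spar)) {
    fit <- tryCatch(stats::splinefun(z, lateral, method = "fmm"),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    d1 <- fit(zz, deriv = 1)
    d2 <- fit(zz, deriv = 2)
  } else {
    fit <- tryCatch(
      stats::smooth.spline(z, lateral, spar = spar, cv = FALSE,
                           all.knots = TRUE),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    d1 <- stats::predict(fit, zz, deriv = 1)$y
    d2 <- stats::predict(fit, zz, deriv = 2)$y
  }
  list(z = zz, angle = atan(d1), curv2 = d2)
}

#' Centerline-tangent Cobb angle
#'
#' Projects the vertebral centroids onto the coronal (x-z) or sagittal (y-z)
#' plane, fits a cubic spline centerline through the projected chain
#' (interpolating by default, smoothing when `spar` is given), and
#' returns the largest angle subtended between centerline tangents within a
#' single curve segment (a run of constant curvature sign).  This is the
#' centerline-tangent analogue of the clinical Cobb angle; vertebral
#' endplates are not modelled.
#'
#' @param annotation a [spine_annotation()].
#' @param plane `"coronal"` or `"sagittal"`.
#' @param spar optional smoothing parameter for [stats::smooth.spline()];
#'   by default the landmarks are interpolated exactly.
#' @return Cobb angle in degrees (0 for a straight spine).
#' @export
cobb_angle <- function(annotation, plane = c("coronal", "sagittal"),
                       spar = NULL) {
  stopifnot(inherits(annotation, "spine_annotation"))
  plane <- match.arg(plane)
  cen <- annotation$centroids
  lateral <- if (plane == "coronal") cen[, 1] else cen[, 2]
  z <- cen[, 3]
  # collinear chains are straight by definition
  if (max(abs(stats::lm.fit(cbind(1, z), lateral)$residuals)) < 1e-9)
    return(0)
  ct <- centerline_tangents(lateral, z, spar = spar)
  if (is.null(ct)) {
    warning("degenerate centerline fit; returning 0 degrees")
    return(0)
  }
  # split at curvature sign changes; Cobb is the largest tangent-angle range
  # within one segment
  sgn <- sign(ct$curv2)
  sgn[sgn == 0] <- 1
  seg <- cumsum(c(1, diff(sgn) != 0))
  best <- 0
  for (s in unique(seg)) {
    a <- ct$angle[seg == s]
    if (length(a) > 1) best <- max(best, diff(range(a)))
  }
  rad2deg(best)
}

#' Composite maximal spine deformity angle
#'
#' Combines the coronal (scoliosis) and sagittal (kyphosis) Cobb angles into
#' the maximal three-dimensional deformity angle
#' `theta_M = 2 * atan(sqrt(tan^2(theta_S/2) + tan^2(theta_K/2)))`.
#' Geometrically this is the bend angle between the end tangents of the
#' three-dimensional curve, equal to the largest Cobb angle observable over
#' all projection planes containing the cranio-caudal axis.
#'
#' @param theta_s coronal Cobb angle, degrees, in `[0, 180)`.
#' @param theta_k sagittal Cobb angle, degrees, in `[0, 180)`.
#' @return `theta_M` in degrees.
#' @export
maximal_deformity_angle <- function(theta_s, theta_k) {
  if (any(theta_s < 0) || any(theta_k < 0) ||
      any(theta_s >= 180) || any(theta_k >= 180))
    stop("Cobb angles must lie in [0, 180) degrees")
  rad2deg(2 * atan(sqrt(tan(deg2rad(theta_s) / 2)^2 +
                        tan(deg2rad(theta_k) / 2)^2)))
}

#' Thoracic rotation angle at the curve apex
#'
#' The apex is the vertebra of maximal centerline curvature (combined
#' coronal + sagittal).  The thoracic rotation angle is that vertebra's
#' trans-axial rotation relative to the mean rotation of the two end
#' vertebrae, so a uniform whole-spine rotation reads as zero.
#'
#' @param annotation a [spine_annotation()] carrying `axial_rotation`.
#' @return list with `tra` (degrees) and `apex_index`.
#' @export
thoracic_rotation_angle <- function(annotation) {
  stopifnot(inherits(annotation, "spine_annotation"))
  if (is.null(annotation$axial_rotation))
    stop("annotation carries no axial rotation data")
  cen <- annotation$centroids
  z <- cen[, 3]
  cx <- centerline_tangents(cen[, 1], z)
  cy <- centerline_tangents(cen[, 2], z)
  n <- nrow(cen)
  if (is.null(cx) || is.null(cy)) {
    apex <- as.integer(ceiling(n / 2))
  } else {
    # geometric curvature of the 3-D centerline parameterised by z
    d1 <- tan(cx$angle)^2 + tan(cy$angle)^2
    curv <- sqrt(cx$curv2^2 + cy$curv2^2) / (1 + d1)^1.5
    z_apex <- cx$z[which.max(curv)]
    apex <- which.min(abs(z - z_apex))
  }
  rot <- annotation$axial_rotation
  tra <- rot[apex] - mean(rot[c(1L, n)])
  list(tra = tra, apex_index = apex)
}

#' Severity classification from the maximal deformity angle
#'
#' Severe above 55 degrees, Moderate in (15, 55], Normal-range otherwise.
#' In pipeline runs the classification is applied to the 10-week deformity
#' angle; the classifier itself is timepoint-agnostic.  The 15-degree
#' Moderate/Normal-range boundary is a package convention for unoperated
#' animals.
#'
#' @param theta_m maximal deformity angle, degrees (>= 0).
#' @return factor with levels `Normal-range`, `Moderate`, `Severe`.
#' @export
classify_severity <- function(theta_m) {
  if (any(theta_m < 0)) stop("theta_m must be non-negative")
  factor(ifelse(theta_m > 55, "Severe",
         ifelse(theta_m > 15, "Moderate", "Normal-range")),
         levels = c("Normal-range", "Moderate", "Severe"))
}

#' All deformity measures from one annotation
#'
#' Convenience wrapper computing both Cobb angles, the composite maximal
#' deformity angle, the thoracic rotation angle (when rotations are present)
#' and the severity class.
#'
#' @param annotation a [spine_annotation()].
#' @return list of class `deformity_result` with fields `theta_S`, `theta_K`,
#'   `theta_M`, `TRA`, `apex_index`, `severity`.
#' @export
deformity_measures <- function(annotation) {
  ts <- cobb_angle(annotation, "coronal")
  tk <- cobb_angle(annotation, "sagittal")
  tm <- maximal_deformity_angle(ts, tk)
  tra <- if (!is.null(annotation$axial_rotation))
    thoracic_rotation_angle(annotation) else list(tra = NA_real_,
                                                  apex_index = NA_integer_)
  structure(list(theta_S = ts, theta_K = tk, theta_M = tm,
                 TRA = tra$tra, apex_index = tra$apex_index,
                 severity = classify_severity(tm)),
            class = "deformity_result")
}

#' @export
print.deformity_result <- function(x, ...) {
  cat(sprintf(
    paste0("<deformity_result> theta_S %.1f deg, theta_K %.1f deg, ",
           "theta_M %.1f deg (%s)\n"),
    x$theta_S, x$theta_K, x$theta_M, as.character(x$severity)))
  if (!is.na(x$TRA))
    cat(sprintf("  TRA %.1f deg at vertebra %d\n", x$TRA, x$apex_index))
  invisible(x)
}
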