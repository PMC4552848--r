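#' CT-like volume container
#'
#' A light container for 3-D Hounsfield-unit voxel grids: a numeric array
#' with millimetre voxel spacing and the breath-hold pressure at which the
#' volume was (synthetically) acquired.  Axis convention throughout the
#' package: x runs right to left, y anterior to posterior, z caudal to
#' cranial.  The animal is prone, so the anterior (low-y) lung is the
#' gravity-dependent side.
#'
#' @param data numeric 3-D array of HU values.
#' @param spacing numeric length-3, voxel spacing in mm.
#' @param pressure breath-hold airway pressure in cmH2O (may be `NA`).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1.25, 1.25, 1.25), pressure = NA_real_) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            is.numeric(spacing), length(spacing) == 3L, all(spacing > 0))
  structure(list(data = data, spacing = as.numeric(spacing),
                 pressure = as.numeric(pressure)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, pressure %s cmH2O\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              format(x$pressure)))
  cat(sprintf("  HU range [%.0f, %.0f]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

# voxel volume in mL (spacing is mm; 1 mL = 1000 mm^3)
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

#' Read / write volumes as NIfTI
#'
#' Volumes are exchanged on disk in NIfTI-1 format with the voxel spacing in
#' the pixdim header.  The breath-hold pressure is not part of the NIfTI
#' header and must be supplied on read.
#'
#' @param x a [ct_volume()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param pressure breath-hold pressure tag to attach on read.
#' @return `write_volume` returns `path` invisibly; `read_volume` a
#'   [ct_volume()].
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "ct_volume"))
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, pressure = NA_real_) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim = dim(img)),
            spacing = RNifti::pixdim(img)[seq_len(3)], pressure = pressure)
}

#' Dense displacement field between two breath-hold volumes
#'
#' A voxelwise mapping defined on the lower-pressure ("fixed") grid.  The
#' field stores, for each fixed-grid voxel, the displacement in mm that
#' carries it onto the corresponding tissue location in the higher-pressure
#' ("moving") image.
#'
#' @param u 4-D numeric array `nx x ny x nz x 3`, displacement in mm.
#' @param spacing voxel spacing in mm.
#' @param fixed_pressure,moving_pressure pressure tags in cmH2O.
#' @param info optional list of convergence diagnostics.
#' @return An object of class `disp_field`.
#' @export
disp_field <- function(u, spacing, fixed_pressure = NA_real_,
                       moving_pressure = NA_real_, info = list()) {
  stopifnot(is.array(u), length(dim(u)) == 4L, dim(u)[4] == 3L)
  structure(list(u = u, spacing = as.numeric(spacing),
                 fixed_pressure = fixed_pressure,
                 moving_pressure = moving_pressure, info = info),
            class = "disp_field")
}

#' @export
print.disp_field <- function(x, ...) {
  mags <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat(sprintf(
    "<disp_field> %s voxels, %s -> %s cmH2O, |u| mean %.2f / max %.2f mm\n",
    paste(dim(x$u)[1:3], collapse = "x"), format(x$fixed_pressure),
    format(x$moving_pressure), mean(mags), max(mags)))
  invisible(x)
}

# thin wrappers around the compiled kernels -------------------------------

warp_volume <- function(vol, ux_vox, uy_vox, uz_vox) {
  d <- dim(vol)
  array(.cpp_warp(as.numeric(vol), as.integer(d), as.numeric(ux_vox),
                  as.numeric(uy_vox), as.numeric(uz_vox)), dim = d)
}

resample_volume <- function(vol, newdims) {
  array(.cpp_resample(as.numeric(vol), as.integer(dim(vol)),
                      as.integer(newdims)), dim = newdims)
}

gauss_smooth <- function(vol, sigma_vox) {
  array(.cpp_gauss_smooth(as.numeric(vol), as.integer(dim(vol)),
                          as.numeric(sigma_vox)), dim = dim(vol))
}

gradient3 <- function(vol, spacing = c(1, 1, 1)) {
  g <- .cpp_gradient(as.numeric(vol), as.integer(dim(vol)),
                     as.numeric(spacing))
  lapply(g, array, dim = dim(vol))
}

label_components <- function(mask) {
  array(.cpp_label6(as.logical(mask), as.integer(dim(mask))), dim = dim(mask))
}

jacobian_det_vox <- function(ux, uy, uz, mask = NULL) {
  array(.cpp_jacobian_det(as.numeric(ux), as.numeric(uy), as.numeric(uz),
                          as.integer(dim(ux)),
                          if (!is.null(mask)) as.logical(mask)),
        dim = dim(ux))
}
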