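# Shared fixtures: small, fast phantoms and analytic annotations built in
# code at test time.

# compact thorax phantom: same physical extent as the default grid but
# 2.0 mm voxels, so rendering and registration stay fast in unit tests
small_spec <- function(seed = 1, ...) {
  phantom_spec(grid_shape = c(40, 40, 60), spacing = c(2, 2, 2),
               seed = seed, ...)
}

# vertebral centroids on a planar circular arc subtending `theta` degrees
# in the coronal (x-z) plane; end tangents of the arc meet at exactly theta
arc_annotation <- function(theta, n = 13, radius = 100, rotation = NULL) {
  phi <- seq(-deg2rad(theta) / 2, deg2rad(theta) / 2, length.out = n)
  cen <- cbind(40 + radius * (1 - cos(phi)), 40, 60 + radius * sin(phi))
  spine_annotation(cen, axial_rotation = rotation)
}

deg2rad <- function(x) x * pi / 180

# brute-force oracle for the composite deformity angle: bend a two-segment
# polyline by theta_s coronally and theta_k sagittally, then take the
# maximal projected bend angle over a dense grid of projection planes
# containing the cranio-caudal axis
projected_max_angle <- function(theta_s, theta_k, n_dir = 721) {
  a <- tan(deg2rad(theta_s) / 2)
  b <- tan(deg2rad(theta_k) / 2)
  d1 <- c(-a, -b, 1)
  d2 <- c(a, b, 1)
  best <- 0
  for (phi in seq(0, pi, length.out = n_dir)) {
    v <- c(cos(phi), sin(phi), 0)
    p1 <- d1 - sum(d1 * v) * v
    p2 <- d2 - sum(d2 * v) * v
    cs <- sum(p1 * p2) / sqrt(sum(p1^2) * sum(p2^2))
    best <- max(best, acos(max(-1, min(1, cs))))
  }
  best * 180 / pi
}

# tiny ct_volume with prescribed HU values
tiny_volume <- function(hu, spacing = c(1, 1, 1), pressure = NA) {
  ct_volume(hu, spacing = spacing, pressure = pressure)
}

# hand-built lung mask for direct densitometry formula tests
manual_mask <- function(label, spacing = c(1, 1, 1)) {
  structure(list(label = label, voxel_volume_ml = prod(spacing) / 1000,
                 spacing = spacing, flag = NULL),
            class = "lung_mask")
}
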