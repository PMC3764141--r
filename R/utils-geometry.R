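# Small 3D geometry helpers shared by the detectors and generators.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle between two vectors in degrees.
.vangle <- function(a, b) {
  ca <- sum(a * b) / (.vnorm(a) * .vnorm(b))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}

# Angle between two planes given their normals, folded to [0, 90] so the
# arbitrary sign of a plane normal does not matter.
.plane_angle <- function(n1, n2) {
  a <- .vangle(n1, n2)
  min(a, 180 - a)
}

.rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, 3, byrow = TRUE)
}

.rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, 3, byrow = TRUE)
}

.rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# Apply rotation R (3x3) then translation t to an n x 3 coordinate matrix.
.transform_coords <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, -t)
}

# Least-squares plane through an n x 3 matrix of points: returns centroid
# and unit normal (smallest principal direction).
.fit_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  s <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, normal = s$v[, 3])
}

# Principal axis (unit vector) through an n x 3 matrix of points.
.fit_line <- function(xyz) {
  ctr <- colMeans(xyz)
  s <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, direction = s$v[, 1])
}

# Random rigid transform, used by invariance tests; deterministic under seed.
.random_rigid <- function() {
  ax <- stats::runif(3, 0, 2 * pi)
  R <- .rot_z(ax[1]) %*% .rot_y(ax[2]) %*% .rot_x(ax[3])
  list(R = R, t = stats::runif(3, -20, 20))
}
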