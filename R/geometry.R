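# Small 3D geometry kernel shared by the builder and all analyses.
# Vectorized over rows: every p* argument is an n x 3 matrix.

vnorm <- function(m) sqrt(rowSums(m^2))

vunit <- function(m) m / vnorm(m)

vcross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

vdot <- function(a, b) rowSums(a * b)

as_row3 <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else p
}

#' Signed torsion angle between four points
#'
#' Computes the torsion (dihedral) angle defined by four points using the
#' IUPAC sign convention: looking from `p2` to `p3`, the angle is positive
#' when the far bond (`p3`-`p4`) is rotated clockwise relative to the near
#' bond (`p2`-`p1`). This is the primitive behind the glycosidic torsion and
#' the five furanose ring torsions.
#'
#' @param p1,p2,p3,p4 Numeric length-3 vectors, or n x 3 matrices for a
#'   vectorized call.
#' @param range Output convention: `"signed"` gives degrees in (-180, 180],
#'   `"positive"` gives degrees in \[0, 360).
#' @return Torsion angle(s) in degrees.
#' @examples
#' # trans (antiperiplanar) arrangement
#' dihedral(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, -1, 0))
#' @export
dihedral <- function(p1, p2, p3, p4, range = c("signed", "positive")) {
  range <- match.arg(range)
  p1 <- as_row3(p1); p2 <- as_row3(p2); p3 <- as_row3(p3); p4 <- as_row3(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (any(vnorm(b1) < 1e-9) || any(vnorm(b2) < 1e-9) || any(vnorm(b3) < 1e-9)) {
    abort("degenerate geometry: two consecutive points coincide", class = "lnahelix_geometry_error")
  }
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (any(vnorm(n1) < 1e-9) || any(vnorm(n2) < 1e-9)) {
    abort("degenerate geometry: three consecutive points are collinear", class = "lnahelix_geometry_error")
  }
  m1 <- vcross(n1, vunit(b2))
  ang <- atan2(vdot(m1, n2), vdot(n1, n2)) * 180 / pi
  if (range == "positive") ang <- ang %% 360
  ang
}

# Rotation matrix about a unit axis (Rodrigues), angle in radians.
rotation_about <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

rot_z <- function(theta) rotation_about(c(0, 0, 1), theta)
rot_x <- function(theta) rotation_about(c(1, 0, 0), theta)

# Rotation taking unit vector a to unit vector b (minimal rotation).
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(a[2] * ref[3] - a[3] * ref[2], a[3] * ref[1] - a[1] * ref[3], a[1] * ref[2] - a[2] * ref[1])
    return(rotation_about(ax, pi))
  }
  rotation_about(v, atan2(s, c_))
}

# Axis-angle decomposition of a rotation matrix. Returns list(axis, angle)
# with angle in [0, pi].
rotation_axis_angle <- function(R) {
  tr <- sum(diag(R))
  angle <- acos(pmin(1, pmax(-1, (tr - 1) / 2)))
  if (angle < 1e-7) return(list(axis = c(0, 0, 1), angle = 0))
  if (pi - angle < 1e-6) {
    # near 180 degrees: axis from the symmetric part
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(0, diag(B)))
    k <- which.max(ax)
    ax <- B[, k] / ax[k]
    return(list(axis = ax / sqrt(sum(ax^2)), angle = angle))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(angle))
  list(axis = ax, angle = angle)
}

# Half rotation: square root of a rotation matrix.
rotation_half <- function(R) {
  aa <- rotation_axis_angle(R)
  rotation_about(aa$axis, aa$angle / 2)
}

# Kabsch superposition: rotation R and translation t such that
# R %*% t(template) + t approximates t(observed) in least squares.
# Returns list(R, t, rmsd).
kabsch_fit <- function(template, observed) {
  ct <- colMeans(template)
  co <- colMeans(observed)
  A <- sweep(template, 2, ct)
  B <- sweep(observed, 2, co)
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_ <- unname(co - as.vector(R %*% ct))
  fitted <- t(R %*% t(template)) + matrix(t_, nrow(template), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - observed)^2)))
  list(R = R, t = t_, rmsd = rmsd)
}

# Place a fourth atom from three predecessors using internal coordinates:
# bond length |c-d|, bond angle b-c-d (deg) and torsion a-b-c-d (deg).
place_atom <- function(a, b, c_, len, ang, tor) {
  bc <- c_ - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- ab - sum(ab * bc) * bc
  n <- n / sqrt(sum(n^2))
  m <- c(bc[2] * n[3] - bc[3] * n[2], bc[3] * n[1] - bc[1] * n[3], bc[1] * n[2] - bc[2] * n[1])
  ang <- ang * pi / 180; tor <- tor * pi / 180
  c_ + len * (-cos(ang) * bc + sin(ang) * (cos(tor) * (-n) + sin(tor) * m))
}

# Vectorized variant: a, b, c_ are n x 3 matrices; len/ang/tor length-n.
place_atoms <- function(a, b, c_, len, ang, tor) {
  bc <- vunit(c_ - b)
  ab <- b - a
  n <- ab - vdot(ab, bc) * bc
  n <- vunit(n)
  m <- vcross(bc, n)
  ang <- ang * pi / 180; tor <- tor * pi / 180
  c_ + len * (-cos(ang) * bc + sin(ang) * (cos(tor) * (-n) + sin(tor) * m))
}

# Random rigid motion, used in tests and documented here for reuse.
random_rigid_motion <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  list(R = rotation_about(ax, runif(1, 0, 2 * pi)), t = rnorm(3, sd = 20))
}

apply_rigid <- function(xyz, motion) {
  t(motion$R %*% t(xyz)) + matrix(motion$t, nrow(xyz), 3, byrow = TRUE)
}
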