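# Internal cartesian geometry helpers. Coordinates are N x 3 matrices in
# Angstrom; angles are returned in radians unless noted.

vec_norm <- function(v) sqrt(sum(v * v))

#' Distance between two atoms
#' @param xyz N x 3 coordinate matrix (Angstrom)
#' @param i,j atom indices
#' @return distance in Angstrom
#' @keywords internal
atom_distance <- function(xyz, i, j) {
  vec_norm(xyz[i, ] - xyz[j, ])
}

# Bend angle i-j-k in radians.
bend_angle <- function(xyz, i, j, k) {
  a <- xyz[i, ] - xyz[j, ]
  b <- xyz[k, ] - xyz[j, ]
  ct <- sum(a * b) / (vec_norm(a) * vec_norm(b))
  acos(max(-1, min(1, ct)))
}

#' Measure a proper dihedral angle
#'
#' Signed torsion angle of the atom chain i-j-k-l, using the standard
#' IUPAC convention (cis = 0, sign from the right-hand rule about the
#' j->k axis). Result lies in (-pi, pi].
#'
#' @param xyz N x 3 coordinate matrix (Angstrom)
#' @param i,j,k,l atom indices forming a bonded chain
#' @return angle in radians in (-pi, pi]
#' @export
dihedral_angle <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, ] - xyz[i, ]
  b2 <- xyz[k, ] - xyz[j, ]
  b3 <- xyz[l, ] - xyz[k, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vec_norm(b2)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  phi <- atan2(y, x)
  if (phi <= -pi) phi <- phi + 2 * pi
  phi
}

# Rotation matrix for angle theta (radians) about unit axis u (Rodrigues).
rotation_matrix <- function(u, theta) {
  u <- u / vec_norm(u)
  ct <- cos(theta)
  st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),       ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),       uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# Rotate the rows in `idx` of xyz about the axis through `origin` with
# direction `axis` by theta radians.
rotate_about_axis <- function(xyz, idx, origin, axis, theta) {
  R <- rotation_matrix(axis, theta)
  shifted <- sweep(xyz[idx, , drop = FALSE], 2, origin)
  xyz[idx, ] <- shifted %*% t(R) + matrix(origin, length(idx), 3, byrow = TRUE)
  xyz
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap an angle in degrees into [0, 360).
wrap_deg_360 <- function(x) ((x %% 360) + 360) %% 360

# Wrap an angle in degrees into (-180, 180].
wrap_deg_180 <- function(x) {
  y <- ((x + 180) %% 360 + 360) %% 360 - 180
  ifelse(y == -180, 180, y)
}
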