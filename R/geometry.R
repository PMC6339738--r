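# Internal vector helpers.  All coordinates are millimetres; angles at the
# interfaces are degrees, radians only ever appear inside a function body.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero-length vector")
  v / n
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Rotation about the +z axis by `theta_deg` degrees (right-handed).
rot_z <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), sin(t), 0,
           -sin(t), cos(t), 0,
           0, 0, 1), nrow = 3)
}

# Minimal rotation taking unit vector `a` onto unit vector `b`
# (Rodrigues; identity when a == b, a 180-degree flip picks any
# perpendicular axis deterministically).
rotation_between <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  s <- vnorm(v)
  if (s < 1e-15) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unitv(p - sum(p * a) * a)
    return(2 * outer(ax, ax) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2],
                 -v[3], 0, v[1],
                 v[2], -v[1], 0), nrow = 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

# Two unit vectors completing `axis` to an orthonormal triad.
perp_basis <- function(axis) {
  axis <- unitv(axis)
  p <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitv(p - sum(p * axis) * axis)
  w <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  list(u = u, v = w)
}

# arccos of a dot product clipped to [-1, 1], in degrees.
acos_deg <- function(x) rad2deg(acos(pmin(1, pmax(-1, x))))
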