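#' Estimate a bone-end center from its landmark ring
#'
#' The default estimator is the arithmetic centroid of the ring points, which
#' is exact for evenly spaced points on a circle and permutation/rigid-motion
#' equivariant.  A least-squares 3D circle fit (plane fit by principal
#' components, then Gauss-Newton circle fit in the plane) is available as an
#' alternative estimator and serves as a cross-check.
#'
#' @param ring a [landmark_ring()].
#' @param method `"centroid"` (default) or `"circle"`.
#' @return Numeric length-3 center (mm).
#' @export
estimate_center <- function(ring, method = c("centroid", "circle")) {
  method <- match.arg(method)
  stopifnot(inherits(ring, "landmark_ring"))
  if (method == "centroid") return(colMeans(ring$points))
  fit_ring_circle(ring$points)$center
}

#' Least-squares 3D circle fit
#'
#' Fits the plane through the points (total least squares via SVD), then fits
#' a circle in that plane: algebraic (Kasa) initialization refined by
#' Gauss-Newton on the geometric distances.
#'
#' @param points numeric matrix (>= 3 rows).
#' @return List with `center` (3-vector), `radius`, `normal`, `rms` residual.
#' @export
fit_ring_circle <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("degenerate-ring: need at least 3 points")
  ctr <- colMeans(points)
  rel <- sweep(points, 2, ctr)
  sv <- svd(rel)
  normal <- sv$v[, 3]
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  u <- rel %*% e1
  v <- rel %*% e2

  # Kasa: minimize ||u^2+v^2 - 2au - 2bv - c||
  A <- cbind(2 * u, 2 * v, 1)
  rhs <- u^2 + v^2
  ab <- qr.solve(A, rhs)
  a <- ab[1]; b <- ab[2]
  r <- sqrt(ab[3] + a^2 + b^2)

  for (it in 1:100) {
    du <- u - a; dv <- v - b
    d <- sqrt(du^2 + dv^2)
    resid <- d - r
    J <- cbind(-du / d, -dv / d, -1)
    step <- tryCatch(qr.solve(J, -resid), error = function(e) c(0, 0, 0))
    a <- a + step[1]; b <- b + step[2]; r <- r + step[3]
    if (max(abs(step)) < 1e-12) break
  }
  d <- sqrt((u - a)^2 + (v - b)^2)
  list(center = as.numeric(ctr + a * e1 + b * e2),
       radius = r,
       normal = as.numeric(normal),
       rms = sqrt(mean((d - r)^2)))
}

#' Bone axis from base and head landmark rings
#'
#' The direction vector from the estimated center of the proximal base to the
#' estimated center of the distal head.
#'
#' @param base_ring,head_ring [landmark_ring()]s for the two ends.
#' @param method center estimator, see [estimate_center()].
#' @return A `bone_axis`: list with `base_center`, `head_center`, unit
#'   `direction`, `bone_id`.
#' @export
bone_axis <- function(base_ring, head_ring, method = "centroid") {
  b <- estimate_center(base_ring, method)
  h <- estimate_center(head_ring, method)
  if (vnorm(h - b) < 1e-9)
    stop("zero-length-axis: base and head centers coincide")
  structure(list(bone_id = base_ring$bone_id,
                 base_center = b, head_center = h,
                 direction = unitv(h - b)),
            class = "bone_axis")
}

#' Flexion angle between two bone axes
#'
#' The unsigned angle in `[0, 180]` degrees between the base-to-head direction
#' vectors of two articulating bones; the dot product is clipped to
#' `[-1, 1]` before the arccosine.
#'
#' @param proximal,distal `bone_axis` objects (or unit 3-vectors).
#' @return Angle in degrees.
#' @export
flexion_angle <- function(proximal, distal) {
  d1 <- if (inherits(proximal, "bone_axis")) proximal$direction else proximal
  d2 <- if (inherits(distal, "bone_axis")) distal$direction else distal
  if (abs(vnorm(d1) - 1) > 1e-6 || abs(vnorm(d2) - 1) > 1e-6)
    stop("normalization error: flexion_angle expects unit direction vectors")
  acos_deg(sum(d1 * d2))
}
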