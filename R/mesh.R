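#' Triangle mesh constructor
#'
#' A minimal triangle-mesh container: a numeric vertex matrix and an integer
#' face matrix with 1-based indices and consistent outward winding.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @return An object of class `grip_mesh`.
#' @export
grip_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || ncol(faces) != 3)
    stop("vertices and faces must have 3 columns")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "grip_mesh")
}

#' @export
print.grip_mesh <- function(x, ...) {
  cat(sprintf("<grip_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Enclosed volume of a closed triangle mesh
#'
#' Signed-tetrahedron (divergence theorem) sum; positive for outward winding.
#'
#' @param mesh a `grip_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Watertightness check
#'
#' A closed orientable surface has every undirected edge shared by exactly two
#' faces, traversed once in each direction.
#'
#' @param mesh a `grip_mesh`.
#' @return `TRUE` if the mesh is watertight and consistently oriented.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  half <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(half[, 1], half[, 2])
  rkey <- paste(half[, 2], half[, 1])
  if (anyDuplicated(key)) return(FALSE)      # same directed edge twice
  all(key %in% rkey)                          # every edge has its twin
}

# Analytic volume of the capsule solid built by make_phalanx_mesh:
# spherical segment (base) + cylinder + spherical segment (head).
capsule_volume <- function(length, shaft_radius, base_radius, head_radius) {
  seg <- function(r, y0, y1) pi * ((r^2 * y1 - y1^3 / 3) - (r^2 * y0 - y0^3 / 3))
  yb <- sqrt(base_radius^2 - shaft_radius^2)
  yh <- sqrt(head_radius^2 - shaft_radius^2)
  seg(base_radius, -base_radius, yb) +
    pi * shaft_radius^2 * (length - yh - yb) +
    seg(head_radius, -yh, head_radius)
}

#' Synthetic phalanx mesh in canonical pose
#'
#' Builds a watertight capsule proxy for a phalanx or metacarpal: a cylindrical
#' shaft capped by spherical head/base ends, base center at the origin and the
#' long axis along +y.  Real phalanx ends present near-circular condylar
#' circumferences, which is the only geometric feature the landmark-ring
#' measurement relies on.
#'
#' @param length bone length (mm), distance between base and head centers.
#' @param shaft_radius radius of the cylindrical shaft (mm); must not exceed
#'   either cap radius.
#' @param base_radius,head_radius radii of the spherical end caps (mm).
#' @param resolution number of segments around the circumference (also sets
#'   cap latitude density).
#' @param bone_id optional identifier attached to the placement.
#' @return A `bone_placement`: list with `mesh`, `true_base_center`,
#'   `true_head_center`, cap radii and `bone_id`.
#' @export
make_phalanx_mesh <- function(length, shaft_radius, base_radius, head_radius,
                              resolution = 32, bone_id = NULL) {
  dims <- c(length = length, shaft_radius = shaft_radius,
            base_radius = base_radius, head_radius = head_radius)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("invalid-geometry: all dimensions must be positive finite numbers")
  if (length <= base_radius + head_radius)
    stop("invalid-geometry: length must exceed base_radius + head_radius")
  if (shaft_radius > min(base_radius, head_radius))
    stop("invalid-geometry: shaft_radius must not exceed the cap radii")
  n <- max(8L, as.integer(resolution))
  m <- max(4L, n %/% 4L)                      # latitude steps per cap

  alpha <- 2 * pi * (seq_len(n) - 1) / n
  ring <- function(r, y) cbind(r * cos(alpha), rep(y, n), r * sin(alpha))

  # base cap: pole at -base_radius up to the shaft tangent latitude
  phi_b <- asin(sqrt(base_radius^2 - shaft_radius^2) / base_radius)
  phis <- seq(-pi / 2, phi_b, length.out = m + 2)[-1]
  verts <- rbind(c(0, -base_radius, 0))
  for (p in phis) verts <- rbind(verts, ring(base_radius * cos(p), base_radius * sin(p)))

  # head cap: from the shaft tangent latitude up to pole at length + head_radius
  phi_h <- asin(sqrt(head_radius^2 - shaft_radius^2) / head_radius)
  phis_h <- seq(-phi_h, pi / 2, length.out = m + 2)
  phis_h <- phis_h[-(m + 2)]
  head_start <- nrow(verts)
  for (p in phis_h) verts <- rbind(verts, ring(head_radius * cos(p), length + head_radius * sin(p)))
  verts <- rbind(verts, c(0, length + head_radius, 0))

  nring <- (m + 1) * 2                        # rings bottom-to-top, all length n
  ring_start <- function(j) 1 + (j - 1) * n   # first vertex index of ring j (+1 pole offset)
  faces <- list()
  # base pole fan
  r1 <- 1 + ring_start(1)
  idx <- r1 + (seq_len(n) - 1)
  nxt <- r1 + (seq_len(n) %% n)
  faces[[length(faces) + 1]] <- cbind(1L, idx, nxt)
  # quad strips between consecutive rings (covers caps and shaft wall)
  for (j in seq_len(nring - 1)) {
    lo <- 1 + ring_start(j) + (seq_len(n) - 1)
    lo_n <- 1 + ring_start(j) + (seq_len(n) %% n)
    hi <- lo + n
    hi_n <- lo_n + n
    faces[[length(faces) + 1]] <- cbind(lo, hi, hi_n)
    faces[[length(faces) + 1]] <- cbind(lo, hi_n, lo_n)
  }
  # head pole fan
  pole2 <- nrow(verts)
  top <- 1 + ring_start(nring) + (seq_len(n) - 1)
  top_n <- 1 + ring_start(nring) + (seq_len(n) %% n)
  faces[[length(faces) + 1]] <- cbind(pole2, top_n, top)

  mesh <- grip_mesh(verts, do.call(rbind, faces))
  structure(list(bone_id = bone_id,
                 mesh = mesh,
                 true_base_center = c(0, 0, 0),
                 true_head_center = c(0, length, 0),
                 length = length,
                 shaft_radius = shaft_radius,
                 base_radius = base_radius,
                 head_radius = head_radius),
            class = "bone_placement")
}

#' @export
print.bone_placement <- function(x, ...) {
  cat(sprintf("<bone_placement%s: length %.1f mm, base (%.1f, %.1f, %.1f), head (%.1f, %.1f, %.1f)>\n",
              if (is.null(x$bone_id)) "" else paste0(" ", paste(x$bone_id, collapse = "/")),
              x$length,
              x$true_base_center[1], x$true_base_center[2], x$true_base_center[3],
              x$true_head_center[1], x$true_head_center[2], x$true_head_center[3]))
  invisible(x)
}

# Apply a rigid motion (3x3 rotation R then translation t) to a placement.
transform_placement <- function(placement, R, t) {
  p <- placement
  if (!is.null(p$mesh)) {
    p$mesh$vertices <- p$mesh$vertices %*% t(R) +
      matrix(t, nrow(p$mesh$vertices), 3, byrow = TRUE)
  }
  p$true_base_center <- as.numeric(R %*% p$true_base_center + t)
  p$true_head_center <- as.numeric(R %*% p$true_head_center + t)
  p
}
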