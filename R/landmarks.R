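# Run expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Landmark ring
#'
#' The picked surface points around one bone-end circumference.
#'
#' @param points numeric matrix (>= 3 rows, columns x/y/z in mm).
#' @param bone_id identifier, e.g. `c("index", "distal")`.
#' @param end `"head"` or `"base"`.
#' @return A `landmark_ring`.
#' @export
landmark_ring <- function(points, bone_id = NULL, end = c("head", "base")) {
  end <- match.arg(end)
  points <- as.matrix(points)
  if (nrow(points) < 3)
    stop("degenerate-ring: a landmark ring needs at least 3 points")
  if (any(!is.finite(points))) stop("degenerate-ring: non-finite coordinates")
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate-ring: points are collinear")
  structure(list(bone_id = bone_id, end = end, points = points),
            class = "landmark_ring")
}

#' @export
print.landmark_ring <- function(x, ...) {
  cat(sprintf("<landmark_ring%s %s: %d points>\n",
              if (is.null(x$bone_id)) "" else paste0(" ", paste(x$bone_id, collapse = "/")),
              x$end, nrow(x$points)))
  invisible(x)
}

#' Sample a landmark ring on a bone end
#'
#' Emulates manual picking of `n_points` surface points at nominally equal
#' angular spacing around the outer circumference of a bone end cap: points on
#' the cap-radius circle perpendicular to the bone axis through the true end
#' center, each displaced by uniform angular jitter and isotropic Gaussian
#' positional noise.
#'
#' @param placement a `bone_placement` (posed or canonical).
#' @param end `"head"` or `"base"`.
#' @param n_points number of points (>= 3; the measurement protocol uses 8 at
#'   about 45 degree intervals).
#' @param angular_jitter_deg half-width of the uniform angular jitter (deg).
#' @param radial_noise_mm sd of the isotropic positional noise (mm); the
#'   default 0.2 mm reflects sub-slice picking error on 0.5 mm CT voxels.
#' @param seed integer RNG seed; the global RNG state is left untouched.
#' @return A [landmark_ring()].
#' @export
sample_landmark_ring <- function(placement, end = c("head", "base"),
                                 n_points = 8, angular_jitter_deg = 10,
                                 radial_noise_mm = 0.2, seed = 1L) {
  end <- match.arg(end)
  stopifnot(inherits(placement, "bone_placement"))
  if (n_points < 3) stop("degenerate-ring: n_points must be at least 3")
  ctr <- if (end == "head") placement$true_head_center else placement$true_base_center
  r <- if (end == "head") placement$head_radius else placement$base_radius
  axis <- unitv(placement$true_head_center - placement$true_base_center)
  uv <- perp_basis(axis)
  with_seed(seed, {
    alpha <- 2 * pi * (seq_len(n_points) - 1) / n_points +
      deg2rad(stats::runif(n_points, -angular_jitter_deg, angular_jitter_deg))
    pts <- matrix(ctr, n_points, 3, byrow = TRUE) +
      r * (cos(alpha) %o% uv$u + sin(alpha) %o% uv$v) +
      matrix(stats::rnorm(3 * n_points, sd = radial_noise_mm), n_points, 3)
    landmark_ring(pts, bone_id = placement$bone_id, end = end)
  })
}

#' Pick end rings directly from a bone mesh
#'
#' Heuristic landmark picker for meshes without ground truth: the bone axis is
#' the first principal component of the vertices; at each axial extreme the
#' cap radius is found by fixed-point search (the cap circumference is where
#' the radial distance at one cap-radius depth from the pole peaks), and one
#' vertex per angular sector is picked on that circumference.
#'
#' @param mesh a `grip_mesh`.
#' @param n_points points per ring.
#' @param bone_id optional identifier for the returned rings.
#' @return List of two `landmark_ring`s named `end1`/`end2` (ordered along the
#'   principal axis; anatomical base/head assignment is done by chain
#'   matching), with attribute `"axis_points"`: approximate end centers.
#' @export
pick_end_rings <- function(mesh, n_points = 8, bone_id = NULL) {
  V <- mesh$vertices
  ctr <- colMeans(V)
  ax <- svd(sweep(V, 2, ctr), nu = 0, nv = 1)$v[, 1]
  t <- as.numeric(sweep(V, 2, ctr) %*% ax)
  radial <- sqrt(rowSums((sweep(V, 2, ctr) - t %o% ax)^2))
  span <- diff(range(t))

  pick_one <- function(sign_) {
    te <- if (sign_ > 0) max(t) else min(t)
    rhat <- 0.25 * span
    for (i in 1:20) {
      inb <- abs(t - te) <= 1.1 * rhat
      rnew <- max(radial[inb])
      if (abs(rnew - rhat) < 1e-9) break
      rhat <- rnew
    }
    t_ring <- te - sign_ * rhat
    cand <- which(abs(t - t_ring) <= 0.35 * rhat & radial >= 0.9 * rhat)
    if (length(cand) < n_points) cand <- which(abs(t - t_ring) <= 0.6 * rhat)
    # meshes built from latitude rings: restrict to the single circumference
    # nearest the target latitude when one holds enough points
    cl <- round((t[cand] - t_ring) / (0.02 * rhat))
    sizes <- table(cl)
    ok_cl <- as.numeric(names(sizes))[sizes >= n_points]
    if (length(ok_cl) > 0) {
      best_cl <- ok_cl[which.min(abs(ok_cl))]
      cand <- cand[cl == best_cl]
    }
    uv <- perp_basis(ax)
    rel <- sweep(V[cand, , drop = FALSE], 2, ctr)
    ang <- atan2(rel %*% uv$v, rel %*% uv$u)
    nominal <- 2 * pi * (seq_len(n_points) - 1) / n_points - pi
    idx <- vapply(nominal, function(a) {
      da <- abs(((ang - a + pi) %% (2 * pi)) - pi)
      # angular proximity dominates; off-latitude candidates are penalized
      cand[which.min(da + 0.5 * abs(t[cand] - t_ring) / rhat)]
    }, integer(1))
    list(ring = V[idx, , drop = FALSE], center = ctr + t_ring * ax)
  }
  lo <- pick_one(-1)
  hi <- pick_one(+1)
  out <- list(end1 = landmark_ring(lo$ring, bone_id = bone_id, end = "base"),
              end2 = landmark_ring(hi$ring, bone_id = bone_id, end = "head"))
  attr(out, "axis_points") <- rbind(end1 = lo$center, end2 = hi$center)
  out
}
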