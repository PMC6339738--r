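#' Grip scenario
#'
#' @param diameter_mm cylinder diameter (mm).
#' @param contact_tolerance_mm allowed gap/penetration between a phalanx's
#'   palmar surface line and the cylinder surface (mm); the default, 4 mm,
#'   covers the soft-tissue pad plus the chord sagitta of the longest phalanx
#'   at the mid-size grip.
#' @return A `grip_scenario`.
#' @export
grip_scenario <- function(diameter_mm, contact_tolerance_mm = 4) {
  if (!is.finite(diameter_mm) || diameter_mm <= 0)
    stop("invalid-geometry: diameter_mm must be positive")
  if (!is.finite(contact_tolerance_mm) || contact_tolerance_mm <= 0)
    stop("invalid-geometry: contact_tolerance_mm must be positive")
  structure(list(diameter_mm = diameter_mm,
                 contact_tolerance_mm = contact_tolerance_mm),
            class = "grip_scenario")
}

#' Flexion range-of-motion caps per finger
#'
#' Maximum flexion (deg) used to saturate the grip solver, from standard
#' normative range-of-motion values for the four fingers.
#'
#' @return Named list (finger) of named vectors (MP, PIP, DIP), degrees.
#' @export
default_rom_caps <- function() {
  list(index  = c(MP = 80, PIP = 104, DIP = 68),
       middle = c(MP = 85, PIP = 107, DIP = 70),
       ring   = c(MP = 87, PIP = 107, DIP = 66),
       small  = c(MP = 86, PIP = 104, DIP = 69))
}

# Soft tissue between bone surface and skin/cylinder, mm.
TISSUE_PAD_MM <- 3

# Half-arc turn contribution of a chord with half-length ratio x = L/(2*rho).
# asin inside the chord-feasible regime, C1 linear extension beyond it so the
# wrap measure stays defined and strictly increasing for arbitrarily tight
# cylinders.
half_arc <- function(x, gamma = pi / 3) {
  ifelse(x <= sin(gamma), asin(pmin(x, 1)), gamma + (x - sin(gamma)) / cos(gamma))
}

# Forward-kinematic planar joint positions for a chain at given angles.
# Returns matrix of joint positions (rows: MC base, MP, PIP, DIP, tip) in the
# flexion plane (x palmar, y proximal).
chain_points <- function(lengths, theta_deg) {
  cum <- cumsum(c(0, theta_deg))
  p <- matrix(0, 5, 2)
  for (k in 1:4) {
    d <- c(sin(deg2rad(cum[k])), -cos(deg2rad(cum[k])))
    p[k + 1, ] <- p[k, ] + lengths[k] * d
  }
  p
}

# Smallest cylinder the capped chain can still pin against the palm: the
# palmar clearance between the fully flexed fingertip and the palm plane.
min_feasible_diameter <- function(spec, rom) {
  L <- spec$segment_lengths[BONES]
  pts <- chain_points(L, rom[JOINTS])
  x_tip <- pts[5, 1]
  max(0, x_tip - 2 * (spec$shaft_radius + TISSUE_PAD_MM))
}

#' Solve the grip pose of one finger around a cylinder
#'
#' Deterministic closed-form wrap model standing in for a human subject.  The
#' bone-axis chain is treated as chords of a circle of radius
#' `diameter/2 + shaft_radius + tissue pad`; the flexion angle at each joint is
#' the sum of the half-arc angles of its two adjacent chords (the distal half
#' of the metacarpal participates in palm cupping), hard-saturated at the
#' finger's range-of-motion cap.  Angles are strictly decreasing in diameter
#' wherever the caps do not bind and non-increasing everywhere.
#'
#' @param spec a [finger_chain_spec()].
#' @param scenario a [grip_scenario()].
#' @param rom_caps per-joint saturation angles (deg); default from
#'   [default_rom_caps()].
#' @return A `pose_spec` for `spec$finger_id` with attribute `"contact"`: a
#'   data.frame flagging, per phalanx, whether it lies on the wrap circle
#'   (`"cylinder"`) or is flexion-limited against adjacent structures.
#' @export
solve_grip_pose <- function(spec, scenario,
                            rom_caps = default_rom_caps()[[spec$finger_id]]) {
  stopifnot(inherits(spec, "finger_chain_spec"), inherits(scenario, "grip_scenario"))
  dmin <- min_feasible_diameter(spec, rom_caps)
  if (scenario$diameter_mm < dmin)
    stop(sprintf(
      "infeasible-grip: diameter %.2f mm is below the minimum feasible diameter %.2f mm for finger '%s'",
      scenario$diameter_mm, dmin, spec$finger_id))

  rho <- scenario$diameter_mm / 2 + spec$shaft_radius + TISSUE_PAD_MM
  L <- spec$segment_lengths
  gamma <- pi / 3
  chord <- c(metacarpal = 0.5 * L[["metacarpal"]],  # distal half cups the palm
             proximal = L[["proximal"]],
             middle = L[["middle"]],
             distal = L[["distal"]])
  x <- chord / (2 * rho)
  beta <- half_arc(x, gamma)
  raw <- c(MP = rad2deg(beta[["metacarpal"]] + beta[["proximal"]]),
           PIP = rad2deg(beta[["proximal"]] + beta[["middle"]]),
           DIP = rad2deg(beta[["middle"]] + beta[["distal"]]))
  ang <- pmin(raw, rom_caps[names(raw)])

  capped <- raw > rom_caps[names(raw)]
  on_circle <- c(
    proximal = !capped[["MP"]] && !capped[["PIP"]] && x[["proximal"]] <= sin(gamma),
    middle = !capped[["PIP"]] && !capped[["DIP"]] && x[["middle"]] <= sin(gamma),
    distal = !capped[["DIP"]] && x[["distal"]] <= sin(gamma))
  pose <- pose_spec_df(data.frame(finger = spec$finger_id,
                                  joint = JOINTS,
                                  angle_deg = unname(ang[JOINTS])))
  attr(pose, "contact") <- data.frame(
    phalanx = names(on_circle),
    regime = ifelse(on_circle, "cylinder", "flexion-limited"))
  attr(pose, "wrap_radius_mm") <- rho
  pose
}

#' Solve the grip pose for all four fingers
#'
#' @param specs named list of [finger_chain_spec()]s (default hand).
#' @param scenario a [grip_scenario()].
#' @param rom_caps named list of per-finger caps.
#' @return A combined `pose_spec` (12 rows).
#' @export
solve_grip_poses <- function(specs = default_hand_specs(), scenario,
                             rom_caps = default_rom_caps()) {
  poses <- lapply(specs, function(s)
    as.data.frame(solve_grip_pose(s, scenario, rom_caps[[s$finger_id]])))
  pose_spec_df(do.call(rbind, c(poses, make.row.names = FALSE)))
}

#' Contact residuals of a solved grip
#'
#' For every phalanx flagged as lying on the wrap circle, the signed distance
#' (mm) from sample points on its palmar bone-surface line (axis endpoints and
#' midpoint, offset by the shaft radius) to the cylinder surface, after
#' placing the cylinder center by least squares on the on-circle joint
#' positions.  Positive values are gaps (soft-tissue pad), negative values
#' penetration (pulp compression).
#'
#' @param spec a [finger_chain_spec()].
#' @param pose the `pose_spec` returned by [solve_grip_pose()].
#' @param scenario the matching [grip_scenario()].
#' @return data.frame with columns `phalanx`, `point`, `residual_mm`.
#' @export
grip_contact_residuals <- function(spec, pose, scenario) {
  contact <- attr(pose, "contact")
  rho <- attr(pose, "wrap_radius_mm")
  if (is.null(contact) || is.null(rho))
    stop("pose must come from solve_grip_pose()")
  onc <- contact$phalanx[contact$regime == "cylinder"]
  if (length(onc) == 0)
    return(data.frame(phalanx = character(), point = character(),
                      residual_mm = numeric()))
  ang <- pose$angle_deg[match(JOINTS, pose$joint)]
  pts <- chain_points(spec$segment_lengths[BONES], ang)
  rownames(pts) <- c("mc_base", "MP", "PIP", "DIP", "tip")
  seg_ends <- list(proximal = c("MP", "PIP"), middle = c("PIP", "DIP"),
                   distal = c("DIP", "tip"))
  joint_pts <- unique(unlist(seg_ends[onc]))
  P <- pts[joint_pts, , drop = FALSE]

  # Gauss-Newton fit of the circle center (radius fixed at rho), initialized
  # from the circle of radius rho through the two extreme on-circle joints
  p1 <- P[1, ]; p2 <- P[nrow(P), ]
  mid <- (p1 + p2) / 2
  half <- vnorm(p2 - p1) / 2
  ctr <- if (half < rho) {
    perp <- unitv(c(-(p2 - p1)[2], (p2 - p1)[1]))
    cand <- rbind(mid + sqrt(rho^2 - half^2) * perp,
                  mid - sqrt(rho^2 - half^2) * perp)
    score <- apply(cand, 1, function(cc)
      sum((sqrt(rowSums((P - matrix(cc, nrow(P), 2, byrow = TRUE))^2)) - rho)^2))
    cand[which.min(score), ]
  } else colMeans(P) + c(rho, 0)
  for (it in 1:50) {
    d <- sqrt(rowSums((P - matrix(ctr, nrow(P), 2, byrow = TRUE))^2))
    r <- d - rho
    J <- (P - matrix(ctr, nrow(P), 2, byrow = TRUE)) / d  # d resid / d P = -J
    step <- tryCatch(solve(crossprod(J), crossprod(J, r)), error = function(e) NULL)
    if (is.null(step)) break
    ctr <- ctr - as.numeric(step)
    if (max(abs(step)) < 1e-12) break
  }

  R_cyl <- scenario$diameter_mm / 2
  out <- do.call(rbind, lapply(onc, function(ph) {
    e <- seg_ends[[ph]]
    samp <- rbind(pts[e[1], ], (pts[e[1], ] + pts[e[2], ]) / 2, pts[e[2], ])
    d <- sqrt(rowSums((samp - matrix(ctr, 3, 2, byrow = TRUE))^2))
    data.frame(phalanx = ph, point = c("base", "mid", "head"),
               residual_mm = d - spec$shaft_radius - R_cyl)
  }))
  rownames(out) <- NULL
  out
}
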