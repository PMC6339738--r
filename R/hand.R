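FINGERS <- c("index", "middle", "ring", "small")
BONES <- c("metacarpal", "proximal", "middle", "distal")
JOINTS <- c("MP", "PIP", "DIP")

#' Finger chain specification
#'
#' Segment lengths and cap radii for one finger ray (metacarpal + three
#' phalanges).
#'
#' @param finger_id one of `"index"`, `"middle"`, `"ring"`, `"small"`.
#' @param segment_lengths named numeric vector (mm) with entries
#'   `metacarpal`, `proximal`, `middle`, `distal`.
#' @param shaft_radius shaft radius (mm), common to the ray's bones.
#' @param end_radii named list: for each bone, a numeric vector
#'   `c(base = , head = )` of cap radii (mm).
#' @return A `finger_chain_spec`.
#' @export
finger_chain_spec <- function(finger_id, segment_lengths, shaft_radius, end_radii) {
  finger_id <- match.arg(finger_id, FINGERS)
  if (!all(BONES %in% names(segment_lengths)))
    stop("segment_lengths must name all of: ", paste(BONES, collapse = ", "))
  segment_lengths <- segment_lengths[BONES]
  radii <- unlist(end_radii)
  if (any(segment_lengths <= 0) || shaft_radius <= 0 || any(radii <= 0))
    stop("all lengths and radii must be positive")
  if (!(segment_lengths["distal"] < segment_lengths["proximal"] &&
        segment_lengths["proximal"] < segment_lengths["metacarpal"]))
    stop("segment lengths must satisfy distal < proximal < metacarpal")
  if (!all(BONES %in% names(end_radii)))
    stop("end_radii must name all of: ", paste(BONES, collapse = ", "))
  structure(list(finger_id = finger_id,
                 segment_lengths = segment_lengths,
                 shaft_radius = shaft_radius,
                 end_radii = end_radii[BONES]),
            class = "finger_chain_spec")
}

#' Default anthropometric hand
#'
#' Chain specs for the four fingers, scaled from a nominal hand length of
#' 185.8 mm (mean adult male hand length of the reference cohort) using
#' standard phalangeal proportions.
#'
#' @param hand_length_mm hand length, middle fingertip to wrist crease (mm).
#' @return Named list of four `finger_chain_spec` objects.
#' @export
default_hand_specs <- function(hand_length_mm = 185.8) {
  s <- hand_length_mm / 185.8
  dims <- list(
    index  = list(len = c(metacarpal = 68, proximal = 39, middle = 22, distal = 16), shaft = 4.0),
    middle = list(len = c(metacarpal = 65, proximal = 42, middle = 26, distal = 17), shaft = 4.2),
    ring   = list(len = c(metacarpal = 58, proximal = 39, middle = 25, distal = 17), shaft = 4.0),
    small  = list(len = c(metacarpal = 54, proximal = 31, middle = 19, distal = 15), shaft = 3.5)
  )
  cap <- list(metacarpal = c(base = 7.0, head = 6.5),
              proximal   = c(base = 6.0, head = 5.0),
              middle     = c(base = 5.0, head = 4.5),
              distal     = c(base = 4.5, head = 4.0))
  out <- lapply(FINGERS, function(f) {
    k <- dims[[f]]$shaft / 4.0
    finger_chain_spec(f,
                      segment_lengths = dims[[f]]$len * s,
                      shaft_radius = dims[[f]]$shaft * s,
                      end_radii = lapply(cap, function(r) pmax(r * k, dims[[f]]$shaft) * s))
  })
  names(out) <- FINGERS
  out
}

#' Pose specification
#'
#' Flexion angles per (finger, joint) in degrees, one row per combination.
#'
#' @param df data.frame with columns `finger`, `joint`, `angle_deg`.
#' @return A `pose_spec` data.frame.
#' @export
pose_spec_df <- function(df) {
  stopifnot(all(c("finger", "joint", "angle_deg") %in% names(df)))
  if (any(df$angle_deg < 0 | df$angle_deg >= 180))
    stop("flexion angles must lie in [0, 180)")
  structure(df[c("finger", "joint", "angle_deg")], class = c("pose_spec", "data.frame"))
}

#' @rdname pose_spec_df
#' @param mp,pip,dip flexion angles (deg) applied to every finger.
#' @export
pose_uniform <- function(mp, pip, dip) {
  df <- expand.grid(finger = FINGERS, joint = JOINTS,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$angle_deg <- c(MP = mp, PIP = pip, DIP = dip)[df$joint]
  pose_spec_df(df)
}

#' Hand coordinate frame
#'
#' Origin at the dorsal concavity of the capitate; y proximal-positive along
#' the third metacarpal, x palmar-positive, z completing the triad.
#'
#' @param origin,x_axis,y_axis,z_axis origin point and unit axes.
#' @return A `hand_frame`.
#' @export
hand_frame <- function(origin = c(0, 0, 0),
                       x_axis = c(1, 0, 0),
                       y_axis = c(0, 1, 0),
                       z_axis = c(0, 0, 1)) {
  M <- cbind(x_axis, y_axis, z_axis)
  if (max(abs(t(M) %*% M - diag(3))) > 1e-9)
    stop("frame-construction error: axes are not orthonormal")
  structure(list(origin = origin, x_axis = x_axis,
                 y_axis = y_axis, z_axis = z_axis),
            class = "hand_frame")
}

#' @export
print.hand_frame <- function(x, ...) {
  cat(sprintf("<hand_frame: origin (%.2f, %.2f, %.2f)>\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Build the hand coordinate frame from anatomical references
#'
#' y is the unit vector from the third-metacarpal head center to its base
#' center (proximal positive), x the component of the palmar reference
#' direction orthogonal to y (palmar positive), z completes the right-handed
#' triad.
#'
#' @param capitate_point frame origin: dorsal concavity of the capitate (mm).
#' @param mc3_base_center,mc3_head_center centers of the third metacarpal's
#'   proximal base and distal head.
#' @param palmar_reference any point on the palmar side, off the y-axis line.
#' @return A `hand_frame`.
#' @export
build_hand_frame <- function(capitate_point, mc3_base_center, mc3_head_center,
                             palmar_reference) {
  if (vnorm(mc3_base_center - mc3_head_center) < 1e-9)
    stop("frame-construction error: metacarpal centers coincide")
  y <- unitv(mc3_base_center - mc3_head_center)
  p <- palmar_reference - capitate_point
  px <- p - sum(p * y) * y
  if (vnorm(px) < 1e-9)
    stop("frame-construction error: palmar reference lies on the y-axis line")
  x <- unitv(px)
  z <- c(x[2] * y[3] - x[3] * y[2],
         x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  hand_frame(origin = capitate_point, x_axis = x, y_axis = y, z_axis = z)
}

# Lateral (z) offset of each finger ray's metacarpal base, mm at 185.8 mm hand.
finger_root_offset <- function(finger_id, hand_length_mm = 185.8) {
  off <- c(index = 24, middle = 8, ring = -8, small = -24)
  c(0, -10, off[[finger_id]]) * hand_length_mm / 185.8
}

#' Pose a finger chain by forward kinematics
#'
#' Places the four bones of one finger ray in hand coordinates.  Flexion is
#' planar about the frame's z-parallel axis: the metacarpal points distally
#' (-y) and each joint rotates the next bone toward the palm (+x) by its
#' flexion angle.
#'
#' @param spec a [finger_chain_spec()].
#' @param pose a `pose_spec` containing MP/PIP/DIP for `spec$finger_id`.
#' @param frame a [hand_frame()].
#' @param include_mesh build capsule meshes (set `FALSE` for fast
#'   center-only chains).
#' @param resolution mesh resolution passed to [make_phalanx_mesh()].
#' @return List of four `bone_placement`s in chain order
#'   (metacarpal, proximal, middle, distal).
#' @export
pose_finger_chain <- function(spec, pose, frame = hand_frame(),
                              include_mesh = TRUE, resolution = 32) {
  stopifnot(inherits(spec, "finger_chain_spec"))
  ang <- pose[pose$finger == spec$finger_id, ]
  if (!all(JOINTS %in% ang$joint))
    stop(sprintf("incomplete-pose: finger '%s' needs MP, PIP and DIP angles",
                 spec$finger_id))
  theta <- stats::setNames(ang$angle_deg[match(JOINTS, ang$joint)], JOINTS)

  Mf <- cbind(frame$x_axis, frame$y_axis, frame$z_axis)  # frame -> world
  base <- frame$origin + as.numeric(Mf %*% finger_root_offset(spec$finger_id))
  cum <- cumsum(c(0, theta))                  # metacarpal, then +MP, +PIP, +DIP
  out <- vector("list", 4)
  for (k in seq_along(BONES)) {
    bone <- BONES[k]
    L <- spec$segment_lengths[[bone]]
    d_local <- as.numeric(rot_z(cum[k]) %*% c(0, -1, 0))
    d <- as.numeric(Mf %*% d_local)
    if (include_mesh) {
      pl <- make_phalanx_mesh(L, spec$shaft_radius,
                              spec$end_radii[[bone]][["base"]],
                              spec$end_radii[[bone]][["head"]],
                              resolution = resolution,
                              bone_id = c(spec$finger_id, bone))
    } else {
      pl <- structure(list(bone_id = c(spec$finger_id, bone), mesh = NULL,
                           true_base_center = c(0, 0, 0),
                           true_head_center = c(0, L, 0),
                           length = L,
                           shaft_radius = spec$shaft_radius,
                           base_radius = spec$end_radii[[bone]][["base"]],
                           head_radius = spec$end_radii[[bone]][["head"]]),
                      class = "bone_placement")
    }
    out[[k]] <- transform_placement(pl, rotation_between(c(0, 1, 0), d), base)
    base <- out[[k]]$true_head_center
  }
  names(out) <- BONES
  out
}
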