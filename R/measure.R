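#' Measure all finger joint angles from landmark rings
#'
#' For each finger, builds the four bone axes from base/head ring centers and
#' returns the three joint flexion angles: MP between metacarpal and proximal
#' axes, PIP between proximal and middle, DIP between middle and distal.
#' Fingers with missing bone rings yield explicit missing-data records rather
#' than being dropped, so downstream balanced-design checks can refuse them.
#'
#' @param rings nested list: `rings[[finger]][[bone]]` is a list with elements
#'   `base` and `head`, each a [landmark_ring()] (see [rings_from_df()] for
#'   the CSV-shaped alternative).
#' @param subject,diameter_mm identifiers copied into the output records.
#' @param method center estimator, see [estimate_center()].
#' @return data.frame with 12 rows and columns `subject`, `diameter_mm`,
#'   `finger`, `joint`, `angle_deg`, `status` (`"ok"` or `"missing-data"`).
#' @export
measure_hand <- function(rings, subject = NA, diameter_mm = NA,
                         method = "centroid") {
  rows <- lapply(FINGERS, function(f) {
    fr <- rings[[f]]
    complete <- !is.null(fr) && all(vapply(BONES, function(b)
      !is.null(fr[[b]]$base) && !is.null(fr[[b]]$head), logical(1)))
    if (!complete) {
      return(data.frame(subject = subject, diameter_mm = diameter_mm,
                        finger = f, joint = JOINTS, angle_deg = NA_real_,
                        status = "missing-data"))
    }
    axes <- lapply(BONES, function(b) bone_axis(fr[[b]]$base, fr[[b]]$head, method))
    names(axes) <- BONES
    ang <- c(MP = flexion_angle(axes$metacarpal, axes$proximal),
             PIP = flexion_angle(axes$proximal, axes$middle),
             DIP = flexion_angle(axes$middle, axes$distal))
    data.frame(subject = subject, diameter_mm = diameter_mm,
               finger = f, joint = JOINTS, angle_deg = unname(ang[JOINTS]),
               status = "ok")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample landmark rings for a whole posed hand
#'
#' Poses each finger chain and samples base/head rings on every bone under
#' the stated landmark noise model.
#'
#' @param specs named list of [finger_chain_spec()]s.
#' @param pose a `pose_spec` for all four fingers.
#' @param frame a [hand_frame()].
#' @param n_points,angular_jitter_deg,radial_noise_mm see
#'   [sample_landmark_ring()].
#' @param seed integer; per-ring seeds are derived deterministically from it.
#' @return Nested ring list as consumed by [measure_hand()].
#' @export
sample_hand_rings <- function(specs, pose, frame = hand_frame(),
                              n_points = 8, angular_jitter_deg = 10,
                              radial_noise_mm = 0.2, seed = 1L) {
  out <- list()
  for (fi in seq_along(FINGERS)) {
    f <- FINGERS[fi]
    chain <- pose_finger_chain(specs[[f]], pose, frame, include_mesh = FALSE)
    out[[f]] <- list()
    for (bi in seq_along(BONES)) {
      b <- BONES[bi]
      s0 <- seed + 1000L * fi + 10L * bi
      out[[f]][[b]] <- list(
        base = sample_landmark_ring(chain[[b]], "base", n_points,
                                    angular_jitter_deg, radial_noise_mm,
                                    seed = s0),
        head = sample_landmark_ring(chain[[b]], "head", n_points,
                                    angular_jitter_deg, radial_noise_mm,
                                    seed = s0 + 1L))
    }
  }
  out
}

#' Convert a ring list to/from the flat CSV schema
#'
#' The interchange schema has one row per picked point:
#' `bone_id,end,point_index,x_mm,y_mm,z_mm` with `bone_id` of the form
#' `finger_bone` (e.g. `index_distal`).
#'
#' @param rings nested ring list as consumed by [measure_hand()].
#' @return data.frame in the interchange schema.
#' @export
rings_to_df <- function(rings) {
  rows <- list()
  for (f in names(rings)) for (b in names(rings[[f]])) for (e in c("base", "head")) {
    r <- rings[[f]][[b]][[e]]
    if (is.null(r)) next
    rows[[length(rows) + 1]] <- data.frame(
      bone_id = paste(f, b, sep = "_"), end = e,
      point_index = seq_len(nrow(r$points)),
      x_mm = r$points[, 1], y_mm = r$points[, 2], z_mm = r$points[, 3])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname rings_to_df
#' @param df data.frame in the interchange schema.
#' @export
rings_from_df <- function(df) {
  need <- c("bone_id", "end", "point_index", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("ring data.frame must have columns: ", paste(need, collapse = ","))
  out <- list()
  for (id in unique(df$bone_id)) {
    parts <- strsplit(id, "_", fixed = TRUE)[[1]]
    f <- parts[1]; b <- parts[2]
    for (e in unique(df$end[df$bone_id == id])) {
      sub <- df[df$bone_id == id & df$end == e, ]
      sub <- sub[order(sub$point_index), ]
      out[[f]][[b]][[e]] <- landmark_ring(as.matrix(sub[c("x_mm", "y_mm", "z_mm")]),
                                          bone_id = c(f, b), end = e)
    }
  }
  out
}
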