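#' Synthetic cohort specification
#'
#' Parameters for simulating a balanced within-subject cohort of joint angles
#' from per-cell means and SDs: each subject carries a standard-normal latent
#' intercept scaled by `subject_sd_fraction` of the cell SD, the residual
#' takes the remaining variance share, so the marginal per-cell SD equals the
#' stated cell SD.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param cells data.frame with columns `diameter_mm`, `finger`, `joint`,
#'   `mean_deg`, `sd_deg`; defaults to the published cells,
#'   [grip_cell_parameters()].
#' @param subject_sd_fraction share of the cell SD assigned to the
#'   subject-level intercept, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10, cells = grip_cell_parameters(),
                        subject_sd_fraction = 0.5, seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  if (any(cells$sd_deg < 0)) stop("cell SDs must be non-negative")
  if (subject_sd_fraction < 0 || subject_sd_fraction > 1)
    stop("subject_sd_fraction must lie in [0, 1]")
  need <- expand.grid(diameter_mm = unique(cells$diameter_mm),
                      finger = unique(cells$finger),
                      joint = unique(cells$joint),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$diameter_mm, d$finger, d$joint)
  missing <- setdiff(key(need), key(cells))
  if (length(missing) > 0)
    stop("incomplete-spec: missing cells: ", paste(missing, collapse = "; "))
  structure(list(n_subjects = as.integer(n_subjects), cells = cells,
                 subject_sd_fraction = subject_sd_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a balanced cohort of joint angle records
#'
#' Generates `n_subjects x diameters x fingers x joints` records:
#' `angle = cell mean + f * cell SD * z_subject + sqrt(1 - f^2) * cell SD * e`,
#' with `z_subject` a per-subject standard normal shared across cells and `e`
#' iid standard normal, clipped to `[0, 180)`.  Deterministic for a fixed
#' spec seed; the global RNG state is left untouched.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `subject`, `diameter_mm`, `finger`,
#'   `joint`, `angle_deg`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  f <- spec$subject_sd_fraction
  cells <- spec$cells
  with_seed(spec$seed, {
    z <- stats::rnorm(n)
    rows <- do.call(rbind, lapply(seq_len(n), function(s) {
      e <- stats::rnorm(nrow(cells))
      ang <- cells$mean_deg + f * cells$sd_deg * z[s] +
        sqrt(1 - f^2) * cells$sd_deg * e
      data.frame(subject = sprintf("S%02d", s),
                 diameter_mm = cells$diameter_mm,
                 finger = cells$finger,
                 joint = cells$joint,
                 angle_deg = pmin(pmax(ang, 0), 180 - 1e-9))
    }))
    rownames(rows) <- NULL
    rows
  })
}
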