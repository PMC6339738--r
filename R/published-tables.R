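# Published summary statistics from the reference CT grip study (10 adult
# male subjects, cylinders of 10/60/120 mm).  The raw per-subject angles were
# never released, so these cell statistics are the study conditions the
# cohort simulator reproduces and the arithmetic the consistency checks
# recompute.

#' Published per-cell flexion angle means and SDs
#'
#' Mean and standard deviation of the flexion angle (deg) for every
#' diameter x finger x joint cell of the reference cohort; these parameterize
#' [simulate_cohort()].
#'
#' @return data.frame with columns `diameter_mm`, `finger`, `joint`,
#'   `mean_deg`, `sd_deg` (36 rows).
#' @export
grip_cell_parameters <- function() {
  tab <- rbind(
    # diameter, finger, DIP mean, DIP sd, PIP mean, PIP sd, MP mean, MP sd
    c(10, "index", 48.2, 22.7, 105.5, 9.2, 65.6, 7.9),
    c(10, "middle", 64.8, 16.4, 104.8, 9.8, 75.9, 5.5),
    c(10, "ring", 57.2, 16.8, 110.5, 6.1, 76.6, 14.9),
    c(10, "small", 65.8, 8.9, 93.0, 13.3, 64.1, 12.1),
    c(60, "index", 35.2, 6.8, 48.0, 7.7, 39.7, 11.8),
    c(60, "middle", 34.5, 7.5, 48.1, 8.1, 46.3, 15.4),
    c(60, "ring", 27.1, 7.1, 48.7, 6.8, 38.7, 12.5),
    c(60, "small", 30.0, 9.6, 32.8, 11.3, 35.2, 15.9),
    c(120, "index", 18.9, 6.1, 24.2, 6.5, 32.2, 5.5),
    c(120, "middle", 20.0, 12.0, 25.9, 6.7, 22.9, 10.3),
    c(120, "ring", 16.1, 6.4, 24.7, 9.1, 15.1, 8.5),
    c(120, "small", 11.9, 5.3, 15.2, 5.2, 12.6, 5.7))
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    data.frame(diameter_mm = as.numeric(tab[i, 1]),
               finger = tab[i, 2],
               joint = c("DIP", "PIP", "MP"),
               mean_deg = as.numeric(tab[i, c(3, 5, 7)]),
               sd_deg = as.numeric(tab[i, c(4, 6, 8)]))
  }))
  rownames(out) <- NULL
  out
}

#' Published three-way ANOVA table of the reference study
#'
#' Source, degrees of freedom (Greenhouse-Geisser corrected where sphericity
#' was rejected), Type III sums of squares, mean squares and F of the
#' three-way repeated-measures ANOVA (diameter x finger x joint) on the
#' flexion angle.
#'
#' @return data.frame with columns `source`, `df`, `type_iii_ss`,
#'   `mean_square`, `f_value`.
#' @export
published_anova_table <- function() {
  data.frame(
    source = c("A", "B", "C", "A:B", "A:C", "B:C", "A:B:C"),
    df = c(1.149, 3, 2, 6, 2.301, 6, 12),
    type_iii_ss = c(207673.697, 4014.324, 26868.242, 2151.941,
                    19652.346, 2653.076, 2488.546),
    mean_square = c(180797.809, 1338.108, 13434.121, 358.657,
                    8542.455, 442.179, 207.379),
    f_value = c(1025.177, 27.279, 28.683, 12.524, 23.408, 6.792, 3.036))
}

#' Published coupling-ratio cells
#'
#' Per diameter x finger mean (SD) of the coupling ratio DIP/PIP in the
#' reference cohort; the published marginals are equal-weight means of these
#' cells, which [summarize_cr()] reproduces on balanced data.
#'
#' @return data.frame with columns `diameter_mm`, `finger`, `mean`, `sd`.
#' @export
published_cr_cells <- function() {
  data.frame(
    diameter_mm = rep(c(10, 60, 120), each = 4),
    finger = rep(c("index", "middle", "ring", "small"), 3),
    mean = c(0.47, 0.62, 0.52, 0.73,
             0.77, 0.75, 0.58, 1.10,
             0.85, 0.96, 0.73, 0.97),
    sd = c(0.24, 0.16, 0.16, 0.18,
           0.29, 0.26, 0.21, 0.67,
           0.41, 0.98, 0.44, 0.67))
}
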