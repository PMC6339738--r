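#' Coupling ratio
#'
#' Ratio of the DIP and PIP flexion angles of one finger for one subject and
#' grip.  Defined only for positive PIP flexion.
#'
#' @param dip_deg,pip_deg flexion angles (deg); vectorized.
#' @return `dip_deg / pip_deg`.
#' @export
coupling_ratio <- function(dip_deg, pip_deg) {
  if (any(pip_deg <= 0))
    stop("undefined-ratio: coupling ratio requires PIP flexion > 0")
  dip_deg / pip_deg
}

#' Per-subject coupling ratio records
#'
#' Computes one CR per subject x diameter x finger from long-format joint
#' angle records (mean-of-ratios convention: the ratio is taken per subject
#' first and only then averaged by [summarize_cr()]).  Records whose PIP is
#' not positive are flagged, not dropped.
#'
#' @param records data.frame with columns `subject`, `diameter_mm`, `finger`,
#'   `joint`, `angle_deg` containing DIP and PIP rows.
#' @return data.frame with columns `subject`, `diameter_mm`, `finger`, `cr`,
#'   `status`.
#' @export
cr_records <- function(records) {
  dip <- records[records$joint == "DIP", ]
  pip <- records[records$joint == "PIP", ]
  key <- function(d) paste(d$subject, d$diameter_mm, d$finger)
  m <- match(key(dip), key(pip))
  if (any(is.na(m)))
    stop("incomplete-design: DIP records without matching PIP records")
  ok <- pip$angle_deg[m] > 0
  data.frame(subject = dip$subject, diameter_mm = dip$diameter_mm,
             finger = dip$finger,
             cr = ifelse(ok, dip$angle_deg / pip$angle_deg[m], NA_real_),
             status = ifelse(ok, "ok", "undefined-ratio"))
}

check_balanced <- function(records, factors) {
  cells <- expand.grid(lapply(factors, function(f) unique(records[[f]])),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(cells) <- factors
  counts <- vapply(seq_len(nrow(cells)), function(i) {
    sel <- rep(TRUE, nrow(records))
    for (f in factors) sel <- sel & records[[f]] == cells[[f]][i]
    length(unique(records$subject[sel]))
  }, integer(1))
  if (any(counts == 0)) {
    bad <- cells[counts == 0, , drop = FALSE]
    stop("incomplete-design: empty cell(s): ",
         paste(apply(bad, 1, paste, collapse = "/"), collapse = "; "))
  }
  if (length(unique(counts)) != 1)
    stop("incomplete-design: unequal subject counts across cells")
  counts[1]
}

#' Summarize joint angles per cell
#'
#' Per diameter x finger x joint cell mean and sample SD (n-1 denominator) of
#' the flexion angle, diameter-major ordering.
#'
#' @param records long-format angle records (`subject`, `diameter_mm`,
#'   `finger`, `joint`, `angle_deg`), balanced.
#' @return data.frame of class `angle_summary` with `diameter_mm`, `finger`,
#'   `joint`, `mean`, `sd`, `n`.
#' @export
summarize_angles <- function(records) {
  if (any(is.na(records$angle_deg)))
    stop("incomplete-design: missing-data records present")
  n <- check_balanced(records, c("diameter_mm", "finger", "joint"))
  agg <- stats::aggregate(angle_deg ~ diameter_mm + finger + joint, records,
                   function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x)))
  out <- data.frame(agg[c("diameter_mm", "finger", "joint")],
                    mean = agg$angle_deg[, "mean"],
                    sd = ifelse(agg$angle_deg[, "n"] > 1, agg$angle_deg[, "sd"], 0),
                    n = as.integer(agg$angle_deg[, "n"]))
  fo <- intersect(FINGERS, unique(out$finger))
  jo <- intersect(c("DIP", "PIP", "MP"), unique(out$joint))
  out <- out[order(out$diameter_mm,
                   match(out$finger, fo), match(out$joint, jo)), ]
  rownames(out) <- NULL
  class(out) <- c("angle_summary", "data.frame")
  out
}

#' Summarize coupling ratios with marginals
#'
#' Per diameter x finger mean and sample SD of the per-subject CRs, plus
#' `"All"` marginal rows/columns.  Marginal means are equal-weight means of
#' the collapsed cells (valid because the design is balanced, where they
#' coincide with pooled means of cell means); marginal SDs are SDs of the
#' pooled records.
#'
#' @param crs output of [cr_records()], balanced, no undefined ratios.
#' @return data.frame of class `cr_summary` with `diameter`, `finger`,
#'   `mean`, `sd`, `n`; `diameter`/`finger` include `"All"`.
#' @export
summarize_cr <- function(crs) {
  if (any(is.na(crs$cr)))
    stop("undefined-ratio: flagged CR records present; resolve before summarizing")
  n <- check_balanced(crs, c("diameter_mm", "finger"))
  diams <- sort(unique(crs$diameter_mm))
  fo <- intersect(c(FINGERS, unique(crs$finger)), unique(crs$finger))
  cell <- function(sel_d, sel_f) {
    sel <- rep(TRUE, nrow(crs))
    if (!is.null(sel_d)) sel <- sel & crs$diameter_mm == sel_d
    if (!is.null(sel_f)) sel <- sel & crs$finger == sel_f
    crs$cr[sel]
  }
  cell_means <- outer(diams, fo, Vectorize(function(d, f) mean(cell(d, f))))
  rows <- list()
  add <- function(diameter, finger, m, s, nn)
    rows[[length(rows) + 1]] <<- data.frame(diameter = diameter, finger = finger,
                                            mean = m, sd = s, n = nn)
  for (i in seq_along(diams)) {
    for (j in seq_along(fo))
      add(as.character(diams[i]), fo[j], cell_means[i, j],
          stats::sd(cell(diams[i], fo[j])), n)
    add(as.character(diams[i]), "All", mean(cell_means[i, ]),
        stats::sd(cell(diams[i], NULL)), n * length(fo))
  }
  for (j in seq_along(fo))
    add("All", fo[j], mean(cell_means[, j]), stats::sd(cell(NULL, fo[j])),
        n * length(diams))
  add("All", "All", mean(cell_means), stats::sd(crs$cr), nrow(crs))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cr_summary", "data.frame")
  out
}

# p-value rendering convention of the published tables
format_p <- function(p) ifelse(p < 5e-4, "<0.0005", sprintf("%.3f", p))

#' Render a summary table as Markdown
#'
#' Angle cells as `mean (SD)` with 1 decimal, CR cells with 2 decimals,
#' mirroring the published table layouts.
#'
#' @param x an `angle_summary` or `cr_summary`.
#' @param ... unused.
#' @return Character vector of Markdown lines.
#' @export
render_markdown <- function(x, ...) UseMethod("render_markdown")

#' @export
render_markdown.angle_summary <- function(x, ...) {
  fo <- unique(x$finger); jo <- unique(x$joint)
  hdr <- paste0("| Diameter | ", paste(vapply(fo, function(f)
    paste(paste0(f, "/", jo), collapse = " | "), character(1)), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---|", 1 + length(fo) * length(jo)), collapse = ""))
  body <- vapply(unique(x$diameter_mm), function(d) {
    cells <- vapply(fo, function(f) paste(vapply(jo, function(j) {
      r <- x[x$diameter_mm == d & x$finger == f & x$joint == j, ]
      sprintf("%.1f (%.1f)", r$mean, r$sd)
    }, character(1)), collapse = " | "), character(1))
    paste0("| ", d, " mm | ", paste(cells, collapse = " | "), " |")
  }, character(1))
  c(hdr, sep, body)
}

#' @export
render_markdown.cr_summary <- function(x, ...) {
  fo <- unique(x$finger)
  hdr <- paste0("| Diameter | ", paste(fo, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---|", 1 + length(fo)), collapse = ""))
  body <- vapply(unique(x$diameter), function(d) {
    cells <- vapply(fo, function(f) {
      r <- x[x$diameter == d & x$finger == f, ]
      sprintf("%.2f (%.2f)", r$mean, r$sd)
    }, character(1))
    paste0("| ", if (d == "All") "All" else paste(d, "mm"), " | ",
           paste(cells, collapse = " | "), " |")
  }, character(1))
  c(hdr, sep, body)
}
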