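# Balanced fully-within-subject factorial ANOVA, written against the closed
# forms that hold for balanced crossed designs: every effect's Type III SS
# equals its sequential SS and is obtained from marginal means by
# inclusion-exclusion; every within effect is tested against its own
# effect x subject interaction.

# Reshape long data into an array with dim (subject, factor1, factor2, ...).
# Errors if the design is not perfectly balanced (one observation per cell).
long_to_array <- function(data, response, factors, subject = "subject") {
  for (v in c(subject, factors, response))
    if (!v %in% names(data)) stop("column not found: ", v)
  levs <- c(list(sort(unique(data[[subject]]))),
            lapply(factors, function(f) sort(unique(data[[f]]))))
  dims <- vapply(levs, length, integer(1))
  if (nrow(data) != prod(dims))
    stop("incomplete-design: expected ", prod(dims), " rows (one per subject x cell), got ",
         nrow(data))
  idx <- mapply(function(v, l) match(data[[v]], l),
                c(subject, factors), levs, SIMPLIFY = FALSE)
  pos <- as.matrix(as.data.frame(idx))
  if (anyDuplicated(pos))
    stop("incomplete-design: duplicated subject x cell observations")
  arr <- array(NA_real_, dim = dims)
  arr[pos] <- data[[response]]
  if (any(is.na(arr))) stop("incomplete-design: empty subject x cell combinations")
  dimnames(arr) <- levs
  names(dimnames(arr)) <- c(subject, factors)
  arr
}

# Marginal-mean array over the given dims (empty -> grand mean scalar).
marg_mean <- function(arr, dims) {
  if (length(dims) == 0) return(mean(arr))
  apply(arr, dims, mean)
}

all_subsets <- function(x) {
  if (length(x) == 1) return(list(x))   # combn treats a scalar as seq_len
  out <- list()
  for (m in seq_along(x)) out <- c(out, utils::combn(x, m, simplify = FALSE))
  out
}

# Sum of squares of the inclusion-exclusion effect estimate for dims `T`.
effect_ss <- function(arr, T_dims) {
  N <- length(arr)
  kT <- prod(dim(arr)[T_dims])
  subs <- c(list(integer(0)), all_subsets(T_dims))
  tot <- 0
  # accumulate the effect array on the T grid
  eff <- array(0, dim = dim(arr)[T_dims])
  for (U in subs) {
    m <- marg_mean(arr, U)
    sgn <- (-1)^(length(T_dims) - length(U))
    if (length(U) == 0) {
      eff <- eff + sgn * m
    } else {
      # broadcast marginal mean over the T grid
      perm_dims <- match(U, T_dims)
      g <- array(0, dim = dim(arr)[T_dims])
      idx_grid <- arrayInd(seq_len(length(g)), dim(g))
      mi <- idx_grid[, perm_dims, drop = FALSE]
      g[] <- m[mi]
      eff <- eff + sgn * g
    }
  }
  (N / kT) * sum(eff^2)
}

#' Degrees of freedom of a balanced within-subject factorial design
#'
#' Main-effect df is `k - 1`, interaction df the product of its factors'
#' `k - 1`, and each effect's error df is its own df times `n - 1`.
#'
#' @param factor_levels named integer vector of level counts, e.g.
#'   `c(A = 3, B = 4, C = 3)`.
#' @param n_subjects number of subjects.
#' @return data.frame with `source`, `df`, `error_df`.
#' @export
anova_dfs <- function(factor_levels, n_subjects) {
  if (any(factor_levels < 2) || n_subjects < 2)
    stop("all factor level counts and n_subjects must be at least 2")
  nm <- names(factor_levels)
  if (is.null(nm)) nm <- LETTERS[seq_along(factor_levels)]
  subs <- all_subsets(seq_along(factor_levels))
  subs <- subs[order(vapply(subs, length, integer(1)))]
  df <- vapply(subs, function(s) prod(factor_levels[s] - 1), numeric(1))
  data.frame(source = vapply(subs, function(s) paste(nm[s], collapse = ":"), character(1)),
             df = df,
             error_df = df * (n_subjects - 1))
}

# Orthonormal contrast matrix (k x (k-1)) for a k-level factor.
orth_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# Per-subject score matrix for a within effect: subjects x (levels of the
# effect's factor grid), averaged over the remaining factors, multiplied by
# the Kronecker product of the member factors' orthonormal contrasts.
effect_scores <- function(arr, eff_dims) {
  Y <- marg_mean(arr, c(1, eff_dims))           # subject x effect grid
  n <- dim(arr)[1]
  Y <- matrix(Y, nrow = n)                      # flatten grid column-major
  Cs <- lapply(rev(eff_dims), function(d) orth_contrasts(dim(arr)[d]))
  C <- Reduce(kronecker, Cs)
  Y %*% C
}

#' Mauchly's test of sphericity and the Greenhouse-Geisser epsilon
#'
#' Tests equality of the variances of all pairwise level differences of a
#' within effect via the orthonormal-contrast covariance matrix: Mauchly's
#' `W` is the ratio of the determinant to the power of the mean eigenvalue,
#' with the standard chi-square approximation; epsilon is the
#' Greenhouse-Geisser estimator, clamped to `[1/p, 1]` where `p` is the
#' effect df.  A two-level effect (p = 1) is vacuously spherical.  A singular
#' contrast covariance (fewer subjects than effect df + 1) is reported as the
#' `W = 0` boundary case with a warning and no test p-value.
#'
#' @param data long-format data.frame.
#' @param response response column name.
#' @param factors character vector of within-factor column names.
#' @param effect character vector naming the factors of the tested effect
#'   (one name for a main effect, several for an interaction).
#' @param subject subject column name.
#' @return List of class `sphericity_result`: `effect`, `mauchly_w`,
#'   `chi_square`, `df`, `p_value`, `epsilon_gg`.
#' @export
mauchly_test <- function(data, response, factors, effect, subject = "subject") {
  arr <- long_to_array(data, response, factors, subject)
  eff_dims <- match(effect, factors) + 1
  if (any(is.na(eff_dims))) stop("effect must name factors among: ",
                                 paste(factors, collapse = ", "))
  sphericity_from_scores(effect_scores(arr, eff_dims), paste(effect, collapse = ":"),
                         n = dim(arr)[1], p_orig = prod(dim(arr)[eff_dims]))
}

sphericity_from_scores <- function(D, effect_label, n, p_orig = ncol(D) + 1) {
  p <- ncol(D)
  if (p == 1) {
    return(structure(list(effect = effect_label, mauchly_w = 1,
                          chi_square = 0, df = 0, p_value = NA_real_,
                          epsilon_gg = 1), class = "sphericity_result"))
  }
  S <- stats::cov(D)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  eps <- sum(ev)^2 / (p * sum(ev^2))
  eps <- min(1, max(1 / p, eps))
  detS <- prod(ev)
  mean_ev <- mean(ev)
  singular <- (n - 1) < p || detS <= mean_ev^p * 1e-12
  if (singular) {
    warning("singular contrast covariance for effect '", effect_label,
            "': Mauchly W reported as 0 boundary case")
    return(structure(list(effect = effect_label, mauchly_w = 0,
                          chi_square = NA_real_, df = p * (p + 1) / 2 - 1,
                          p_value = NA_real_, epsilon_gg = eps),
                     class = "sphericity_result"))
  }
  W <- detS / mean_ev^p
  nu <- n - 1
  rho <- 1 - (2 * p^2 + p + 2) / (6 * p * nu)
  chi <- -nu * rho * log(W)
  dfc <- p * (p + 1) / 2 - 1
  # two-term asymptotic expansion (the standard Mauchly approximation)
  w2 <- (p + 2) * (p - 1) * (p - 2) * (2 * p^3 + 6 * p^2 + 3 * p_orig + 2) /
    (288 * (nu * p * rho)^2)
  pval <- stats::pchisq(chi, dfc, lower.tail = FALSE) +
    w2 * (stats::pchisq(chi, dfc + 4, lower.tail = FALSE) -
            stats::pchisq(chi, dfc, lower.tail = FALSE))
  structure(list(effect = effect_label, mauchly_w = W, chi_square = chi,
                 df = dfc, p_value = pval, epsilon_gg = eps),
            class = "sphericity_result")
}

#' @export
print.sphericity_result <- function(x, ...) {
  cat(sprintf("Mauchly sphericity, effect %s: W = %.4f, chi2(%g) = %s, p = %s; GG epsilon = %.4f\n",
              x$effect, x$mauchly_w, x$df,
              ifelse(is.na(x$chi_square), "NA", sprintf("%.3f", x$chi_square)),
              ifelse(is.na(x$p_value), "NA", format_p(x$p_value)), x$epsilon_gg))
  invisible(x)
}

#' Repeated-measures factorial ANOVA (balanced, fully within-subject)
#'
#' Type III sums of squares for every main effect and interaction (equal to
#' sequential SS in this balanced, fully crossed design), each tested against
#' its own effect x subject error term.  When `correction = "mauchly"`, any
#' effect with at least 3 levels whose Mauchly test rejects at `alpha` has
#' both its numerator and denominator df multiplied by the Greenhouse-Geisser
#' epsilon (which never decreases the p-value); effects whose contrast
#' covariance is singular cannot be tested and are left uncorrected.
#'
#' @param data long-format data.frame, fully balanced.
#' @param response response column name.
#' @param factors character vector of within-factor column names.
#' @param subject subject column name.
#' @param correction `"mauchly"` (gated Greenhouse-Geisser, default),
#'   `"none"`, or `"always"`.
#' @param alpha sphericity-gate level.
#' @return data.frame of class `rm_anova_table`: one row per effect with
#'   `source`, `df`, `error_df`, `type_iii_ss`, `error_ss`, `mean_square`,
#'   `error_ms`, `f_value`, `p_value`, `correction_applied`, `epsilon_gg`,
#'   `mauchly_w`, `mauchly_p`.  Attributes `ss_total`, `ss_subject` complete
#'   the decomposition.
#' @export
rm_anova <- function(data, response, factors, subject = "subject",
                     correction = c("mauchly", "none", "always"), alpha = 0.05) {
  correction <- match.arg(correction)
  arr <- long_to_array(data, response, factors, subject)
  n <- dim(arr)[1]
  if (n < 2) stop("incomplete-design: at least 2 subjects required")
  fdims <- seq_along(factors) + 1
  ss_total <- sum((arr - mean(arr))^2)
  zero_var <- ss_total < 1e-12 * max(1, mean(arr)^2)
  subs <- all_subsets(fdims)
  subs <- subs[order(vapply(subs, length, integer(1)))]

  rows <- lapply(subs, function(E) {
    lab <- paste(factors[E - 1], collapse = ":")
    ss <- effect_ss(arr, E)
    ss_err <- effect_ss(arr, c(1, E))
    df <- prod(dim(arr)[E] - 1)
    df_err <- df * (n - 1)
    sph <- if (df >= 2 && !zero_var)
      suppressWarnings(sphericity_from_scores(effect_scores(arr, E), lab, n,
                                              p_orig = prod(dim(arr)[E])))
    else NULL
    eps <- 1
    applied <- "none"
    if (!is.null(sph) && correction == "always") {
      eps <- sph$epsilon_gg; applied <- "greenhouse_geisser"
    } else if (!is.null(sph) && correction == "mauchly" &&
               !is.na(sph$p_value) && sph$p_value < alpha) {
      eps <- sph$epsilon_gg; applied <- "greenhouse_geisser"
    }
    df_c <- df * eps
    df_err_c <- df_err * eps
    f <- if (zero_var) NA_real_ else (ss / df_c) / (ss_err / df_err_c)
    p <- if (zero_var) NA_real_ else stats::pf(f, df_c, df_err_c, lower.tail = FALSE)
    data.frame(source = lab, df = df_c, error_df = df_err_c,
               type_iii_ss = ss, error_ss = ss_err,
               mean_square = ss / df_c, error_ms = ss_err / df_err_c,
               f_value = f, p_value = p,
               correction_applied = applied, epsilon_gg = eps,
               mauchly_w = if (is.null(sph)) NA_real_ else sph$mauchly_w,
               mauchly_p = if (is.null(sph)) NA_real_ else sph$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ss_total") <- ss_total
  attr(out, "ss_subject") <- effect_ss(arr, 1)
  attr(out, "n_subjects") <- n
  attr(out, "zero_variance") <- zero_var
  class(out) <- c("rm_anova_table", "data.frame")
  out
}

#' @export
print.rm_anova_table <- function(x, ...) {
  cat("Repeated-measures ANOVA (within-subject, balanced)\n")
  if (isTRUE(attr(x, "zero_variance")))
    cat("  [zero-variance response: F undefined]\n")
  df <- as.data.frame(x)
  df$p <- ifelse(is.na(df$p_value), "NA", format_p(df$p_value))
  df$corr <- ifelse(df$correction_applied == "greenhouse_geisser", "GG", "")
  print(data.frame(source = df$source, df = round(df$df, 3),
                   error_df = round(df$error_df, 3),
                   SS = round(df$type_iii_ss, 3), MS = round(df$mean_square, 3),
                   F = round(df$f_value, 3), p = df$p, correction = df$corr),
        row.names = FALSE)
  invisible(x)
}

#' Simple main effects of one factor at fixed levels of the others
#'
#' One-way repeated-measures ANOVA of `target` within each combination of the
#' remaining factors' levels, each using its own within-combination error
#' term (identical to running [rm_anova()] on the subset).
#'
#' @param data long-format data.frame, balanced.
#' @param response response column name.
#' @param target factor whose effect is tested.
#' @param within character vector of the other within-factor columns fixed to
#'   each of their level combinations.
#' @param subject subject column name.
#' @param ... passed to [rm_anova()] (correction, alpha).
#' @return data.frame: one row per fixed combination with the fixed levels,
#'   `df`, `error_df`, `type_iii_ss`, `f_value`, `p_value`,
#'   `correction_applied`.
#' @export
simple_main_effects <- function(data, response, target, within,
                                subject = "subject", ...) {
  combos <- expand.grid(lapply(within, function(f) sort(unique(data[[f]]))),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(combos) <- within
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- rep(TRUE, nrow(data))
    for (f in within) sel <- sel & data[[f]] == combos[[f]][i]
    if (!any(sel)) stop("missing-cell: no data at ",
                        paste(within, unlist(combos[i, ]), collapse = ", "))
    tab <- rm_anova(data[sel, , drop = FALSE], response, target, subject, ...)
    cbind(combos[i, , drop = FALSE],
          tab[c("df", "error_df", "type_iii_ss", "f_value", "p_value",
                "correction_applied")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected pairwise comparisons of a within factor
#'
#' Paired t-tests for every pair of `target` levels within one fixed
#' combination of the other factors; the Bonferroni family is the
#' `m = k(k-1)/2` comparisons within that combination
#' (`p_adj = min(1, m * p_raw)`).  The direction string is emitted only when
#' `p_adj < alpha`.
#'
#' @param data long-format data.frame, balanced.
#' @param response response column name.
#' @param target factor compared pairwise.
#' @param fixed named list of `factor = level` selections (may be empty).
#' @param alpha significance level for the direction string.
#' @param subject subject column name.
#' @param family `"within"` (default: m per fixed combination) or `"global"`
#'   (m multiplied by the number of fixed combinations in `n_combos`).
#' @param n_combos number of fixed combinations for the global family.
#' @return data.frame with `level_1`, `level_2`, `mean_diff`, `t`, `df`,
#'   `p_raw`, `p_bonferroni`, `direction` (`"n.s."` when not significant).
#' @export
bonferroni_pairwise <- function(data, response, target, fixed = list(),
                                alpha = 0.05, subject = "subject",
                                family = c("within", "global"), n_combos = 1) {
  family <- match.arg(family)
  sel <- rep(TRUE, nrow(data))
  for (f in names(fixed)) sel <- sel & data[[f]] == fixed[[f]]
  d <- data[sel, , drop = FALSE]
  levs <- sort(unique(d[[target]]))
  if (length(levs) < 2) stop("target factor needs at least 2 levels")
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  m <- length(pairs) * if (family == "global") n_combos else 1
  rows <- lapply(pairs, function(pr) {
    x <- d[d[[target]] == pr[1], ]
    y <- d[d[[target]] == pr[2], ]
    x <- stats::aggregate(x[[response]], list(subject = x[[subject]]), mean)
    y <- stats::aggregate(y[[response]], list(subject = y[[subject]]), mean)
    if (nrow(x) < 2 || !identical(x$subject, y$subject))
      stop("insufficient-data: paired comparisons need >= 2 common subjects")
    tt <- stats::t.test(x$x, y$x, paired = TRUE)
    p_adj <- min(1, m * tt$p.value)
    dirn <- if (p_adj < alpha) {
      if (tt$estimate > 0) paste(pr[1], ">", pr[2]) else paste(pr[2], ">", pr[1])
    } else "n.s."
    data.frame(level_1 = as.character(pr[1]), level_2 = as.character(pr[2]),
               mean_diff = unname(tt$estimate), t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value,
               p_bonferroni = p_adj, direction = dirn)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise comparison tables across all fixed combinations
#'
#' Runs [bonferroni_pairwise()] for every combination of the `within`
#' factors' levels, mirroring the published multiple-comparison tables.
#'
#' @inheritParams simple_main_effects
#' @param alpha significance level.
#' @return data.frame: fixed-combination columns plus the pairwise columns.
#' @export
pairwise_table <- function(data, response, target, within, alpha = 0.05,
                           subject = "subject") {
  combos <- expand.grid(lapply(within, function(f) sort(unique(data[[f]]))),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(combos) <- within
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    fixed <- as.list(combos[i, , drop = FALSE])
    cbind(combos[i, , drop = FALSE],
          bonferroni_pairwise(data, response, target, fixed, alpha, subject),
          row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
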