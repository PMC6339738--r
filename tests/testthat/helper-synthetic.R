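# Shared fixtures, all generated in code.

random_rotation <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# A regular n-gon of radius r centered at `center` in the plane spanned by
# u, v (defaults: z = const plane).
regular_ring <- function(center, r, n = 8, u = c(1, 0, 0), v = c(0, 1, 0)) {
  a <- 2 * pi * (seq_len(n) - 1) / n
  matrix(center, n, 3, byrow = TRUE) + r * (cos(a) %o% u + sin(a) %o% v)
}

# Long-format balanced within-subject dataset with iid N(0,1) response.
null_dataset <- function(n_subjects, levels, seed) {
  grids <- c(list(subject = sprintf("S%02d", seq_len(n_subjects))),
             lapply(seq_along(levels), function(i)
               paste0(names(levels)[i], seq_len(levels[i]))))
  names(grids)[-1] <- names(levels)
  d <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(seed)
  d$y <- rnorm(nrow(d))
  d
}

# aov() Error-strata oracle for a fully-within design, returns one row per
# effect: SS, error SS, F, p (uncorrected).
aov_oracle <- function(data, response, factors, subject = "subject") {
  d <- data
  d$.s <- factor(d[[subject]])
  for (f in factors) d[[f]] <- factor(d[[f]])
  fml <- stats::as.formula(paste(response, "~", paste(factors, collapse = "*"),
                                 "+ Error(.s/(", paste(factors, collapse = "*"), "))"))
  sm <- summary(stats::aov(fml, data = d))
  strata <- names(sm)[-1]                       # drop the subject stratum
  t(vapply(strata, function(nm) {
    x <- sm[[nm]][[1]]
    c(ss = x[1, "Sum Sq"], error_ss = x[2, "Sum Sq"],
      f = x[1, "F value"], p = x[1, "Pr(>F)"])
  }, numeric(4)))
}
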