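test_that("design degrees of freedom follow the balanced within-subject rules", {
  d3 <- anova_dfs(c(A = 3, B = 4, C = 3), 10)
  expect_equal(d3$df[d3$source == "A:B:C"], 12)
  expect_equal(d3$df[d3$source == "B"], 3)
  expect_equal(d3$df[d3$source == "A"], 2)
  expect_equal(d3$error_df[d3$source == "A"], 18)

  d2 <- anova_dfs(c(A = 3, B = 4), 10)
  expect_equal(d2$df[d2$source == "A:B"], 6)
  expect_equal(d2$error_df[d2$source == "A:B"], 54)

  d1 <- anova_dfs(c(A = 2), 2)
  expect_equal(d1$df, 1)
  expect_equal(d1$error_df, 1)
})

test_that("a constant response yields zero SS with F flagged undefined", {
  d <- null_dataset(4, c(A = 3, B = 2), seed = 1)
  d$y <- 7
  tab <- rm_anova(d, "y", c("A", "B"))
  expect_true(all(abs(tab$type_iii_ss) < 1e-18))
  expect_true(all(is.na(tab$f_value)))
  expect_true(all(is.na(tab$p_value)))
})

test_that("the full three-way table matches the aov error-strata oracle", {
  for (s in 1:5) {
    co <- simulate_cohort(cohort_spec(10, seed = 100 + s))
    tab <- rm_anova(co, "angle_deg", c("diameter_mm", "finger", "joint"),
                    correction = "none")
    oracle <- aov_oracle(co, "angle_deg", c("diameter_mm", "finger", "joint"))
    mine <- as.matrix(tab[c("type_iii_ss", "error_ss", "f_value", "p_value")])
    expect_lt(max(abs(mine - oracle) / pmax(abs(oracle), 1e-300)), 1e-8)
  }
})

test_that("the SS decomposition closes on any balanced dataset", {
  for (s in 1:5) {
    d <- null_dataset(6, c(A = 3, B = 4, C = 2), seed = 200 + s)
    tab <- rm_anova(d, "y", c("A", "B", "C"), correction = "none")
    total <- attr(tab, "ss_total")
    parts <- attr(tab, "ss_subject") + sum(tab$type_iii_ss) + sum(tab$error_ss)
    expect_lt(abs(total - parts) / total, 1e-8)
  }
})

test_that("Mauchly test matches stats::mauchly.test and two levels are vacuous", {
  fac <- c("diameter_mm", "finger", "joint")
  co <- simulate_cohort(cohort_spec(10, seed = 300))
  arr <- gripangle:::long_to_array(co, "angle_deg", fac)
  for (eff in list(2, 3, c(2, 3), c(2, 4))) {
    Y <- matrix(apply(arr, c(1, eff), mean), nrow = 10)
    C <- Reduce(kronecker, lapply(rev(eff), function(d)
      gripangle:::orth_contrasts(dim(arr)[d])))
    ref <- stats::mauchly.test(stats::lm(Y ~ 1), T = t(C))
    m <- mauchly_test(co, "angle_deg", fac, fac[eff - 1])
    expect_equal(m$mauchly_w, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(m$p_value, ref$p.value, tolerance = 1e-8)
  }

  d2 <- null_dataset(8, c(A = 2), seed = 4)
  m2 <- mauchly_test(d2, "y", "A", "A")
  expect_equal(m2$mauchly_w, 1)
  expect_equal(m2$epsilon_gg, 1)
  expect_equal(m2$df, 0)
})

test_that("Greenhouse-Geisser epsilon matches car and scales both df", {
  skip_if_not_installed("car")
  co <- simulate_cohort(cohort_spec(10, seed = 301))
  arr <- gripangle:::long_to_array(co, "angle_deg",
                                   c("diameter_mm", "finger", "joint"))
  Y <- matrix(apply(arr, c(1, 3), mean), nrow = 10)   # finger main effect
  idata <- data.frame(B = factor(dimnames(arr)[[3]]))
  av <- summary(car::Anova(stats::lm(Y ~ 1), idata = idata, idesign = ~B,
                           type = 3), multivariate = FALSE)
  m <- mauchly_test(co, "angle_deg", c("diameter_mm", "finger", "joint"),
                    "finger")
  expect_equal(m$epsilon_gg, unname(av$pval.adjustments["B", "GG eps"]),
               tolerance = 1e-8)
  expect_equal(m$mauchly_w, unname(av$sphericity.tests["B", 1]),
               tolerance = 1e-8)

  tab <- rm_anova(co, "angle_deg", c("diameter_mm", "finger", "joint"),
                  correction = "always")
  nominal <- anova_dfs(c(3, 4, 3), 10)
  corr <- tab$correction_applied == "greenhouse_geisser"
  expect_true(any(corr))
  expect_equal(tab$df[corr], (nominal$df * tab$epsilon_gg)[corr],
               tolerance = 1e-12)
  expect_equal(tab$error_df[corr], (nominal$error_df * tab$epsilon_gg)[corr],
               tolerance = 1e-12)
  # mean squares always equal SS / df on the reported (possibly corrected) df
  expect_equal(tab$mean_square, tab$type_iii_ss / tab$df, tolerance = 1e-9)
})

test_that("applying epsilon <= 1 never decreases the p-value", {
  for (s in 1:5) {
    co <- simulate_cohort(cohort_spec(10, seed = 400 + s))
    none <- rm_anova(co, "angle_deg", c("diameter_mm", "finger", "joint"),
                     correction = "none")
    gg <- rm_anova(co, "angle_deg", c("diameter_mm", "finger", "joint"),
                   correction = "always")
    expect_true(all(gg$p_value >= none$p_value - 1e-12))
  }
})

test_that("a singular contrast covariance is reported as the W = 0 boundary", {
  d <- null_dataset(5, c(A = 3, B = 4), seed = 7)   # effect df 6 > n - 1 = 4
  expect_warning(m <- mauchly_test(d, "y", c("A", "B"), c("A", "B")),
                 "singular")
  expect_equal(m$mauchly_w, 0)
  expect_true(is.na(m$p_value))
})

test_that("unbalanced data are refused with an incomplete-design error", {
  d <- null_dataset(6, c(A = 3, B = 2), seed = 9)
  expect_error(rm_anova(d[-1, ], "y", c("A", "B")), "incomplete-design")
  d2 <- d; d2$A[1] <- d2$A[7]
  expect_error(rm_anova(d2, "y", c("A", "B")), "incomplete-design")
})

test_that("simple main effects equal the ANOVA on each subset", {
  co <- simulate_cohort(cohort_spec(10, seed = 500))
  sme <- simple_main_effects(co, "angle_deg", "diameter_mm",
                             c("finger", "joint"), correction = "none")
  expect_equal(nrow(sme), 4 * 3)
  for (i in c(1, 5, 12)) {
    sub <- co[co$finger == sme$finger[i] & co$joint == sme$joint[i], ]
    ref <- rm_anova(sub, "angle_deg", "diameter_mm", correction = "none")
    expect_equal(sme$f_value[i], ref$f_value, tolerance = 1e-10)
    expect_equal(sme$p_value[i], ref$p_value, tolerance = 1e-10)
  }

  # identical cell means at one fixed combination -> F ~ 0
  flat <- co
  sel <- flat$finger == "index" & flat$joint == "DIP"
  v <- flat$angle_deg[sel]
  flat$angle_deg[sel] <- v - ave(v, flat$diameter_mm[sel]) + mean(v)
  sme2 <- simple_main_effects(flat, "angle_deg", "diameter_mm",
                              c("finger", "joint"), correction = "none")
  f0 <- sme2$f_value[sme2$finger == "index" & sme2$joint == "DIP"]
  expect_lt(f0, 1e-20)
})

test_that("Bonferroni adjustment multiplies and caps, and gates the direction string", {
  # arithmetic contract on a crafted dataset via the returned columns
  co <- simulate_cohort(cohort_spec(10, seed = 600))
  pw <- bonferroni_pairwise(co, "angle_deg", "diameter_mm",
                            fixed = list(finger = "index", joint = "DIP"))
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_bonferroni, pmin(1, 3 * pw$p_raw), tolerance = 1e-12)
  expect_true(all(pw$direction[pw$p_bonferroni >= 0.05] == "n.s."))
  sig <- pw$p_bonferroni < 0.05
  expect_true(all(grepl(">", pw$direction[sig])))

  # the cap rule
  same <- co
  set.seed(1)
  same$angle_deg <- rnorm(nrow(same))    # pure noise -> large p
  pw2 <- bonferroni_pairwise(same, "angle_deg", "diameter_mm",
                             fixed = list(finger = "index", joint = "DIP"))
  expect_true(all(pw2$p_bonferroni <= 1))
  expect_true(any(pw2$p_bonferroni == 1))

  one <- co[co$subject == "S01", ]
  expect_error(bonferroni_pairwise(one, "angle_deg", "diameter_mm",
                                   fixed = list(finger = "index", joint = "DIP")),
               "insufficient-data")
})

test_that("pairwise tables cover every fixed combination", {
  co <- simulate_cohort(cohort_spec(6, seed = 700))
  pt <- pairwise_table(co, "angle_deg", "diameter_mm", c("finger", "joint"))
  expect_equal(nrow(pt), 4 * 3 * 3)
  pt2 <- pairwise_table(co, "angle_deg", "finger", c("diameter_mm", "joint"))
  expect_equal(nrow(pt2), 3 * 3 * 6)
})
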