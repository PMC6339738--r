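test_that("coupling ratio is plain division guarded against zero PIP", {
  expect_equal(coupling_ratio(60, 60), 1.0)
  expect_equal(coupling_ratio(50, 100), 0.5)
  expect_error(coupling_ratio(50, 0), "undefined-ratio")
})

test_that("angle summaries use the sample SD and reproduce hand arithmetic", {
  vals <- c(48.2, 51.3, 44.0, 47.7, 52.9, 46.1, 50.5, 49.2, 45.8, 53.3)
  rec <- data.frame(subject = sprintf("S%02d", 1:10), diameter_mm = 10,
                    finger = "index", joint = "DIP", angle_deg = vals)
  s <- summarize_angles(rec)
  expect_equal(s$mean, mean(vals), tolerance = 1e-12)
  expect_equal(s$sd, sqrt(sum((vals - mean(vals))^2) / 9), tolerance = 1e-12)
  expect_equal(s$n, 10L)

  single <- summarize_angles(data.frame(subject = "S01", diameter_mm = 10,
                                        finger = "index", joint = "DIP",
                                        angle_deg = 42))
  expect_equal(single$sd, 0)
  expect_equal(single$n, 1L)
})

test_that("summaries refuse unbalanced or incomplete designs", {
  co <- simulate_cohort(cohort_spec(4, seed = 2))
  expect_error(summarize_angles(co[-1, ]), "incomplete-design")
  crs <- cr_records(co)
  expect_error(summarize_cr(crs[-1, ]), "incomplete-design")
})

test_that("CR is mean-of-ratios per subject, never ratio-of-means", {
  # heterogeneous subjects where the two conventions differ visibly
  rec <- rbind(
    data.frame(subject = "S01", diameter_mm = 10, finger = "index",
               joint = c("DIP", "PIP"), angle_deg = c(20, 100)),
    data.frame(subject = "S02", diameter_mm = 10, finger = "index",
               joint = c("DIP", "PIP"), angle_deg = c(80, 100)))
  crs <- cr_records(rec)
  s <- summarize_cr(crs)
  cell <- s$mean[s$diameter == "10" & s$finger == "index"]
  expect_equal(cell, mean(c(0.2, 0.8)), tolerance = 1e-12)
  ratio_of_means <- mean(c(20, 80)) / mean(c(100, 100))
  expect_equal(cell, ratio_of_means)   # equal here by construction...
  rec$angle_deg[4] <- 50               # ...but not once PIP varies
  crs2 <- cr_records(rec)
  s2 <- summarize_cr(crs2)
  cell2 <- s2$mean[s2$diameter == "10" & s2$finger == "index"]
  expect_equal(cell2, mean(c(20 / 100, 80 / 50)), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cell2, mean(c(20, 80)) / mean(c(100, 50)))))
})

test_that("CR marginals are equal-weight means of their cells and constants pass through", {
  co <- simulate_cohort(cohort_spec(8, seed = 6))
  crs <- cr_records(co)
  s <- summarize_cr(crs)
  for (d in c("10", "60", "120")) {
    cells <- s$mean[s$diameter == d & s$finger != "All"]
    expect_equal(s$mean[s$diameter == d & s$finger == "All"], mean(cells),
                 tolerance = 1e-12)
  }
  grand_cells <- s$mean[s$diameter != "All" & s$finger != "All"]
  expect_equal(s$mean[s$diameter == "All" & s$finger == "All"],
               mean(grand_cells), tolerance = 1e-12)

  # permutation invariance of aggregation
  set.seed(1)
  s_perm <- summarize_cr(crs[sample(nrow(crs)), ])
  expect_equal(s_perm$mean, s$mean, tolerance = 1e-12)

  const <- crs; const$cr <- 0.64
  sc <- summarize_cr(const)
  expect_true(all(abs(sc$mean - 0.64) < 1e-12))
  expect_true(all(sc$sd < 1e-12))
})

test_that("undefined ratios are flagged, then refused by the summary", {
  rec <- data.frame(subject = rep(c("S01", "S02"), each = 2),
                    diameter_mm = 10, finger = "index",
                    joint = rep(c("DIP", "PIP"), 2),
                    angle_deg = c(10, 0, 20, 40))
  crs <- cr_records(rec)
  expect_equal(crs$status, c("undefined-ratio", "ok"))
  expect_true(is.na(crs$cr[1]))
  expect_error(summarize_cr(crs), "undefined-ratio")
})

test_that("published CR cells reproduce the published marginals", {
  cells <- published_cr_cells()
  m <- vapply(c(10, 60, 120), function(d)
    mean(cells$mean[cells$diameter_mm == d]), numeric(1))
  expect_equal(round(m, 2), c(0.58, 0.80, 0.88))
  expect_equal(round(mean(cells$mean), 2), 0.75)
})
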