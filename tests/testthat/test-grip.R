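test_that("grip angles shrink strictly across the study diameters and never grow on a fine sweep", {
  specs <- default_hand_specs()
  for (f in names(specs)) {
    study <- sapply(c(10, 60, 120), function(d)
      solve_grip_pose(specs[[f]], grip_scenario(d))$angle_deg)
    # strict decrease at every joint between 10, 60 and 120 mm
    expect_true(all(study[, 1] > study[, 2]))
    expect_true(all(study[, 2] > study[, 3]))
    sweep_d <- seq(10, 120, by = 5)
    ang <- sapply(sweep_d, function(d)
      solve_grip_pose(specs[[f]], grip_scenario(d))$angle_deg)
    expect_true(all(diff(t(ang)) <= 1e-12))   # non-increasing everywhere
  }
})

test_that("a locally flat cylinder leaves the fingers almost straight", {
  specs <- default_hand_specs()
  for (f in names(specs)) {
    pose <- solve_grip_pose(specs[[f]], grip_scenario(1e6))
    expect_true(all(pose$angle_deg < 5))
  }
})

test_that("grip solving is deterministic", {
  specs <- default_hand_specs()
  p1 <- solve_grip_pose(specs$index, grip_scenario(60))
  p2 <- solve_grip_pose(specs$index, grip_scenario(60))
  expect_identical(as.data.frame(p1), as.data.frame(p2))
})

test_that("contact residuals stay within the scenario tolerance in the wrap regime", {
  specs <- default_hand_specs()
  for (d in c(60, 120)) {
    scen <- grip_scenario(d)
    for (f in names(specs)) {
      pose <- solve_grip_pose(specs[[f]], scen)
      contact <- attr(pose, "contact")
      expect_true(all(contact$regime == "cylinder"))
      res <- grip_contact_residuals(specs[[f]], pose, scen)
      expect_true(all(abs(res$residual_mm) <= scen$contact_tolerance_mm))
    }
  }
})

test_that("the tight-cylinder regime is flexion-limited, not cylinder contact", {
  specs <- default_hand_specs()
  pose <- solve_grip_pose(specs$middle, grip_scenario(10))
  rom <- default_rom_caps()$middle
  expect_equal(unname(pose$angle_deg[match(c("MP", "PIP", "DIP"), pose$joint)]),
               unname(rom[c("MP", "PIP", "DIP")]))
  expect_true(all(attr(pose, "contact")$regime == "flexion-limited"))
})

test_that("an unreachable cylinder raises an infeasible-grip error with the minimum diameter", {
  specs <- default_hand_specs()
  stiff <- c(MP = 15, PIP = 15, DIP = 10)   # barely flexing finger
  err <- tryCatch(solve_grip_pose(specs$index, grip_scenario(5), rom_caps = stiff),
                  error = function(e) conditionMessage(e))
  expect_match(err, "infeasible-grip")
  expect_match(err, "minimum feasible diameter")
  dmin <- as.numeric(sub(".*minimum feasible diameter ([0-9.]+) mm.*", "\\1", err))
  expect_gt(dmin, 5)
  # at or above the reported minimum the solve succeeds
  expect_s3_class(solve_grip_pose(specs$index, grip_scenario(dmin + 0.01),
                                  rom_caps = stiff), "pose_spec")
  expect_error(grip_scenario(-3), "invalid-geometry")
})
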