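test_that("finger chain spec validates lengths and radii", {
  expect_error(finger_chain_spec("index",
                                 c(metacarpal = 68, proximal = 39, middle = 22, distal = -1),
                                 4, gripangle::default_hand_specs()$index$end_radii),
               "positive")
  expect_error(finger_chain_spec("index",
                                 c(metacarpal = 30, proximal = 39, middle = 22, distal = 16),
                                 4, default_hand_specs()$index$end_radii),
               "distal < proximal < metacarpal")
  specs <- default_hand_specs()
  for (s in specs) {
    L <- s$segment_lengths
    expect_true(L[["distal"]] < L[["proximal"]] && L[["proximal"]] < L[["metacarpal"]])
  }
})

test_that("identity pose yields a straight colinear chain", {
  specs <- default_hand_specs()
  chain <- pose_finger_chain(specs$middle, pose_uniform(0, 0, 0),
                             include_mesh = FALSE)
  dirs <- sapply(chain, function(b)
    (b$true_head_center - b$true_base_center) /
      sqrt(sum((b$true_head_center - b$true_base_center)^2)))
  for (k in 2:4) expect_equal(dirs[, k], dirs[, 1], tolerance = 1e-12)
  # consecutive bones share endpoints
  for (k in 1:3)
    expect_equal(chain[[k]]$true_head_center, chain[[k + 1]]$true_base_center)
})

test_that("posed joint angles are recovered exactly from true centers", {
  specs <- default_hand_specs()
  # right-angle pose: each per-joint recovered angle is 90, and the
  # metacarpal-to-distal angle folds 270 back to 90 in the unsigned convention
  chain <- pose_finger_chain(specs$index, pose_uniform(90, 90, 90),
                             include_mesh = FALSE)
  dirs <- lapply(chain, function(b)
    (b$true_head_center - b$true_base_center) /
      sqrt(sum((b$true_head_center - b$true_base_center)^2)))
  for (k in 1:3)
    expect_equal(flexion_angle(dirs[[k]], dirs[[k + 1]]), 90, tolerance = 1e-9)
  expect_equal(flexion_angle(dirs[[1]], dirs[[4]]), 90, tolerance = 1e-9)

  # random poses: arccos oracle between consecutive axes returns the input
  set.seed(31)
  for (rep in 1:20) {
    ang <- runif(3, 5, 110)
    chain <- pose_finger_chain(specs$ring,
                               pose_uniform(ang[1], ang[2], ang[3]),
                               include_mesh = FALSE)
    dirs <- lapply(chain, function(b)
      (b$true_head_center - b$true_base_center) /
        sqrt(sum((b$true_head_center - b$true_base_center)^2)))
    rec <- vapply(1:3, function(k) flexion_angle(dirs[[k]], dirs[[k + 1]]),
                  numeric(1))
    expect_equal(rec, ang, tolerance = 1e-9)
  }
})

test_that("an incomplete pose is rejected", {
  specs <- default_hand_specs()
  pose <- pose_spec_df(data.frame(finger = "index", joint = c("MP", "PIP"),
                                  angle_deg = c(10, 20)))
  expect_error(pose_finger_chain(specs$index, pose), "incomplete-pose")
  expect_error(pose_spec_df(data.frame(finger = "index", joint = "MP",
                                       angle_deg = 190)),
               "\\[0, 180\\)")
})
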