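test_that("rest-only scenarios carry no motion phases or episodes", {
  sim <- generate_gait(gait_scenario(list(seg_rest(5)), seed = 1))
  expect_equal(nrow(sim$truth$motion_phases), 0)
  expect_equal(nrow(sim$truth$fog_episodes), 0)
  expect_gt(nrow(sim$stream), 5 * 200)
})

test_that("programmed stride counts become annotated motion phases", {
  for (seed in c(1, 2, 3)) {
    sim <- generate_gait(
      gait_scenario(list(seg_walk(10)), seed = seed)
    )
    expect_equal(nrow(sim$truth$motion_phases), 10)
    # at cadence 1 Hz ten strides occupy about ten seconds
    expect_equal(
      max(sim$truth$per_stride$end) - min(sim$truth$per_stride$start) + 0.6,
      10,
      tolerance = 0.1
    )
  }
  # akinesia contributes an episode but no phases
  sim <- generate_gait(
    gait_scenario(list(seg_walk(3), seg_akinesia(4)), seed = 4)
  )
  expect_equal(nrow(sim$truth$motion_phases), 3)
  expect_equal(sim$truth$fog_episodes$subtype, "akinesia")
})

test_that("FoG segments are covered exactly by one episode each", {
  sim <- generate_gait(gait_scenario(
    list(seg_shuffling(5), seg_trembling(3), seg_festination(4)),
    seed = 9
  ))
  ep <- sim$truth$fog_episodes
  expect_equal(ep$subtype, c("shuffling", "trembling", "festination"))
  # every stride motion phase of a FoG segment lies inside its episode
  ps <- sim$truth$per_stride
  for (k in seq_len(nrow(ps))) {
    seg_ep <- ep[ep$subtype == ps$kind[k], ]
    expect_true(ps$start[k] >= seg_ep$start && ps$end[k] <= seg_ep$end)
  }
  # shuffling strides are short with low foot lift
  shuf <- ps[ps$kind == "shuffling", ]
  expect_true(all(shuf$true_stride_length_m <= 0.25))
})

test_that("rest acceleration norm averages gravity", {
  sim <- generate_gait(
    gait_scenario(list(seg_rest(5)), seed = 2)
  )
  norm <- sqrt(sim$stream$ax^2 + sim$stream$ay^2 + sim$stream$az^2)
  expect_equal(mean(norm), 9.81, tolerance = 0.1)
})

test_that("double integration of the noise-free trajectory recovers stride length", {
  sim <- generate_gait(
    gait_scenario(list(seg_rest(1), seg_walk(3)), seed = 6),
    noise = FALSE, keep_kinematics = TRUE
  )
  kin <- sim$kinematics
  for (k in seq_len(nrow(sim$truth$per_stride))) {
    st <- sim$truth$per_stride[k, ]
    idx <- which(kin$t >= st$start & kin$t <= st$end)
    dt <- 1 / 200
    vx <- cumsum(kin$agx[idx]) * dt
    vy <- cumsum(kin$agy[idx]) * dt
    dx <- sum(vx) * dt
    dy <- sum(vy) * dt
    len <- sqrt(dx^2 + dy^2)
    expect_equal(len, st$true_stride_length_m, tolerance = 0.01)
  }
})

test_that("10MWT protocol scripts the right strides, turn and determinism", {
  subj <- subject_params(stride_length_m = 1.0)
  scen <- protocol_10mwt(subj, fog_density = 0, seed = 3)
  kinds <- vapply(scen$segments, `[[`, "", "kind")
  expect_equal(sum(kinds == "turn"), 1)
  walk_strides <- sum(vapply(
    scen$segments[kinds == "normal_walk"], `[[`, 0, "strides"
  ))
  expect_equal(walk_strides, 20)

  # fog_density 1 forces an episode at the turn
  scen_fog <- protocol_10mwt(subj, fog_density = 1, seed = 3)
  kinds_fog <- vapply(scen_fog$segments, `[[`, "", "kind")
  expect_true(any(kinds_fog %in% c("shuffling", "festination", "trembling")))

  # same seed, same scenario
  expect_identical(protocol_10mwt(subj, 0.5, seed = 7),
    protocol_10mwt(subj, 0.5, seed = 7))
})

test_that("FAC protocol contains both 360-degree turns with exact yaw truth", {
  scen <- protocol_fac(subject_params(), fog_density = 0, seed = 5)
  kinds <- vapply(scen$segments, `[[`, "", "kind")
  turns <- which(kinds == "turn")
  expect_length(turns, 2)
  angles <- vapply(scen$segments[turns], `[[`, 0, "angle_deg")
  expect_equal(sort(angles), c(-360, 360))

  sim <- generate_gait(scen)
  ps <- sim$truth$per_stride
  for (seg_i in turns) {
    total <- sum(ps$true_turn_deg[ps$segment == seg_i])
    expect_equal(abs(total), 360, tolerance = 1)
  }
  expect_true(any(kinds == "sway"))
})

test_that("cohorts vary between subjects and reproduce under one seed", {
  expect_error(make_cohort(n_subjects = 1), class = "gaitcue_validation_error")
  cohort <- make_cohort(n_subjects = 3, seed = 11)
  expect_equal(nrow(cohort), 3)
  lens <- vapply(
    cohort$scenario, function(s) s$subject$stride_length_m, 0
  )
  expect_gt(length(unique(lens)), 1)
  cohort2 <- make_cohort(n_subjects = 3, seed = 11)
  expect_identical(
    as.data.frame(cohort$stream[[2]]),
    as.data.frame(cohort2$stream[[2]])
  )
})
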