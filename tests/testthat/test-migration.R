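test_that("trajectory filter applies duration and on-pattern gates", {
  short <- as_cohort(list(straight_track(0.1, 0.1, n_steps = 35)))  # 350 min
  long <- as_cohort(list(straight_track(0.1, 0.1, n_steps = 60)))   # 600 min
  long$cell_id <- "long1"
  off <- as_cohort(list(straight_track(0.1, 0.1, n_steps = 60)),
                   on_pattern = FALSE)
  off$cell_id <- "off1"
  ctrl_off <- as_cohort(list(straight_track(0.1, 0.1, n_steps = 60)),
                        condition = "control", on_pattern = FALSE)
  ctrl_off$cell_id <- "ctrl1"
  all_tracks <- rbind(short, long, off, ctrl_off)
  kept <- filter_trajectories(all_tracks)
  expect_setequal(unique(kept$cell_id), c("long1", "ctrl1"))
  log <- attr(kept, "exclusion_log")
  expect_true("too_short" %in% log$reason[log$cell_id == "cell001"])
  expect_true("off_pattern" %in% log$reason[log$cell_id == "off1"])

  bad <- long
  bad$on_pattern[3] <- NA
  expect_error(filter_trajectories(bad), "long1")
})

test_that("directional orientation folds the net displacement onto the groove axis", {
  expect_equal(directional_orientation(track_from_steps(0, 10)), 0)
  expect_equal(directional_orientation(track_from_steps(10, 0)), 90)
  expect_equal(directional_orientation(track_from_steps(5, 5)), 45)
  # net displacement matters, not the path
  expect_equal(directional_orientation(track_from_steps(c(3, -3), c(1, 1))), 0)
  loop <- track_from_steps(c(1, -1), c(1, -1))
  expect_error(directional_orientation(loop), "zero net displacement")
})

test_that("angular displacement reproduces the closed-form angles", {
  up_up <- track_from_steps(c(0, 0), c(1, 1))
  expect_equal(angular_displacement(up_up, 10), 0, ignore_attr = TRUE)
  right_up <- track_from_steps(c(1, 0), c(0, 1))
  expect_equal(angular_displacement(right_up, 10), 90, ignore_attr = TRUE)
  up_down <- track_from_steps(c(0, 0), c(1, -1))
  expect_equal(angular_displacement(up_down, 10), 180, ignore_attr = TRUE)
  # delta = 20 min spans two samples per displacement vector
  tr <- track_from_steps(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(angular_displacement(tr, 20), 90, ignore_attr = TRUE)
  expect_error(angular_displacement(tr, 15), "multiple")
  # zero-magnitude displacements are skipped and counted
  paused <- track_from_steps(c(1, 0, 1), c(0, 0, 0))
  d <- angular_displacement(paused, 10)
  expect_equal(length(d), 0)
  expect_equal(attr(d, "n_skipped"), 2)
})

test_that("angular displacements stay in [0, 180] on rough random walks", {
  set.seed(401)
  for (i in 1:5) {
    tr <- track_from_steps(rnorm(40), rnorm(40))
    d <- angular_displacement(tr, 20)
    expect_true(all(d >= 0 & d <= 180))
  }
})

test_that("occurrence histogram of turning angles", {
  h <- occurrence_histogram(rep(0, 10))
  expect_equal(nrow(h), 12)
  expect_equal(h$fraction[1], 1)
  h2 <- occurrence_histogram(c(0, 180))
  expect_equal(h2$fraction[c(1, 12)], c(0.5, 0.5))
  expect_error(occurrence_histogram(numeric(0)), "empty")
  expect_error(occurrence_histogram(181), "\\[0, 180\\]")
})

test_that("speeds and their groove-axis decomposition", {
  tr <- track_from_steps(3, 4)  # one 5-um step in 10 min
  expect_equal(average_speed(tr), 0.5)
  sp <- directional_speeds(tr)
  expect_equal(sp$v_x_bar, 0.3)
  expect_equal(sp$v_y_bar, 0.4)
  expect_equal(sp$ratio, 4 / 3)

  expect_equal(average_speed(track_from_steps(c(0, 0), c(0, 0))), 0)
  two <- track_from_steps(c(1, 0), c(0, 1))  # two 1-um steps in 20 min
  expect_equal(average_speed(two), 0.1)

  pure_y <- directional_speeds(track_from_steps(c(0, 0), c(1, 1)))
  expect_equal(pure_y$v_x_bar, 0)
  expect_true(is.infinite(pure_y$ratio))
  expect_false(pure_y$ratio_defined)

  loop <- directional_speeds(track_from_steps(c(1, 0, -1, 0), c(0, 1, 0, -1)))
  expect_equal(loop$ratio, 1)
  expect_error(average_speed(data.frame(t_min = 0, x_um = 0, y_um = 0)),
               "at least 2")
})

test_that("directional displacement and directionality ratios on toy paths", {
  up <- straight_track(0, 0.3, n_steps = 20)
  for (D in c(10, 100, 200)) {
    expect_equal(directional_displacement_ratio(up, D), 1.0)
    expect_equal(directionality_ratio(up, D), 1.0)
  }
  right <- straight_track(0.3, 0, n_steps = 20)
  expect_equal(directional_displacement_ratio(right, 100), 0.0)
  expect_equal(directionality_ratio(right, 100), 1.0)

  toy <- track_from_steps(c(0, 0, 0, 0), c(1, 1, 1, -1))
  expect_equal(directional_displacement_ratio(toy, 40), 0.5)
  expect_equal(directionality_ratio(toy, 40), 0.5)

  loop <- track_from_steps(c(1, 0, -1, 0), c(0, 1, 0, -1))
  expect_equal(directionality_ratio(loop, 40), 0.0)

  down <- straight_track(0, -0.3, n_steps = 20)
  expect_equal(directional_displacement_ratio(down, 100), -1.0)

  still <- track_from_steps(c(0, 0), c(0, 0))
  expect_error(directional_displacement_ratio(still, 20), "stationary")
  expect_error(directional_displacement_ratio(up, 25), "multiple")
  expect_error(directional_displacement_ratio(up, 500), "duration")
})

test_that("cohort ratio curves aggregate mean and SEM per window", {
  cohort <- as_cohort(list(straight_track(0, 0.3, 60),
                           straight_track(0, 0.4, 60),
                           straight_track(0, 0.2, 30)))
  cc <- cohort_ratio_curve(cohort, c(100, 300, 400))
  expect_equal(cc$mean, c(1, 1, 1))
  expect_equal(cc$sem, c(0, 0, 0))
  expect_equal(cc$n, c(3L, 3L, 2L))  # the short cell drops out beyond 300

  one <- cohort_ratio_curve(as_cohort(list(straight_track(0.1, 0.2, 20))), 100)
  expect_equal(one$n, 1L)
  expect_equal(one$sem, 0)

  dd <- cohort_ratio_curve(cohort, 100, statistic = "directionality")
  expect_equal(dd$mean, 1)
  expect_error(cohort_ratio_curve(cohort[0, ], 100), "empty")
})

test_that("signed cohort ratio of an isotropic cohort is near zero", {
  p <- sim_params(n_cells = 500, persistence = 0, axis_bias = 0, seed = 402)
  tr <- simulate_trajectories(p, substrate_condition(0, 0, 0))
  cc <- cohort_ratio_curve(tr, c(300, 600))
  expect_true(all(abs(cc$mean) < 0.05))
})

test_that("MSD matches closed forms", {
  line <- as_cohort(list(straight_track(0, 0.5, 30)))
  msd <- mean_squared_displacement(line, c(10, 50, 100))
  expect_equal(msd$msd_um2, (0.5 * c(10, 50, 100))^2)
  still <- as_cohort(list(track_from_steps(c(0, 0), c(0, 0))))
  expect_equal(mean_squared_displacement(still, 10)$msd_um2, 0)
  expect_error(mean_squared_displacement(line, 1000), "exceeds")

  # diffusive scaling of an isotropic non-persistent walk:
  # MSD(k dt) = k * E[step^2]
  p <- sim_params(n_cells = 500, persistence = 0, axis_bias = 0, seed = 403)
  tr <- simulate_trajectories(p, substrate_condition(0, 0, 0))
  mu <- 0.35 * 10; sg <- 0.1 * 10
  expected <- c(1, 4, 10) * (mu^2 + sg^2)
  got <- mean_squared_displacement(tr, c(10, 40, 100))$msd_um2
  expect_true(all(abs(got / expected - 1) < 0.05))
})

test_that("velocity autocorrelation matches the walk's persistence", {
  line <- as_cohort(list(straight_track(0.2, 0.3, 30)))
  v <- velocity_autocorrelation(line, c(0, 10, 100))
  expect_equal(v$vacf, c(1, 1, 1))

  p0 <- sim_params(n_cells = 500, persistence = 0, axis_bias = 0, seed = 404)
  tr0 <- simulate_trajectories(p0, substrate_condition(0, 0, 0))
  v0 <- velocity_autocorrelation(tr0, c(10, 20))
  expect_true(all(abs(v0$vacf) < 0.05))

  pp <- sim_params(n_cells = 500, persistence = 0.7, axis_bias = 0,
                   speed_sd = 0, seed = 405)
  trp <- simulate_trajectories(pp, substrate_condition(0, 0, 0))
  vp <- velocity_autocorrelation(trp, 10)
  expect_lt(abs(vp$vacf - 0.7), 0.05)
  vc <- velocity_autocorrelation(trp, 10, method = "cosine")
  expect_lt(abs(vc$vacf - 0.7), 0.05)
})

test_that("speed decomposition and ratio orderings hold on random tracks", {
  set.seed(406)
  for (i in 1:20) {
    tr <- track_from_steps(rnorm(60, sd = 2), rnorm(60, sd = 2))
    v <- average_speed(tr)
    sp <- directional_speeds(tr)
    expect_lte(max(sp$v_x_bar, sp$v_y_bar), v + 1e-12)
    expect_lte(v, sp$v_x_bar + sp$v_y_bar + 1e-12)
    for (D in c(100, 300, 600)) {
      ddr <- directional_displacement_ratio(tr, D)
      dr <- directionality_ratio(tr, D)
      expect_lte(abs(ddr), dr + 1e-12)
      expect_lte(dr, 1 + 1e-12)
    }
  }
})

test_that("migration table gates orientation by duration", {
  cohort <- rbind(as_cohort(list(straight_track(0.1, 0.3, 60))),
                  within(as_cohort(list(straight_track(0.1, 0.3, 40))),
                         cell_id <- "short1"))
  m <- migration_table(cohort)
  expect_false(is.na(m$orientation_deg[m$cell_id == "cell001"]))
  expect_true(is.na(m$orientation_deg[m$cell_id == "short1"]))
  expect_equal(m$mean_speed[1], sqrt(0.01 + 0.09), tolerance = 1e-10)
})
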