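sched <- c(0, 15, 30, 60, 90)

test_that("background correction is elementwise and rejects dead baselines", {
  expect_equal(background_correct(sched, c(100, 150, 200, 300, 400), rep(50, 5)),
               c(50, 100, 150, 250, 350))
  expect_equal(background_correct(sched, c(100, 150, 200, 300, 400), 0),
               c(100, 150, 200, 300, 400))
  expect_error(background_correct(sched, rep(50, 5), rep(50, 5)),
               class = "invalid_baseline")
  expect_error(background_correct(sched, 1:5, rep(0, 3)), "schedule")
})

test_that("start-value-normalized AUC matches hand-computed trapezoids", {
  expect_equal(auc_normalized(sched, rep(7, 5)), 90)       # f_rel constant 1
  expect_equal(auc_normalized(sched, c(100, 200, 300, 500, 700)), 360)
  expect_equal(auc_normalized(c(0, 90), c(10, 30)), 180)   # single trapezoid
  expect_error(auc_normalized(0, 10), "insufficient")
  expect_error(auc_normalized(sched, c(-1, 2, 3, 4, 5)), "baseline")
})

test_that("trapezoidal AUC agrees with a fine-grid Riemann oracle", {
  set.seed(31)
  for (i in 1:25) {
    f <- cumsum(runif(5, 0.1, 2))
    auc <- auc_normalized(sched, f)
    # oracle: midpoint Riemann sum on the piecewise-linear interpolant
    grid <- seq(0, 90, length.out = 360001)
    mid <- (grid[-1] + grid[-length(grid)]) / 2
    oracle <- sum(approx(sched, f / f[1], xout = mid)$y) * diff(grid)[1]
    expect_equal(auc, oracle, tolerance = 1e-9)
  }
})

test_that("two-anchor normalization pins the controls and the midpoint", {
  expect_equal(normalize_two_anchor(290, 90, 290), 100)
  expect_equal(normalize_two_anchor(90, 90, 290), 0)
  expect_equal(normalize_two_anchor(190, 90, 290), 50)
  expect_error(normalize_two_anchor(100, 90, 90), "degenerate")
})

test_that("replicate summaries report mean and sample SD", {
  s <- summarize_ros(c(40, 50, 60))
  expect_equal(s$mean, 50)
  expect_equal(s$sd, 10)
  s1 <- summarize_ros(70)
  expect_equal(s1$mean, 70)
  expect_equal(s1$sd, 0)
  expect_equal(s1$n, 1L)
})

test_that("ROS percentages are invariant to a common fluorescence scale factor", {
  f <- c(120, 200, 310, 520, 700)
  a1 <- auc_normalized(sched, f)
  a2 <- auc_normalized(sched, 3.7 * f)
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("the full DCF chain maps stress controls to 100% and untreated to 0%", {
  # deliberately noisy campaign: the anchor identity holds by construction
  camp <- make_campaign(tiny_config(seed = 13, noise_cv = 0.08))
  map <- read_plate_map(camp$files$ros_dcf_map)
  meas <- read_measurements(camp$files$ros_dcf_meas, map, read_schedule = sched)
  ros <- process_ros(meas)
  pw <- ros$per_well
  for (p in unique(pw$plate_id)) {
    expect_equal(mean(pw$pct[pw$plate_id == p & pw$role == "stress_control"]),
                 100, tolerance = 1e-9)
    expect_equal(mean(pw$pct[pw$plate_id == p & pw$role == "untreated_control"]),
                 0, tolerance = 1e-9)
  }
})

test_that("wells with invalid baselines are excluded, not imputed", {
  map_lines <- c("plate_id,row,col,role,standard_conc,sample_id",
                 "P1,A,1,blank,,", "P1,B,1,untreated_control,,",
                 "P1,C,1,stress_control,,",
                 "P1,D,1,treatment,,EXT001", "P1,E,1,treatment,,EXT001")
  mk <- function(row, f) sprintf("P1,%s,1,ros_dcf,%d,%g", row, sched, f)
  meas_lines <- c(mk("A", rep(50, 5)),             # blank
                  mk("B", c(100, 110, 120, 130, 140)),
                  mk("C", c(100, 200, 300, 500, 700)),
                  mk("D", c(45, 80, 120, 200, 260)),  # below blank at t=0
                  mk("E", c(100, 180, 260, 420, 580)))
  map <- read_plate_map(write_lines_csv(map_lines))
  meas <- read_measurements(write_lines_csv(
    c("plate_id,row,col,assay,time_min,value", meas_lines)), map,
    read_schedule = sched)
  ros <- process_ros(meas)
  expect_equal(ros$excluded_wells$well, "P1:D:1")
  expect_match(ros$excluded_wells$reason, "invalid baseline")
  expect_equal(ros$per_sample$n[ros$per_sample$sample_id == "EXT001"], 1L)
})
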