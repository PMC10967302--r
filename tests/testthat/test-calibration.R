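test_that("standard curves recover exact lines and match the normal equations", {
  cv <- fit_standard_curve(c(0, 100, 200), c(0, 0.2, 0.4), "gallic_acid")
  expect_equal(cv$slope, 0.002)
  expect_equal(cv$intercept, 0)
  expect_equal(cv$r_squared, 1)
  expect_equal(cv$n_points, 3L)

  # independent oracle: solve the 2x2 normal equations directly
  conc <- c(0, 50, 100, 200); abs_ <- c(0.01, 0.12, 0.19, 0.41)
  X <- cbind(1, conc)
  beta <- solve(t(X) %*% X, t(X) %*% abs_)
  cv <- fit_standard_curve(conc, abs_, "trolox")
  expect_equal(cv$intercept, beta[1], tolerance = 1e-12)
  expect_equal(cv$slope, beta[2], tolerance = 1e-12)
})

test_that("degenerate or decreasing calibrations are rejected", {
  expect_error(fit_standard_curve(c(100, 100), c(0.2, 0.3), "gallic_acid"),
               "degenerate")
  expect_error(fit_standard_curve(c(0, 100, 200), c(0.4, 0.2, 0.0), "trolox"),
               "slope is not positive")
})

test_that("curve inversion scales with dilution and round-trips any line", {
  cv <- fit_standard_curve(c(0, 100, 200), c(0, 0.2, 0.4), "gallic_acid")
  expect_equal(absorbance_to_concentration(cv, 0.5, 1), 250)
  expect_equal(absorbance_to_concentration(cv, 0.5, 10), 2500)

  cv2 <- fit_standard_curve(c(0, 100, 200), 0.01 + 0.002 * c(0, 100, 200),
                            "gallic_acid")
  expect_equal(absorbance_to_concentration(cv2, 0.41, 1), 200)

  set.seed(21)
  for (i in 1:20) {
    slope <- runif(1, 1e-4, 1e-2); icpt <- runif(1, -0.05, 0.05)
    conc <- sort(runif(5, 0, 500))
    cv <- fit_standard_curve(conc, slope * conc + icpt, "gallic_acid")
    expect_equal(cv$r_squared, 1, tolerance = 1e-9)
    c0 <- runif(1, 0, 400); d <- sample(c(1, 17, 200), 1)
    expect_equal(absorbance_to_concentration(cv, slope * c0 + icpt, d),
                 d * c0, tolerance = 1e-6)
  }

  # monotonicity in the sample absorbance
  a <- seq(0.05, 0.5, by = 0.05)
  expect_true(all(diff(absorbance_to_concentration(cv, a, 1)) > 0))
  expect_error(absorbance_to_concentration(cv, NaN), "finite")
})

test_that("FRAP plateau detection follows the consecutive-difference rule", {
  res <- frap_endpoint(0:2, c(0.3, 0.3, 0.3), delta_tol = 0.005)
  expect_equal(res$endpoint_au, 0.3)
  expect_equal(res$t_plateau, 0)
  expect_true(res$converged)

  res <- frap_endpoint(1:5, c(0.10, 0.20, 0.28, 0.29, 0.29), delta_tol = 0.02)
  expect_equal(res$t_plateau, 4)
  expect_equal(res$endpoint_au, 0.29)
  expect_true(res$converged)

  res <- frap_endpoint(0:4, c(0.1, 0.2, 0.3, 0.4, 0.5), delta_tol = 0)
  expect_false(res$converged)
  expect_equal(res$endpoint_au, 0.5)

  expect_error(frap_endpoint(0, 0.3), "insufficient")
  expect_error(frap_endpoint(c(0, 0), c(0.3, 0.3)), "strictly increasing")
})

test_that("full cell-free quantification recovers the generated concentrations", {
  camp <- make_campaign(tiny_config(seed = 5))
  map <- read_plate_map(camp$files$tpc_map)
  meas <- read_measurements(camp$files$tpc_meas, map)
  q <- quantify_cellfree(meas, dilution_factor = 17)
  expect_true(all(vapply(q$curves, function(cv) cv$r_squared, numeric(1)) > 0.999))
  idx <- match(q$per_extract$extract_id, camp$truth$extract_id)
  rel <- q$per_extract$conc / camp$truth$true_tpc[idx] - 1
  # relative accuracy holds away from the quantification limit; extracts whose
  # diluted signal approaches the read noise are only rank-consistent
  strong <- camp$truth$true_tpc[idx] > 1000
  expect_true(all(abs(rel[strong]) < 0.1))
  expect_gt(cor(q$per_extract$conc, camp$truth$true_tpc[idx],
                method = "spearman"), 0.97)
  expect_equal(median(abs(rel)), 0, tolerance = 0.03)
  expect_true(all(q$per_extract$n == 3))

  fmap <- read_plate_map(camp$files$frap_map)
  fmeas <- read_measurements(camp$files$frap_meas, fmap)
  qf <- quantify_cellfree(fmeas, dilution_factor = 31)
  idx <- match(qf$per_extract$extract_id, camp$truth$extract_id)
  expect_gt(cor(qf$per_extract$conc, camp$truth$true_frap[idx],
                method = "spearman"), 0.99)
})
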