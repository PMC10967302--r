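map_header <- "plate_id,row,col,role,standard_conc,sample_id"
meas_header <- "plate_id,row,col,assay,time_min,value"

test_that("plate maps parse roles, standards and sample ids", {
  p <- write_lines_csv(c(map_header, "P1,A,1,blank,,"))
  m <- read_plate_map(p)
  expect_equal(nrow(m), 1L)
  expect_equal(m$role, "blank")
  expect_true(is.na(m$standard_conc) && is.na(m$sample_id))

  p <- write_lines_csv(c(map_header, "P1,A,2,standard,100,"))
  m <- read_plate_map(p)
  expect_equal(m$standard_conc, 100)

  p <- write_lines_csv(c(map_header, "P1,B,1,treatment,,EXT001",
                         "P1,A,1,positive_control,,QUERCETIN"))
  m <- read_plate_map(p)
  expect_equal(m$sample_id, c("QUERCETIN", "EXT001"))  # canonical order
})

test_that("plate-map invariant violations are rejected with informative errors", {
  dup <- write_lines_csv(c(map_header, "P1,A,3,treatment,,EXT001", "P1,A,3,blank,,"))
  expect_error(read_plate_map(dup), "duplicate well address")

  bad_role <- write_lines_csv(c(map_header, "P1,A,1,solvent,,"))
  expect_error(read_plate_map(bad_role), "unknown role 'solvent'.*row 1")

  expect_error(read_plate_map(write_lines_csv(c(map_header, "P1,J,1,blank,,"))),
               "row must be a letter A-H")
  expect_error(read_plate_map(write_lines_csv(c(map_header, "P1,A,13,blank,,"))),
               "column must be an integer 1-12")
  expect_error(read_plate_map(write_lines_csv(c(map_header, "P1,A,1,standard,,"))),
               "must carry standard_conc")
  expect_error(read_plate_map(write_lines_csv(c(map_header, "P1,A,1,treatment,,"))),
               "must carry sample_id")
  expect_error(read_plate_map(write_lines_csv(c(map_header, "P1,A,1,blank,5,"))),
               "non-standard well")
})

test_that("measurements join to roles and enforce the kinetic read schedule", {
  map <- read_plate_map(write_lines_csv(c(map_header, "P1,A,1,treatment,,EXT001")))
  trace <- sprintf("P1,A,1,ros_dcf,%d,%g", c(0, 15, 30, 60, 90),
                   c(100, 150, 200, 300, 400))
  m <- read_measurements(write_lines_csv(c(meas_header, trace)), map,
                         read_schedule = c(0, 15, 30, 60, 90))
  expect_equal(nrow(m), 5L)
  expect_equal(unique(m$role), "treatment")
  expect_equal(m$time_min, c(0, 15, 30, 60, 90))

  # empty data section: an empty table, not an error
  empty <- read_measurements(write_lines_csv(meas_header), map)
  expect_equal(nrow(empty), 0L)

  # truncated schedule
  expect_error(
    read_measurements(write_lines_csv(c(meas_header, trace[1:3])), map,
                      read_schedule = c(0, 15, 30, 60, 90)),
    "read schedule.*missing t = 60, 90")

  # orphan well and non-numeric value
  expect_error(
    read_measurements(write_lines_csv(c(meas_header, "P1,B,1,tpc,,0.3")), map),
    "absent from the plate map")
  expect_error(
    read_measurements(write_lines_csv(c(meas_header, "P1,A,1,tpc,,abc")), map),
    "non-numeric")
  expect_error(
    read_measurements(write_lines_csv(c(meas_header, "P1,A,1,tpc,,0.3",
                                        "P1,A,1,ros_dcf,0,5")), map),
    "one assay")
})

test_that("parsing is order-independent: shuffled rows give an identical table", {
  map_lines <- c(map_header,
                 "P1,A,1,blank,,", "P1,B,1,treatment,,EXT001",
                 "P2,A,1,stress_control,,", "P1,H,12,untreated_control,,")
  meas_lines <- c(
    sprintf("P1,A,1,ros_dcf,%d,%g", c(0, 15, 30, 60, 90), 200 + 1:5),
    sprintf("P1,B,1,ros_dcf,%d,%g", c(0, 15, 30, 60, 90), 300 + 1:5),
    sprintf("P2,A,1,ros_dcf,%d,%g", c(0, 15, 30, 60, 90), 400 + 1:5),
    sprintf("P1,H,12,ros_dcf,%d,%g", c(0, 15, 30, 60, 90), 500 + 1:5))
  map <- read_plate_map(write_lines_csv(map_lines))
  set.seed(4)
  shuffled_map <- read_plate_map(write_lines_csv(c(map_header,
                                                   sample(map_lines[-1]))))
  expect_identical(map, shuffled_map)

  m1 <- read_measurements(write_lines_csv(c(meas_header, meas_lines)), map)
  m2 <- read_measurements(write_lines_csv(c(meas_header, sample(meas_lines))), map)
  expect_identical(m1, m2)
})

test_that("results tables round-trip through CSV at full precision", {
  set.seed(9)
  n <- 10
  res <- data.frame(
    extract_id = sprintf("EXT%04d", 1:n),
    tpc_gae_mg_L = rlnorm(n, 6, 1), frap_te_umol_L = rlnorm(n, 8, 1),
    ros_pct = runif(n, 0, 120), ros_sd = runif(n, 0, 10),
    no_pct = runif(n, 0, 130), no_sd = runif(n, 0, 10),
    viability_caco2_pct = runif(n, 50, 110), viability_raw_pct = runif(n, 50, 110),
    excluded_ros = rep(c(TRUE, FALSE), 5), excluded_no = rep(FALSE, n),
    sig_ros = rep(c(TRUE, FALSE), 5), sig_no = rep(TRUE, n),
    reduction30_ros = rep(FALSE, n), reduction30_no = rep(c(TRUE, FALSE), 5),
    selectivity = rep(c("dual", "no_selective", "ros_selective",
                        "unclassified", "excluded"), 2),
    stringsAsFactors = FALSE
  )
  # missing endpoints survive as NA
  res$ros_pct[1] <- NA; res$sig_ros[1] <- NA
  path <- tempfile(fileext = ".csv")
  write_results(res, path)
  back <- read_results(path)
  expect_equal(back, res, tolerance = 1e-12)
  expect_identical(names(back),
                   c("extract_id", "tpc_gae_mg_L", "frap_te_umol_L",
                     "ros_pct", "ros_sd", "no_pct", "no_sd",
                     "viability_caco2_pct", "viability_raw_pct",
                     "excluded_ros", "excluded_no", "sig_ros", "sig_no",
                     "reduction30_ros", "reduction30_no", "selectivity"))

  res$selectivity[1] <- "mystery"
  expect_error(write_results(res, path), "invalid selectivity class")
})

test_that("selectivity column of a pipeline run stays within the class vocabulary", {
  camp <- make_campaign(tiny_config(seed = 3))
  run <- run_screen(camp$files)
  expect_true(all(run$results$selectivity %in%
                    c("dual", "no_selective", "ros_selective",
                      "unclassified", "excluded")))
})
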