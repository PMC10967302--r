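test_that("a single-treatment Dunnett reduces to the pooled two-sided t-test", {
  set.seed(41)
  for (i in 1:5) {
    ctrl <- rnorm(4, 100, 5); trt <- rnorm(3, 95, 5)
    dt <- dunnett_test(ctrl, list(A = trt), nodes = 192)
    ref <- t.test(trt, ctrl, var.equal = TRUE)$p.value
    expect_equal(dt$p_adj, ref, tolerance = 1e-4)
  }
})

test_that("a treatment equal to the control mean gets p = 1", {
  dt <- dunnett_test(c(100, 100, 100),
                     list(null = c(100, 100, 100), other = c(90, 95, 100)))
  expect_equal(dt$p_adj[dt$sample_id == "null"], 1)
  expect_equal(dt$t[dt$sample_id == "null"], 0)
})

test_that("degenerate designs are rejected", {
  expect_error(dunnett_test(c(100), list(A = c(1, 2))), ">= 2 replicates")
  expect_error(dunnett_test(c(1, 1), list(A = c(2, 2))), "degenerate variance")
  expect_error(dunnett_test(c(1, 2), list()), "at least one treatment")
})

test_that("adjusted p dominates the pairwise p and is bounded by Bonferroni", {
  set.seed(43)
  for (i in 1:8) {
    k <- sample(2:8, 1)
    ctrl <- rnorm(3, 100, 4)
    trts <- replicate(k, rnorm(3, rnorm(1, 100, 4), 4), simplify = FALSE)
    names(trts) <- paste0("t", seq_len(k))
    dt <- dunnett_test(ctrl, trts)
    groups <- c(list(ctrl), trts)
    df <- sum(lengths(groups) - 1L)
    pairwise <- 2 * pt(-abs(dt$t), df)
    expect_true(all(dt$p_adj >= pairwise - 2e-3))
    expect_true(all(dt$p_adj <= pmin(1, k * pairwise) + 2e-3))
  }
})

test_that("the family-wise quadrature matches the multivariate-t integrator", {
  skip_if_not_installed("mvtnorm")
  lam <- sqrt(3 / 6)
  for (k in c(2, 5, 12)) {
    R <- matrix(lam^2, k, k); diag(R) <- 1
    for (tt in c(1.2, 2.4, 3.2)) {
      ours <- dunnett_pmax_le(tt, rep(lam, k), df = 16, nodes = 96)
      ref <- mvtnorm::pmvt(lower = rep(-tt, k), upper = rep(tt, k), df = 16,
                           corr = R,
                           algorithm = mvtnorm::GenzBretz(abseps = 1e-5))
      expect_equal(ours, ref[1], tolerance = 2e-3,
                   ignore_attr = TRUE)
    }
  }
  # unbalanced design: per-pair product correlations
  lam2 <- sqrt(c(3, 5, 8) / (c(3, 5, 8) + 4))
  R2 <- outer(lam2, lam2); diag(R2) <- 1
  ours <- dunnett_pmax_le(2.1, lam2, df = 17, nodes = 96)
  ref <- mvtnorm::pmvt(lower = rep(-2.1, 3), upper = rep(2.1, 3), df = 17,
                       corr = R2, algorithm = mvtnorm::GenzBretz(abseps = 1e-5))
  expect_equal(ours, ref[1], tolerance = 2e-3, ignore_attr = TRUE)
})

test_that("the Dunnett critical value inverts the family-wise probability", {
  lam <- rep(sqrt(0.5), 6)
  crit <- dunnett_critical(lam, df = 14, alpha = 0.05)
  expect_equal(dunnett_pmax_le(crit, lam, 14), 0.95, tolerance = 1e-6)
  # flagging by p < alpha is identical to |t| > critical value
  set.seed(47)
  ctrl <- rnorm(3, 100, 3)
  trts <- replicate(6, rnorm(3, 100, 3), simplify = FALSE)
  names(trts) <- paste0("t", 1:6)
  dt <- dunnett_test(ctrl, trts)
  crit <- dunnett_critical(rep(sqrt(0.5), 6), df = attr(dt, "df"))
  expect_identical(dt$p_adj < 0.05, abs(dt$t) > crit)
})

test_that("hit calls combine direction, significance and the 30% reduction flag", {
  camp <- make_campaign(tiny_config(seed = 29))
  map <- read_plate_map(camp$files$ros_dcf_map)
  ros <- process_ros(read_measurements(camp$files$ros_dcf_meas, map,
                                       read_schedule = c(0, 15, 30, 60, 90)))
  hits <- call_hits(ros, "ros")
  expect_setequal(hits$sample_id,
                  camp$truth$extract_id)
  expect_true(all(hits$reduction30 == (hits$mean_pct <= 70)))
  expect_true(all(hits$direction[hits$p_adj >= 0.05] == "none"))
  expect_true(all(hits$mean_pct[hits$direction == "decrease"] < 100))
  expect_true(all(hits$mean_pct[hits$direction == "increase"] > 100))
})

test_that("printed worked examples classify as reported", {
  # boundary of the 30% reduction: exactly 70% still counts
  hits <- data.frame(mean_pct = c(38.98, 70, 105),
                     p_adj = c(0.001, 0.5, 0.02))
  direction <- ifelse(hits$p_adj < 0.05 & hits$mean_pct < 100, "decrease",
                      ifelse(hits$p_adj < 0.05 & hits$mean_pct > 100,
                             "increase", "none"))
  expect_identical(direction, c("decrease", "none", "increase"))
  expect_identical(hits$mean_pct <= 70, c(TRUE, TRUE, FALSE))
})

test_that("selectivity classes partition the gated library", {
  camp <- make_campaign(tiny_config(seed = 37, n_extracts = 60))
  run <- run_screen(camp$files)
  r <- run$results
  gated <- r$excluded_ros | r$excluded_no
  expect_true(all(r$selectivity[gated] == "excluded"))
  expect_true(all(r$selectivity[!gated] %in%
                    c("dual", "no_selective", "ros_selective", "unclassified")))
  expect_equal(sum(table(r$selectivity)), nrow(r))
})

test_that("spearman_cor matches hand-ranked Pearson and is monotone-invariant", {
  expect_equal(spearman_cor(1:4, c(10, 20, 30, 40))$r_s, 1)
  expect_lt(spearman_cor(1:4, c(10, 20, 30, 40))$p_value, 1e-200)
  expect_equal(spearman_cor(1:3, 3:1)$r_s, -1)

  # ties: average ranks computed by hand
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  hand <- cor(c(1, 2.5, 2.5, 4), c(1, 3, 2, 4))
  expect_equal(spearman_cor(x, y)$r_s, hand)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(spearman_cor(x, y)$r_s, unname(ref$estimate))

  set.seed(53)
  x <- rnorm(40); y <- x + rnorm(40)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$r_s, base$r_s)
  expect_equal(spearman_cor(x, y^3)$r_s, base$r_s)
  expect_equal(spearman_cor(qlogis(pnorm(x)), exp(y))$r_s, base$r_s)
  # p-value against the t reference implementation
  ref2 <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(base$p_value, ref2$p.value, tolerance = 1e-10)

  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 2:1), ">= 3")
  # pairwise-complete handling
  expect_equal(spearman_cor(c(1, 2, 3, NA), c(2, 4, 6, 1))$n, 3L)
})
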