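## Hit calling and correlation statistics for the screen: many-to-one
## Dunnett comparisons of every extract against the plate's stress control,
## >=30%-reduction flagging, selectivity classification of hits, and
## Spearman rank correlation across endpoints.

#' Family-wise probability for the two-sided Dunnett statistic
#'
#' Computes `P(max_j |T_j| <= t)` where `(T_1, ..., T_k)` follows the
#' multivariate t distribution of the many-to-one comparison statistics with
#' product correlation structure `corr(T_i, T_j) = lambda_i * lambda_j`,
#' `lambda_i = sqrt(n_i / (n_i + n_0))` (equicorrelated at 1/2 for balanced
#' designs). Evaluated by exact 2-D Gauss-Legendre quadrature over the shared
#' normal factor and the pooled-variance chi factor; cost is independent of
#' the number of Monte-Carlo draws an equivalent simulation would need.
#'
#' @param t Non-negative quantile(s) of `max |T|`.
#' @param lambda Vector of k factor loadings in (0,1).
#' @param df Degrees of freedom of the pooled variance estimate.
#' @param nodes Quadrature nodes per dimension (default 48).
#' @return `P(max|T| <= t)`, one value per element of `t`.
#' @export
dunnett_pmax_le <- function(t, lambda, df, nodes = 48) {
  stopifnot(all(lambda > 0 & lambda < 1), df >= 1)
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  u_nodes <- sqrt(stats::qchisq(gl$x, df) / df)   # U = sqrt(chi2_df / df)
  z_nodes <- stats::qnorm(gl$x)                   # shared standard-normal factor
  w <- gl$w
  s <- sqrt(1 - lambda^2)
  lam_tab <- table(lambda)
  lam_u <- as.numeric(names(lam_tab))
  s_u <- sqrt(1 - lam_u^2)
  m_u <- as.integer(lam_tab)
  vapply(t, function(ti) {
    if (ti <= 0) return(0)
    tu <- ti * u_nodes
    M <- matrix(1, nodes, nodes)                  # rows: z, cols: u
    for (j in seq_along(lam_u)) {
      up <- outer(lam_u[j] * z_nodes, tu, "+") / s_u[j]
      lo <- outer(lam_u[j] * z_nodes, -tu, "+") / s_u[j]
      M <- M * (stats::pnorm(up) - stats::pnorm(lo))^m_u[j]
    }
    drop(t(w) %*% M %*% w)
  }, numeric(1))
}

#' Dunnett critical value
#'
#' Two-sided family-wise critical value `c` with
#' `P(max|T| >= c) = alpha` under the Dunnett null of [dunnett_pmax_le()].
#'
#' @inheritParams dunnett_pmax_le
#' @param alpha Family-wise error rate.
#' @return The critical value.
#' @export
dunnett_critical <- function(lambda, df, alpha = 0.05, nodes = 48) {
  stats::uniroot(function(t) dunnett_pmax_le(t, lambda, df, nodes) - (1 - alpha),
                 interval = c(1e-3, 50), tol = 1e-8)$root
}

#' Dunnett many-to-one test
#'
#' One-way ANOVA pooling with Dunnett's multiple-comparison adjustment:
#' the within-group variance is pooled across the control and all treatment
#' groups (`MSE`, df `= sum(n_g - 1)`); each treatment's statistic is
#' `t_i = (mean_i - mean_0) / sqrt(MSE * (1/n_i + 1/n_0))` and its adjusted
#' two-sided p-value is `P(max_j |T_j| >= |t_i|)` under the multivariate-t
#' null. With a single treatment group the adjusted p equals the ordinary
#' pooled two-sided t-test p.
#'
#' @param control Replicate values of the (stress) control group, length >= 2.
#' @param treatments Named list of replicate vectors, one per treatment group
#'   (each length >= 2 for a positive-variance contribution; length 1 is
#'   tolerated but contributes no df).
#' @param nodes Quadrature nodes for the adjustment (default 48).
#' @return Data frame `sample_id, mean, n, t, p_adj` with attributes `df`,
#'   `mse` and `control_mean`.
#' @export
dunnett_test <- function(control, treatments, nodes = 48) {
  if (length(control) < 2L) {
    stop("control group needs >= 2 replicates", call. = FALSE)
  }
  if (!length(treatments)) {
    stop("need at least one treatment group", call. = FALSE)
  }
  if (is.null(names(treatments))) {
    names(treatments) <- paste0("trt", seq_along(treatments))
  }
  groups <- c(list(control), treatments)
  n_g <- lengths(groups)
  ss <- vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))
  df <- sum(n_g - 1L)
  if (df < 1L) stop("no residual degrees of freedom", call. = FALSE)
  mse <- sum(ss) / df
  if (mse <= 0) {
    stop("degenerate variance: pooled within-group variance is zero",
         call. = FALSE)
  }
  n0 <- length(control)
  ni <- lengths(treatments)
  mi <- vapply(treatments, mean, numeric(1))
  m0 <- mean(control)
  tstat <- (mi - m0) / sqrt(mse * (1 / ni + 1 / n0))
  lambda <- sqrt(ni / (ni + n0))
  p_adj <- 1 - dunnett_pmax_le(abs(tstat), lambda, df, nodes)
  p_adj <- pmin(pmax(p_adj, 0), 1)
  out <- data.frame(sample_id = names(treatments), mean = unname(mi),
                    n = unname(ni), t = unname(tstat), p_adj = unname(p_adj),
                    stringsAsFactors = FALSE)
  attr(out, "df") <- df
  attr(out, "mse") <- mse
  attr(out, "control_mean") <- m0
  rownames(out) <- NULL
  out
}

#' Call hits against the stress control
#'
#' Runs the Dunnett test per plate family (all treatment groups sharing a
#' plate's stress control form one family; positive-control wells are not
#' part of the family) and flags, per extract: a significant decrease
#' (`p_adj < alpha` and mean below the 100% stress level), a significant
#' increase, and the >=30% reduction flag (`mean <= 70%` of the stress
#' control), the latter independent of significance.
#'
#' @param processed Output of [process_ros()] or [process_no()].
#' @param endpoint `"ros"` or `"no"` (label carried into the output).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Data frame `sample_id, endpoint, mean_pct, p_adj, direction,
#'   reduction30` covering every treatment extract.
#' @export
call_hits <- function(processed, endpoint = c("ros", "no"), alpha = 0.05) {
  endpoint <- match.arg(endpoint)
  ps <- processed$per_sample
  trt_ids <- ps$sample_id[ps$role == "treatment"]
  rows <- list()
  for (p in names(processed$control_replicates)) {
    ctrl <- processed$control_replicates[[p]]
    ids <- trt_ids[processed$sample_plate[trt_ids] == p]
    if (!length(ids)) next
    dt <- dunnett_test(ctrl, processed$replicates[ids])
    rows[[p]] <- dt
  }
  dt_all <- do.call(rbind, rows)
  idx <- match(dt_all$sample_id, ps$sample_id)
  mean_pct <- dt_all$mean
  direction <- rep("none", nrow(dt_all))
  direction[dt_all$p_adj < alpha & mean_pct < 100] <- "decrease"
  direction[dt_all$p_adj < alpha & mean_pct > 100] <- "increase"
  out <- data.frame(
    sample_id = dt_all$sample_id, endpoint = endpoint,
    mean_pct = mean_pct, p_adj = dt_all$p_adj,
    direction = direction, reduction30 = mean_pct <= 70,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$sample_id), , drop = FALSE]
}

#' Classify the selectivity of a screening hit
#'
#' Applies the fixed rule order of the screen's selectivity map: (1) `dual`
#' if both normalized levels are below 60%; (2) `no_selective` if the NO
#' decrease is significant while ROS stays above 90%; (3) `ros_selective`
#' if the ROS decrease is significant while NO stays above 90%;
#' (4) `unclassified` otherwise. Extracts excluded by the viability gate on
#' either endpoint (or with a missing endpoint) are `excluded`. Vectorized;
#' the classes partition the library.
#'
#' @param no_pct,ros_pct Normalized NO / ROS levels (% of stress control).
#' @param no_sig_decrease,ros_sig_decrease Logical: significant Dunnett
#'   decrease on that endpoint.
#' @param excluded Logical: failed the viability gate on either endpoint.
#' @return Character vector over
#'   `c("dual", "no_selective", "ros_selective", "unclassified", "excluded")`.
#' @export
classify_selectivity <- function(no_pct, ros_pct, no_sig_decrease,
                                 ros_sig_decrease, excluded = FALSE) {
  n <- max(length(no_pct), length(ros_pct))
  no_pct <- rep_len(no_pct, n); ros_pct <- rep_len(ros_pct, n)
  no_sig_decrease <- rep_len(no_sig_decrease, n)
  ros_sig_decrease <- rep_len(ros_sig_decrease, n)
  excluded <- rep_len(excluded, n)
  out <- rep("unclassified", n)
  out[no_pct < 60 & ros_pct < 60] <- "dual"
  sel_no <- out == "unclassified" & no_sig_decrease & ros_pct > 90
  out[sel_no] <- "no_selective"
  sel_ros <- out == "unclassified" & ros_sig_decrease & no_pct > 90
  out[sel_ros] <- "ros_selective"
  out[excluded | is.na(no_pct) | is.na(ros_pct)] <- "excluded"
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pairwise-complete Spearman correlation: average (mid-) ranks for ties,
#' Pearson correlation of the rank vectors, and a two-sided p-value from
#' `t = r_s * sqrt((n - 2) / (1 - r_s^2))` on `n - 2` degrees of freedom.
#' `|r_s| = 1` is reported with a p-value at the machine floor.
#'
#' @param x,y Numeric vectors of equal length; pairs with missing values are
#'   dropped. At least 3 complete pairs.
#' @return List with `r_s`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("undefined correlation: constant input vector", call. = FALSE)
  }
  rs <- stats::cor(rank(x), rank(y))
  if (abs(rs) >= 1 - 1e-15) {
    p <- .Machine$double.xmin
  } else {
    tval <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r_s = rs, p_value = p, n = n)
}
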