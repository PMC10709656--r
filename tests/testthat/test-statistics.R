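test_that("Kruskal-Wallis H matches the hand-evaluated rank-sum formula", {
  sym <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_lt(sym$H, 1e-10)

  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-10)  # 3.857
  expect_equal(kw$H, kw_by_hand(list(c(1, 2, 3), c(4, 5, 6))),
               tolerance = 1e-12)

  set.seed(501)
  for (i in 1:10) {
    g <- split(sample(100, 12), rep(1:3, each = 4))  # distinct values, no ties
    expect_equal(kruskal_wallis(g)$H, kw_by_hand(g), tolerance = 1e-10)
  }

  # p-values are a monotone transform of H at fixed group structure
  hs <- ps <- numeric(10)
  set.seed(502)
  for (i in 1:10) {
    g <- split(rnorm(15), rep(1:3, each = 5))
    r <- kruskal_wallis(g)
    hs[i] <- r$H; ps[i] <- r$p_value
  }
  expect_equal(order(hs), order(ps, decreasing = TRUE))
})

test_that("all-identical data is flagged degenerate with H = 0, p = 1", {
  r <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(r$H, 0)
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "nonempty")
})

test_that("Dunn-Sidak post hoc adjusts pairwise p-values", {
  g2 <- list(a = c(1, 5, 9, 2), b = c(7, 3, 8, 10))
  t2 <- dunn_sidak_posthoc(g2)
  expect_equal(nrow(t2), 1)
  expect_equal(t2$p_adj, t2$p_raw)  # m = 1

  # Sidak arithmetic: raw 0.05 over m = 3 comparisons
  expect_equal(1 - (1 - 0.05)^3, 0.142625)

  same <- dunn_sidak_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$z, 0)
  expect_equal(same$p_adj, 1)

  set.seed(503)
  g3 <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 3))
  t3 <- dunn_sidak_posthoc(g3)
  expect_equal(nrow(t3), 3)
  expect_true(all(t3$p_adj >= t3$p_raw))
  expect_true(all(t3$p_adj >= 0 & t3$p_adj <= 1))
  # Sidak adjustment is monotone in the raw p-value
  expect_equal(order(t3$p_raw), order(t3$p_adj))
  # significant extremes separate
  expect_lt(t3$p_adj[t3$group_i == "a" & t3$group_j == "c"], 0.05)
})

test_that("box summaries flag outliers by the 1.5 IQR fences", {
  b <- box_summary(c(1:9, 100))
  expect_equal(b$outliers, 100)
  expect_equal(b$median, 5.5)
  expect_equal(b$q1, 3)   # type-5 quantiles of 10 points
  expect_equal(b$q3, 8)
  expect_equal(b$whisker_hi, 9)

  const <- box_summary(rep(4, 6))
  expect_equal(const$q1, const$q3)
  expect_length(const$outliers, 0)

  b3 <- box_summary(c(1, 2, 3))
  expect_equal(b3$q1, 1.25)
  expect_equal(b3$q3, 2.75)
  expect_length(b3$outliers, 0)

  low <- box_summary(c(-100, 1:9))
  expect_equal(low$outliers, -100)
  expect_error(box_summary(numeric(0)), "empty")
})

test_that("population regression recovers exact linear structure", {
  grid <- expand.grid(groove_depth_nm = c(0, 330, 725),
                      ridge_width_um = c(0, 2, 4, 8),
                      groove_width_um = c(0, 2, 6))
  grid$p_elongated <- 5 + 0.03 * grid$groove_depth_nm
  r <- suppressWarnings(population_regression(grid, "p_elongated", "case1"))
  co <- r$coefficients
  expect_equal(co$estimate[co$term == "(Intercept)"], 5, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "G_D"], 0.03, tolerance = 1e-10)
  others <- co$estimate[!co$term %in% c("(Intercept)", "G_D")]
  expect_true(all(abs(others) < 1e-10))
  expect_equal(r$r_squared, 1, tolerance = 1e-10)

  grid$p_elongated <- 7
  rc <- suppressWarnings(population_regression(grid, "p_elongated", "case2"))
  expect_equal(rc$r_squared, 0)
  expect_true(all(abs(rc$coefficients$estimate[-1]) < 1e-10))

  expect_error(population_regression(grid[1:4, ], "p_elongated"), "rows")
  expect_error(population_regression(grid[, -4], "p_elongated"), "missing")
})

test_that("case filters restrict the depth range", {
  grid <- expand.grid(groove_depth_nm = c(0, 330, 725, 1000),
                      ridge_width_um = c(0, 2, 4, 8),
                      groove_width_um = c(0, 2, 6))
  grid$p_elongated <- 5 + 0.01 * grid$groove_depth_nm + rnorm(nrow(grid), 0, 0.1)
  r1 <- population_regression(grid, "p_elongated", "case1")
  r2 <- population_regression(grid, "p_elongated", "case2")
  expect_equal(r1$n, sum(grid$groove_depth_nm <= 725))
  expect_equal(r2$n, nrow(grid))
})

test_that("OLS residuals are orthogonal to the design and recovery is calibrated", {
  set.seed(504)
  grid <- expand.grid(groove_depth_nm = c(0, 330, 725, 1000),
                      ridge_width_um = c(0, 2, 4, 6, 8, 10),
                      groove_width_um = c(0, 2))
  beta0 <- 5; betaD <- 0.03; betaDR <- 2e-3
  sigma <- 3
  n_cover <- 0
  n_rep <- 200
  for (rep in seq_len(n_rep)) {
    grid$p_elongated <- beta0 + betaD * grid$groove_depth_nm +
      betaDR * grid$groove_depth_nm * grid$ridge_width_um +
      rnorm(nrow(grid), 0, sigma)
    r <- population_regression(grid, "p_elongated", "case2")
    if (rep == 1) {
      X <- stats::model.matrix(r$fit)
      expect_true(all(abs(crossprod(X, stats::residuals(r$fit))) < 1e-8))
      sse <- sum(stats::residuals(r$fit)^2)
      sst <- sum((grid$p_elongated - mean(grid$p_elongated))^2)
      expect_equal(r$r_squared, 1 - sse / sst, tolerance = 1e-10)
    }
    est <- r$coefficients$estimate[r$coefficients$term == "G_D"]
    se <- sqrt(diag(stats::vcov(r$fit)))[["G_D"]]
    if (abs(est - betaD) <= 3 * se) n_cover <- n_cover + 1
  }
  expect_gte(n_cover / n_rep, 0.95)
})
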