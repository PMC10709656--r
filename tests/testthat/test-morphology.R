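square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))

test_that("polygon_area matches closed forms and ignores orientation", {
  expect_equal(polygon_area(square), 1.0)
  expect_equal(polygon_area(square[4:1, ]), 1.0)
  circle <- make_ellipse_poly(10, 10, 0, n = 256)
  expect_lt(abs(polygon_area(circle) / (100 * pi) - 1), 0.001)
  expect_error(polygon_area(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
  expect_error(polygon_area(square[1:2, ]), "3")
})

test_that("moment-matched ellipse fit recovers shape, orientation and area", {
  poly <- make_ellipse_poly(10, 2, 30, n = 720)  # full axes 20 and 4
  f <- fit_ellipse(poly)
  expect_lt(abs(f$aspect_ratio / 5 - 1), 0.005)
  expect_lt(abs(f$orientation_deg - 30), 0.5)
  # area preserved by construction
  expect_lt(abs(pi * f$major_um * f$minor_um / 4 / f$area_um2 - 1), 1e-6)
  expect_lt(abs(f$area_um2 / polygon_area(poly) - 1), 1e-9)

  sq <- fit_ellipse(square)
  expect_equal(sq$aspect_ratio, 1.0)
  expect_equal(sq$orientation_deg, 0)

  circ <- fit_ellipse(make_ellipse_poly(7, 7, 0))
  expect_lt(abs(circ$aspect_ratio - 1), 1e-3)
})

test_that("fit agrees with the raster-moment oracle on random noisy ellipses", {
  skip_if_not_installed("mgcv")
  set.seed(301)
  for (i in 1:5) {
    a <- runif(1, 6, 10); b <- runif(1, 2, 4); rot <- runif(1, 0, 180)
    poly <- make_ellipse_poly(a, b, rot, n = 128, noise = 0.01)
    f <- fit_ellipse(poly)
    o <- raster_moments(poly, px = 0.05)
    expect_lt(abs(f$aspect_ratio / o$aspect - 1), 0.01)
    d <- abs(f$orientation_deg - o$orientation_deg) %% 180
    expect_lt(min(d, 180 - d), 1)
  }
})

test_that("area and aspect are rigid-motion invariant; orientation rotates", {
  set.seed(302)
  for (i in 1:10) {
    poly <- make_ellipse_poly(runif(1, 5, 12), runif(1, 1.5, 4),
                              runif(1, 0, 180), n = 96, noise = 0.03)
    f0 <- fit_ellipse(poly)
    shifted <- sweep(poly, 2, c(-17.3, 42.1), "+")
    f1 <- fit_ellipse(shifted)
    expect_equal(f1$area_um2, f0$area_um2, tolerance = 1e-10)
    expect_equal(f1$aspect_ratio, f0$aspect_ratio, tolerance = 1e-10)
    expect_equal(f1$orientation_deg, f0$orientation_deg, tolerance = 1e-8)
    rot <- 37 * pi / 180
    R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
    rotated <- poly %*% t(R)
    f2 <- fit_ellipse(rotated)
    expect_equal(f2$area_um2, f0$area_um2, tolerance = 1e-8)
    expect_equal(f2$aspect_ratio, f0$aspect_ratio, tolerance = 1e-8)
    expect_equal((f2$orientation_deg - f0$orientation_deg) %% 180, 37,
                 tolerance = 1e-6)
  }
})

test_that("alignment angle folds orientations onto the groove axis", {
  expect_equal(alignment_angle(90), 0)
  expect_equal(alignment_angle(0), 90)
  expect_equal(alignment_angle(150), 60)
  expect_equal(alignment_angle(c(89, 91, 179)), c(1, 1, 89))
  f <- fit_ellipse(make_ellipse_poly(10, 2, 90, n = 360))
  expect_lt(alignment_angle(f), 0.5)
})

make_records <- function(n, mitosis = rep(FALSE, n), spans = rep(FALSE, n)) {
  tibble::tibble(cell_id = sprintf("c%d", seq_len(n)),
                 condition = "G2R2D725",
                 alpha = rep(4, n), theta_deg = rep(10, n),
                 flag_mitosis = mitosis, flag_spans_flat_and_pattern = spans)
}

test_that("static exclusion rules remove flagged cells and log reasons", {
  r <- make_records(10, mitosis = c(rep(TRUE, 2), rep(FALSE, 8)))
  out <- filter_static_cells(r)
  expect_equal(sum(out$included), 8)
  expect_equal(nrow(attr(out, "exclusion_log")), 2)

  out2 <- filter_static_cells(make_records(5))
  expect_true(all(out2$included))

  both <- make_records(3, mitosis = c(TRUE, FALSE, FALSE),
                       spans = c(TRUE, FALSE, FALSE))
  out3 <- filter_static_cells(both)
  expect_equal(sum(!out3$included), 1)
  log <- attr(out3, "exclusion_log")
  expect_setequal(log$reason[log$cell_id == "c1"],
                  c("mitosis", "spans_flat_and_pattern"))

  r_bad <- make_records(3)
  r_bad$flag_mitosis[2] <- NA
  expect_error(filter_static_cells(r_bad), "c2")
  expect_error(filter_static_cells(r_bad[, -5]), "flag_mitosis")
})

test_that("aspect ratios are normalised by the control mean", {
  rec <- tibble::tibble(condition = c("control", "control", "G2R2"),
                        alpha = c(3, 5, 12))
  out <- normalize_aspect_ratios(rec)
  expect_equal(attr(out, "alpha_cont"), 4)
  expect_equal(out$alpha_bar, c(0.75, 1.25, 3))

  rec2 <- tibble::tibble(condition = c("control", "G2R2"), alpha = c(4, 8))
  expect_equal(normalize_aspect_ratios(rec2)$alpha_bar, c(1, 2))
  expect_error(normalize_aspect_ratios(rec[3, ]), "control")

  med <- normalize_aspect_ratios(
    tibble::tibble(condition = rep("control", 3), alpha = c(2, 4, 100)),
    stat = "median")
  expect_equal(attr(med, "alpha_cont"), 4)
})

test_that("population fractions use inclusive thresholds", {
  rec <- tibble::tibble(condition = "x", alpha = c(5, 3.8, 4),
                        alpha_bar = c(2.5, 1.9, 2.0),
                        theta_deg = c(1, 2, 3))
  f <- population_fractions(rec)
  expect_equal(f$p_elongated, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(f$p_aligned, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(f$n_cells, 3L)

  single <- population_fractions(
    tibble::tibble(condition = "x", alpha = 1, alpha_bar = 1, theta_deg = 45))
  expect_equal(single$p_elongated, 0)
  expect_equal(single$p_aligned, 0)

  # monotone in the thresholds
  loose <- population_fractions(rec, elong_threshold = 1.5, align_threshold = 5)
  expect_gte(loose$p_elongated, f$p_elongated)
  expect_gte(loose$p_aligned, f$p_aligned)
  strict <- population_fractions(rec, elong_threshold = 3, align_threshold = 0.5)
  expect_lte(strict$p_elongated, f$p_elongated)
  expect_lte(strict$p_aligned, f$p_aligned)
})

test_that("alignment histogram bins, normalisation and edge rule", {
  h0 <- alignment_histogram(rep(0, 50))
  expect_equal(nrow(h0), 45)
  expect_equal(h0$fraction[1], 1)
  expect_equal(sum(h0$fraction[-1]), 0)

  h90 <- alignment_histogram(90)
  expect_equal(h90$fraction[45], 1)
  expect_equal(h90$bin_lo[45], 88)

  set.seed(303)
  hu <- alignment_histogram(runif(1e4, 0, 90))
  expect_lt(abs(sum(hu$fraction) - 1), 1e-12)
  expect_gt(stats::chisq.test(hu$fraction * attr(hu, "n_samples"))$p.value,
            0.01)
  expect_true(all(diff(hu$cum_fraction) >= 0))
  expect_equal(hu$cum_fraction[45], 1, tolerance = 1e-12)

  expect_error(alignment_histogram(numeric(0)), "empty")
  expect_error(alignment_histogram(91), "\\[0, 90\\]")
})
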