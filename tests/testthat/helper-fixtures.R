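# Fixtures and independent oracles used across the suite. Everything here is
# built in code; nothing is read from disk.

# Discretised ellipse polygon from semi-axes a >= b and a rotation angle, in
# degrees counterclockwise from +x. Independent of the package's generator.
make_ellipse_poly <- function(a, b, rot_deg, n = 256, noise = 0, centre = c(0, 0)) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  px <- a * cos(t)
  py <- b * sin(t)
  if (noise > 0) {
    px <- px * (1 + noise * rnorm(n))
    py <- py * (1 + noise * rnorm(n))
  }
  r <- rot_deg * pi / 180
  cbind(x_um = centre[1] + px * cos(r) - py * sin(r),
        y_um = centre[2] + px * sin(r) + py * cos(r))
}

# Raster oracle: pixelate the polygon and compute discrete area moments.
# Returns the aspect ratio (sqrt of the covariance eigenvalue ratio) and the
# principal-axis orientation in [0, 180). Uses mgcv::in.out for the
# point-in-polygon test; entirely independent of the exact polygon-integral
# path used by fit_ellipse().
raster_moments <- function(poly, px = 0.05) {
  stopifnot(requireNamespace("mgcv", quietly = TRUE))
  xr <- range(poly[, 1]) + c(-2, 2) * px
  yr <- range(poly[, 2]) + c(-2, 2) * px
  gx <- seq(xr[1], xr[2], by = px)
  gy <- seq(yr[1], yr[2], by = px)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  bnd <- rbind(poly, poly[1, ])
  inside <- mgcv::in.out(bnd, grid)
  pts <- grid[inside, , drop = FALSE]
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  cxx <- mean((pts[, 1] - mx)^2)
  cyy <- mean((pts[, 2] - my)^2)
  cxy <- mean((pts[, 1] - mx) * (pts[, 2] - my))
  tr <- cxx + cyy
  disc <- sqrt(((cxx - cyy) / 2)^2 + cxy^2)
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  orient <- (atan2(2 * cxy, cxx - cyy) / 2) * 180 / pi
  list(aspect = sqrt(l1 / l2), orientation_deg = orient %% 180,
       n_pixels = nrow(pts))
}

# Hand evaluation of the Kruskal-Wallis rank-sum formula (no tie handling;
# use on tie-free data only). Independent of stats::kruskal.test.
kw_by_hand <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  stopifnot(!anyDuplicated(values))
  r <- rank(values)
  n <- lengths(groups)
  N <- length(values)
  g <- rep(seq_along(groups), n)
  rs <- tapply(r, g, sum)
  12 / (N * (N + 1)) * sum(rs^2 / n) - 3 * (N + 1)
}

# Straight-line track builder.
straight_track <- function(vx, vy, n_steps = 10, dt = 10) {
  t <- seq(0, by = dt, length.out = n_steps + 1)
  data.frame(t_min = t, x_um = vx * t, y_um = vy * t)
}

# Track from a sequence of per-interval step vectors.
track_from_steps <- function(steps_x, steps_y, dt = 10) {
  data.frame(t_min = seq(0, by = dt, length.out = length(steps_x) + 1),
             x_um = c(0, cumsum(steps_x)),
             y_um = c(0, cumsum(steps_y)))
}

# Long-format cohort tibble from a list of per-cell track data frames.
as_cohort <- function(tracks, condition = "G2R2D725", on_pattern = TRUE) {
  do.call(rbind, lapply(seq_along(tracks), function(i) {
    d <- tracks[[i]]
    tibble::tibble(cell_id = sprintf("cell%03d", i), t_min = d$t_min,
                   x_um = d$x_um, y_um = d$y_um, condition = condition,
                   on_pattern = on_pattern)
  }))
}
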