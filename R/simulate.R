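# Synthetic-data generator: anisotropic persistent random walks for nucleus
# tracks and noisy discretised ellipses for cell outlines. The generator
# emulates the statistical structure of live-cell recordings on ridge/groove
# substrates (10-min sampling, ~10-h tracks, speeds of a few tenths of a
# um/min, axial alignment that strengthens with groove depth); it is the
# ground-truth source for the parameter-recovery tests.

#' Simulation parameters
#'
#' Bundles and validates every knob of the synthetic-data generator. Defaults
#' describe a control-like cohort at the study's imaging cadence: 10-min
#' sampling, 600-min tracks, around 30 cells per condition, mean path speed
#' 0.35 um/min, isotropic headings and outline orientations.
#'
#' @param n_cells Number of cells to generate (positive integer).
#' @param duration_min Track duration in minutes (default 600, i.e. 10 h).
#' @param dt_min Sampling interval in minutes (default 10).
#' @param base_speed_um_per_min Mean path speed in um/min (default 0.35).
#' @param speed_sd Standard deviation of per-step speed in um/min (default
#'   0.1; 0 gives constant step lengths).
#' @param persistence Heading autocorrelation per step, in `[0, 1)`: the
#'   expected cosine of the heading change over one interval when
#'   `axis_bias = 0`. 0 draws an independent heading every step.
#' @param axis_bias Concentration of the heading pull toward the nearer of
#'   the +/- groove axis (+/- y); 0 is the isotropic (control-like) regime.
#' @param outline_mean_aspect Mean outline aspect ratio (>= 1).
#' @param outline_aspect_sd Standard deviation of the aspect ratio (0 fixes
#'   it at the mean).
#' @param outline_orientation_concentration Concentration of the axial
#'   (period-pi) orientation distribution of outline major axes about the
#'   groove axis; 0 is uniform.
#' @param outline_area_mean_um2 Mean outline area in um^2 (default 2400,
#'   a typical patterned-substrate fibroblast spread area).
#' @param outline_area_sd_um2 Standard deviation of the area (0 fixes it).
#' @param outline_noise Relative radial noise applied to outline vertices
#'   (standard deviation as a fraction of the local radius; default 0.05).
#' @param n_vertices Vertices per outline polygon (default 64).
#' @param fixed_orientation_deg If non-`NULL`, every outline major axis is
#'   fixed at this angle (degrees counterclockwise from +x) instead of being
#'   drawn from the axial distribution.
#' @param p_flag_mitosis Probability that a cell is flagged as mitotic.
#' @param p_flag_spans Probability that a cell is flagged as spanning both
#'   flat and patterned regions.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_cells = 30,
                       duration_min = 600,
                       dt_min = 10,
                       base_speed_um_per_min = 0.35,
                       speed_sd = 0.1,
                       persistence = 0.7,
                       axis_bias = 0,
                       outline_mean_aspect = 4.8,
                       outline_aspect_sd = 2,
                       outline_orientation_concentration = 0,
                       outline_area_mean_um2 = 2400,
                       outline_area_sd_um2 = 600,
                       outline_noise = 0.05,
                       n_vertices = 64,
                       fixed_orientation_deg = NULL,
                       p_flag_mitosis = 0.05,
                       p_flag_spans = 0.05,
                       seed = 1L) {
  p <- list(n_cells = as.integer(n_cells), duration_min = duration_min,
            dt_min = dt_min, base_speed_um_per_min = base_speed_um_per_min,
            speed_sd = speed_sd, persistence = persistence,
            axis_bias = axis_bias, outline_mean_aspect = outline_mean_aspect,
            outline_aspect_sd = outline_aspect_sd,
            outline_orientation_concentration = outline_orientation_concentration,
            outline_area_mean_um2 = outline_area_mean_um2,
            outline_area_sd_um2 = outline_area_sd_um2,
            outline_noise = outline_noise, n_vertices = as.integer(n_vertices),
            fixed_orientation_deg = fixed_orientation_deg,
            p_flag_mitosis = p_flag_mitosis, p_flag_spans = p_flag_spans,
            seed = as.integer(seed))
  if (p$n_cells < 0) stop("n_cells must be nonnegative")
  if (p$duration_min <= 0) stop("duration_min must be positive")
  if (p$dt_min <= 0) stop("dt_min must be positive")
  if (p$base_speed_um_per_min <= 0) stop("base_speed_um_per_min must be positive")
  if (p$speed_sd < 0) stop("speed_sd must be nonnegative")
  if (p$persistence < 0 || p$persistence >= 1) stop("persistence must be in [0, 1)")
  if (p$axis_bias < 0) stop("axis_bias must be nonnegative")
  if (p$outline_mean_aspect < 1) stop("outline_mean_aspect must be >= 1")
  if (p$outline_orientation_concentration < 0) {
    stop("outline_orientation_concentration must be nonnegative")
  }
  if (p$n_vertices < 8) stop("n_vertices must be at least 8")
  structure(p, class = "sim_params")
}

# Positive per-step lengths with mean mu and sd sigma (gamma; degenerate at
# sigma = 0).
.step_lengths <- function(n, mu, sigma) {
  if (sigma <= 0) return(rep(mu, n))
  shape <- (mu / sigma)^2
  stats::rgamma(n, shape = shape, rate = shape / mu)
}

#' Simulate nucleus trajectories
#'
#' Generates `n_cells` planar random-walk tracks on a regular `dt_min` time
#' grid. Headings evolve by a wrapped-normal update whose mean is the
#' resultant of a persistence pull toward the current heading and an axial
#' pull (concentration `axis_bias`) toward the nearer of the +/- groove axis
#' (+y convention), so the stationary heading distribution is axis-symmetric
#' and folded: +y and -y motion are equally likely. Step lengths are
#' gamma-distributed with mean `base_speed_um_per_min * dt_min`. Headings are
#' burned in for 20 updates before positions are recorded so recorded tracks
#' start at the stationary heading distribution.
#'
#' @param params A [sim_params()] object.
#' @param condition A `substrate_condition`; its label is attached to every
#'   track.
#' @return A tibble with columns `cell_id`, `t_min`, `x_um`, `y_um`,
#'   `condition`, `on_pattern`, one row per (cell, time) sample, plus a
#'   `"params"` attribute.
#' @export
simulate_trajectories <- function(params, condition) {
  stopifnot(inherits(params, "sim_params"),
            inherits(condition, "substrate_condition"))
  n <- params$n_cells
  n_steps <- round(params$duration_min / params$dt_min)
  if (n_steps < 1) stop("duration_min must cover at least one sampling interval")
  times <- seq(0, by = params$dt_min, length.out = n_steps + 1)
  if (n == 0L) {
    return(tibble::tibble(cell_id = character(), t_min = numeric(),
                          x_um = numeric(), y_um = numeric(),
                          condition = character(), on_pattern = logical()))
  }
  kp <- .vm_kappa(params$persistence)
  ka <- params$axis_bias
  mu_step <- params$base_speed_um_per_min * params$dt_min
  sd_step <- params$speed_sd * params$dt_min
  res <- .with_seed(params$seed, {
    x <- matrix(0, nrow = n_steps + 1, ncol = n)
    y <- matrix(0, nrow = n_steps + 1, ncol = n)
    x[1, ] <- stats::runif(n, 0, 500)
    y[1, ] <- stats::runif(n, 0, 500)
    phi <- stats::runif(n, -pi, pi)
    for (b in seq_len(20)) phi <- .step_heading(phi, kp, ka)
    for (s in seq_len(n_steps)) {
      phi <- .step_heading(phi, kp, ka)
      len <- .step_lengths(n, mu_step, sd_step)
      x[s + 1, ] <- x[s, ] + len * cos(phi)
      y[s + 1, ] <- y[s, ] + len * sin(phi)
    }
    list(x = x, y = y)
  })
  ids <- sprintf("%s_c%03d", condition$label, seq_len(n))
  out <- tibble::tibble(
    cell_id = rep(ids, each = n_steps + 1),
    t_min = rep(times, times = n),
    x_um = as.vector(res$x),
    y_um = as.vector(res$y),
    condition = condition$label,
    on_pattern = TRUE
  )
  attr(out, "params") <- params
  out
}

# Build one noisy discretised ellipse polygon (counterclockwise).
.ellipse_polygon <- function(area, aspect, orientation_deg, n_vertices, noise) {
  b <- sqrt(area / (pi * aspect))  # minor semi-axis
  a <- aspect * b
  t <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  px <- a * cos(t)
  py <- b * sin(t)
  if (noise > 0) {
    px <- px * (1 + noise * stats::rnorm(n_vertices))
    py <- py * (1 + noise * stats::rnorm(n_vertices))
  }
  th <- orientation_deg * pi / 180
  cbind(x_um = px * cos(th) - py * sin(th),
        y_um = px * sin(th) + py * cos(th))
}

#' Simulate cell outlines
#'
#' Generates `n_cells` simple polygons as noisy discretised ellipses. The
#' major-axis orientation is drawn from an axial (period-pi) distribution
#' about the groove axis with concentration
#' `outline_orientation_concentration` (0 = uniform, so the alignment angle
#' is uniform on 0-90 degrees); the aspect ratio and area are drawn from
#' positive distributions with the stated means. Mitosis and
#' flat/pattern-spanning exclusion flags are sampled at the configured rates.
#'
#' @param params A [sim_params()] object.
#' @param condition A `substrate_condition`.
#' @return A list of class `outline_set` with elements `vertices` (tibble
#'   `cell_id`, `vertex_index`, `x_um`, `y_um`) and `cells` (tibble
#'   `cell_id`, `condition`, `flag_mitosis`, `flag_spans_flat_and_pattern`,
#'   plus ground-truth columns `true_area_um2`, `true_aspect`,
#'   `true_orientation_deg`).
#' @export
simulate_outlines <- function(params, condition) {
  stopifnot(inherits(params, "sim_params"),
            inherits(condition, "substrate_condition"))
  n <- params$n_cells
  ids <- sprintf("%s_o%03d", condition$label, seq_len(n))
  if (n == 0L) {
    empty_v <- tibble::tibble(cell_id = character(), vertex_index = integer(),
                              x_um = numeric(), y_um = numeric())
    empty_c <- tibble::tibble(cell_id = character(), condition = character(),
                              flag_mitosis = logical(),
                              flag_spans_flat_and_pattern = logical(),
                              true_area_um2 = numeric(), true_aspect = numeric(),
                              true_orientation_deg = numeric())
    return(structure(list(vertices = empty_v, cells = empty_c),
                     class = "outline_set"))
  }
  res <- .with_seed(params$seed + 1L, {
    # areas: lognormal with the stated mean/sd (degenerate at sd = 0)
    if (params$outline_area_sd_um2 <= 0) {
      areas <- rep(params$outline_area_mean_um2, n)
    } else {
      cv2 <- (params$outline_area_sd_um2 / params$outline_area_mean_um2)^2
      sdlog <- sqrt(log1p(cv2))
      areas <- stats::rlnorm(n, log(params$outline_area_mean_um2) - sdlog^2 / 2,
                             sdlog)
    }
    aspects <- 1 + .step_lengths(n, params$outline_mean_aspect - 1,
                                 params$outline_aspect_sd)
    if (params$outline_mean_aspect == 1) aspects <- rep(1, n)
    if (!is.null(params$fixed_orientation_deg)) {
      orients <- rep(params$fixed_orientation_deg, n)
    } else {
      # axial distribution about the groove axis (+y = 90 deg): draw the
      # doubled angle from a circular law with the stated concentration
      kap <- params$outline_orientation_concentration
      if (kap < 1e-8) {
        chi <- stats::runif(n, -pi, pi)
      } else {
        sigma <- sqrt(-2 * log(.vm_rho(kap)))
        chi <- .wrap_angle(sigma * stats::rnorm(n))
      }
      orients <- (90 + chi * 90 / pi) %% 180
    }
    polys <- vector("list", n)
    for (i in seq_len(n)) {
      polys[[i]] <- .ellipse_polygon(areas[i], aspects[i], orients[i],
                                     params$n_vertices, params$outline_noise)
    }
    flags_m <- stats::runif(n) < params$p_flag_mitosis
    flags_s <- stats::runif(n) < params$p_flag_spans
    list(areas = areas, aspects = aspects, orients = orients, polys = polys,
         flags_m = flags_m, flags_s = flags_s)
  })
  vertices <- tibble::tibble(
    cell_id = rep(ids, each = params$n_vertices),
    vertex_index = rep(seq_len(params$n_vertices), times = n),
    x_um = unlist(lapply(res$polys, function(p) p[, 1])),
    y_um = unlist(lapply(res$polys, function(p) p[, 2]))
  )
  cells <- tibble::tibble(
    cell_id = ids,
    condition = condition$label,
    flag_mitosis = res$flags_m,
    flag_spans_flat_and_pattern = res$flags_s,
    true_area_um2 = res$areas,
    true_aspect = res$aspects,
    true_orientation_deg = res$orients
  )
  structure(list(vertices = vertices, cells = cells), class = "outline_set")
}

#' Per-condition simulation parameters for the study's depth series
#'
#' Maps a substrate condition onto generator parameters that reproduce the
#' qualitative structure of the study: axial bias and outline
#' alignment/elongation rise steeply from the flat control to a 725-nm groove
#' depth and saturate (weakly reverse) at 1000 nm, mean path speed dips at
#' 725 nm, and narrower ridges strengthen elongation and alignment. The
#' depth anchors are fixed package choices (there is no mechanistic
#' depth-to-bias law); intermediate depths are linearly interpolated.
#'
#' @param condition A `substrate_condition`.
#' @param base A [sim_params()] object supplying everything not covered by
#'   the map (cell count, cadence, seed, noise levels).
#' @return A [sim_params()] object for this condition.
#' @export
condition_sim_params <- function(condition, base = sim_params()) {
  stopifnot(inherits(condition, "substrate_condition"),
            inherits(base, "sim_params"))
  depths <- c(0, 330, 725, 1000)
  bias_map <- c(0, 1.5, 6, 5.5)
  speed_map <- c(0.39, 0.35, 0.25, 0.29)
  aspect_map <- c(4.81, 5.92, 8.66, 7.64)
  conc_map <- c(0, 2, 8, 7)
  area_map <- c(2816.8, 2365.3, 2115.3, 2259.4)
  d <- min(condition$groove_depth_nm, 1000)
  interp <- function(map) stats::approx(depths, map, xout = d)$y
  # narrower ridges confine focal adhesions: scale anisotropy down as the
  # ridge widens (ridge width matters more than groove width)
  rw <- condition$ridge_width_um
  lateral <- if (is_control_condition(condition)) 1 else 1 / (1 + 0.08 * max(rw - 2, 0))
  p <- unclass(base)
  p$base_speed_um_per_min <- interp(speed_map)
  p$axis_bias <- interp(bias_map) * lateral
  p$outline_mean_aspect <- 1 + (interp(aspect_map) - 1) * lateral
  p$outline_orientation_concentration <- interp(conc_map) * lateral
  p$outline_area_mean_um2 <- interp(area_map)
  do.call(sim_params, p[setdiff(names(p), character(0))])
}

#' Write a fixture set to disk
#'
#' Simulates trajectories and outlines for every condition and writes them as
#' CSV files (one trajectory file, one outline-vertex file, one flags file
#' and one ground-truth file per condition) together with a plain-text
#' key-value manifest enumerating seeds and file paths. Per-condition seeds
#' are derived deterministically from `params$seed`, so re-running with the
#' same inputs reproduces byte-identical payloads.
#'
#' @param conditions A list of `substrate_condition` objects.
#' @param params A [sim_params()] object (its seed is the master seed).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the manifest as a named list; also written to
#'   `manifest.txt`.
#' @export
write_fixture_set <- function(conditions, params, out_dir) {
  stopifnot(is.list(conditions), inherits(params, "sim_params"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop(sprintf("cannot write to directory '%s'", out_dir))
  }
  manifest <- list(master_seed = params$seed,
                   n_conditions = length(conditions))
  truth_all <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[[i]]
    p_i <- params
    p_i$seed <- params$seed + 1000L * i
    tracks <- simulate_trajectories(p_i, cond)
    outl <- simulate_outlines(p_i, cond)
    stem <- gsub("[^A-Za-z0-9]", "_", cond$label)
    track_file <- file.path(out_dir, sprintf("tracks_%s.csv", stem))
    vert_file <- file.path(out_dir, sprintf("outlines_%s.csv", stem))
    flag_file <- file.path(out_dir, sprintf("flags_%s.csv", stem))
    write_trajectories(tracks, track_file)
    write_outlines(outl, vert_file, flag_file)
    manifest[[sprintf("condition_%d", i)]] <- cond$label
    manifest[[sprintf("seed_%d", i)]] <- p_i$seed
    manifest[[sprintf("tracks_%d", i)]] <- basename(track_file)
    manifest[[sprintf("outlines_%d", i)]] <- basename(vert_file)
    manifest[[sprintf("flags_%d", i)]] <- basename(flag_file)
    truth_all[[i]] <- outl$cells[, c("cell_id", "condition", "true_area_um2",
                                     "true_aspect", "true_orientation_deg")]
  }
  truth <- do.call(rbind, truth_all)
  truth_file <- file.path(out_dir, "ground_truth.csv")
  if (!is.null(truth)) utils::write.csv(truth, truth_file, row.names = FALSE)
  manifest$ground_truth <- basename(truth_file)
  lines <- sprintf("%s: %s", names(manifest),
                   vapply(manifest, function(v) as.character(v), character(1)))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
  invisible(manifest)
}
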