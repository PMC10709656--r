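# Static morphology: polygon geometry, moment-matched ellipse fits, alignment
# angles, exclusion filtering, aspect-ratio normalisation, population
# fractions and alignment histograms.

# Coerce an outline to a 2-column vertex matrix.
.as_vertex_matrix <- function(vertices) {
  if (is.data.frame(vertices)) {
    cols <- intersect(c("x_um", "y_um"), names(vertices))
    if (length(cols) == 2) {
      vertices <- cbind(vertices$x_um, vertices$y_um)
    } else if (all(c("x", "y") %in% names(vertices))) {
      vertices <- cbind(vertices$x, vertices$y)
    } else {
      stop("vertex data frame must have columns x_um/y_um (or x/y)")
    }
  }
  v <- as.matrix(vertices)
  if (ncol(v) != 2 || nrow(v) < 3) {
    stop("an outline needs at least 3 planar vertices")
  }
  storage.mode(v) <- "double"
  if (any(!is.finite(v))) stop("outline vertices must be finite")
  # drop a duplicated closing vertex
  if (isTRUE(all.equal(v[1, ], v[nrow(v), ], check.attributes = FALSE))) {
    v <- v[-nrow(v), , drop = FALSE]
  }
  if (nrow(v) < 3) stop("an outline needs at least 3 distinct vertices")
  v
}

#' Polygon area of a cell outline
#'
#' Shoelace area of a simple closed polygon, in um^2; independent of vertex
#' orientation (the absolute value is returned).
#'
#' @param vertices A 2-column matrix or a data frame with columns
#'   `x_um`, `y_um` (vertices in order; an explicit closing vertex is
#'   optional).
#' @return Area in um^2 (positive).
#' @export
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # 1
polygon_area <- function(vertices) {
  v <- .as_vertex_matrix(vertices)
  a <- .polygon_moments(v)$area_signed
  if (abs(a) < 1e-9) stop("degenerate polygon: area is (numerically) zero")
  abs(a)
}

# Exact area, centroid and second central moments of a polygonal region via
# Green's-theorem edge sums. Returns signed area; centroid and covariance are
# orientation-independent.
.polygon_moments <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.xmin) {
    return(list(area_signed = 0))
  }
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  ixx <- sum(cr * (x^2 + x * xn + xn^2)) / 12
  iyy <- sum(cr * (y^2 + y * yn + yn^2)) / 12
  ixy <- sum(cr * (2 * x * y + x * yn + xn * y + 2 * xn * yn)) / 24
  cov <- matrix(c(ixx / a - cx^2, ixy / a - cx * cy,
                  ixy / a - cx * cy, iyy / a - cy^2), 2, 2)
  list(area_signed = a, centroid = c(cx, cy), cov = cov)
}

#' Moment-matched ellipse fit of a cell outline
#'
#' Fits the ellipse whose area, centroid, principal-axis direction and
#' second-moment ratio match those of the filled polygonal region (moments
#' computed by exact polygon integrals, i.e. the region is treated as a
#' uniform lamina, matching how image-analysis tools fit outlines of filled
#' shapes). The aspect ratio is the square root of the ratio of the
#' covariance eigenvalues; the axes are then scaled jointly so the ellipse
#' area equals the polygon area exactly. An isotropic covariance (e.g. a
#' square or circle) resolves the orientation to 0 degrees.
#'
#' @inheritParams polygon_area
#' @return A list of class `ellipse_fit`: `area_um2`, `major_um`,
#'   `minor_um` (full axis lengths), `aspect_ratio` (major/minor, >= 1),
#'   `orientation_deg` (major-axis direction in `[0, 180)`, counterclockwise
#'   from +x) and `centroid_um`.
#' @export
fit_ellipse <- function(vertices) {
  v <- .as_vertex_matrix(vertices)
  m <- .polygon_moments(v)
  if (abs(m$area_signed) < 1e-9) {
    stop("degenerate polygon: area is (numerically) zero")
  }
  area <- abs(m$area_signed)
  cov <- m$cov
  tr <- cov[1, 1] + cov[2, 2]
  diff <- cov[1, 1] - cov[2, 2]
  disc <- sqrt((diff / 2)^2 + cov[1, 2]^2)
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  l2 <- max(l2, 0)
  if (l2 <= 0) stop("degenerate polygon: zero minor second moment")
  if (disc <= 1e-12 * tr) {
    orientation <- 0
    aspect <- 1
  } else {
    orientation <- (atan2(2 * cov[1, 2], diff) / 2) * 180 / pi
    orientation <- orientation %% 180
    aspect <- sqrt(l1 / l2)
  }
  minor <- 2 * sqrt(area / (pi * aspect))  # full axes; pi*maj*min/4 = area
  major <- aspect * minor
  structure(list(area_um2 = area, major_um = major, minor_um = minor,
                 aspect_ratio = aspect, orientation_deg = orientation,
                 centroid_um = m$centroid),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit> area %.2f um^2, aspect %.3f, orientation %.2f deg\n",
              x$area_um2, x$aspect_ratio, x$orientation_deg))
  invisible(x)
}

#' Alignment angle of a major axis to the groove direction
#'
#' Folds a major-axis orientation (degrees counterclockwise from +x,
#' period 180) into the acute angle to the groove axis. The groove axis is
#' +y (90 degrees) by package convention; control-substrate cells use the
#' same reference axis for bookkeeping.
#'
#' @param orientation_deg Numeric vector of orientations in degrees, or an
#'   `ellipse_fit`.
#' @param groove_axis_deg Direction of the groove axis (default 90, i.e. +y).
#' @return Alignment angle(s) theta in `[0, 90]` degrees.
#' @export
#' @examples
#' alignment_angle(90)   # parallel to the grooves -> 0
#' alignment_angle(0)    # perpendicular -> 90
#' alignment_angle(150)  # -> 60
alignment_angle <- function(orientation_deg, groove_axis_deg = 90) {
  if (inherits(orientation_deg, "ellipse_fit")) {
    orientation_deg <- orientation_deg$orientation_deg
  }
  stopifnot(is.numeric(orientation_deg))
  d <- abs(orientation_deg - groove_axis_deg) %% 180
  pmin(d, 180 - d)
}

#' Per-cell morphology table of an outline set
#'
#' Fits every outline and tabulates area, aspect ratio, raw orientation and
#' alignment angle together with the exclusion flags.
#'
#' @param outlines An `outline_set` (from [simulate_outlines()] or
#'   [read_outlines()]).
#' @return A tibble with one row per cell: `cell_id`, `condition`,
#'   `area_um2`, `alpha` (aspect ratio), `orientation_deg`, `theta_deg`
#'   (alignment angle) and the two flag columns.
#' @export
morphology_table <- function(outlines) {
  stopifnot(inherits(outlines, "outline_set"))
  cells <- outlines$cells
  verts <- outlines$vertices
  idx <- split(seq_len(nrow(verts)), verts$cell_id)
  fit_one <- function(id) {
    fit_ellipse(verts[idx[[id]], c("x_um", "y_um")])
  }
  fits <- lapply(cells$cell_id, fit_one)
  tibble::tibble(
    cell_id = cells$cell_id,
    condition = cells$condition,
    area_um2 = vapply(fits, `[[`, numeric(1), "area_um2"),
    alpha = vapply(fits, `[[`, numeric(1), "aspect_ratio"),
    orientation_deg = vapply(fits, `[[`, numeric(1), "orientation_deg"),
    theta_deg = alignment_angle(
      vapply(fits, `[[`, numeric(1), "orientation_deg")),
    flag_mitosis = cells$flag_mitosis,
    flag_spans_flat_and_pattern = cells$flag_spans_flat_and_pattern
  )
}

#' Apply the static-analysis exclusion rules
#'
#' Excludes cells that underwent mitosis and cells that spread over both the
#' flat and the patterned area of a substrate. The exclusion counts and
#' per-cell reasons are recorded in the `"exclusion_log"` attribute.
#'
#' @param records A morphology tibble with logical columns `flag_mitosis`
#'   and `flag_spans_flat_and_pattern` (see [morphology_table()]).
#' @return `records` with an added logical column `included`; excluded rows
#'   are retained but marked. Attribute `"exclusion_log"` is a tibble of
#'   `cell_id`, `reason`.
#' @export
filter_static_cells <- function(records) {
  need <- c("flag_mitosis", "flag_spans_flat_and_pattern")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop(sprintf("missing flag columns: %s", paste(miss, collapse = ", ")))
  }
  bad <- is.na(records$flag_mitosis) | is.na(records$flag_spans_flat_and_pattern)
  if (any(bad)) {
    stop(sprintf("missing flags for cells: %s",
                 paste(records$cell_id[bad], collapse = ", ")))
  }
  log <- rbind(
    data.frame(cell_id = records$cell_id[records$flag_mitosis],
               reason = rep("mitosis", sum(records$flag_mitosis)),
               stringsAsFactors = FALSE),
    data.frame(cell_id = records$cell_id[records$flag_spans_flat_and_pattern],
               reason = rep("spans_flat_and_pattern",
                            sum(records$flag_spans_flat_and_pattern)),
               stringsAsFactors = FALSE)
  )
  records$included <- !(records$flag_mitosis | records$flag_spans_flat_and_pattern)
  attr(records, "exclusion_log") <- tibble::as_tibble(log)
  records
}

#' Normalise aspect ratios by the control cohort
#'
#' Adds the normalised aspect ratio `alpha_bar = alpha / alpha_Cont`, where
#' `alpha_Cont` is the mean (optionally median) aspect ratio of included
#' cells on the flat control substrate, pooled across the dataset.
#'
#' @param records A morphology tibble with columns `condition`, `alpha` and
#'   (optionally) `included`; rows with `included = FALSE` are ignored when
#'   computing `alpha_Cont` but still receive `alpha_bar`.
#' @param control_label Condition label of the flat control (default
#'   `"control"`).
#' @param stat `"mean"` (default) or `"median"`.
#' @return `records` with an added `alpha_bar` column and an
#'   `"alpha_cont"` attribute.
#' @export
normalize_aspect_ratios <- function(records, control_label = "control",
                                    stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(all(c("condition", "alpha") %in% names(records)))
  inc <- if ("included" %in% names(records)) records$included else TRUE
  ctrl <- records$alpha[records$condition == control_label & inc]
  if (length(ctrl) == 0) {
    stop(sprintf("no included control cells (condition '%s')", control_label))
  }
  alpha_cont <- if (stat == "mean") mean(ctrl) else stats::median(ctrl)
  records$alpha_bar <- records$alpha / alpha_cont
  attr(records, "alpha_cont") <- alpha_cont
  records
}

#' Elongated and aligned population fractions
#'
#' Summarises, per group, the percentage of elongated cells (normalised
#' aspect ratio `alpha_bar >= elong_threshold`) and of aligned cells
#' (alignment angle `theta_deg <= align_threshold` degrees), both with
#' inclusive comparisons, together with the mean aspect ratio and mean
#' alignment angle. Only rows with `included = TRUE` (when present)
#' contribute.
#'
#' @param records A morphology tibble with `alpha`, `alpha_bar`, `theta_deg`
#'   and a grouping column.
#' @param by Name of the grouping column (default `"condition"`); use
#'   `NULL` to summarise all rows as one group.
#' @param elong_threshold Elongation threshold on `alpha_bar` (default 2).
#' @param align_threshold Alignment threshold on `theta_deg` in degrees
#'   (default 2).
#' @return A tibble with columns `group`, `n_cells`, `p_elongated`,
#'   `p_aligned` (percentages), `alpha_mean`, `theta_mean`.
#' @export
population_fractions <- function(records, by = "condition",
                                 elong_threshold = 2, align_threshold = 2) {
  stopifnot(all(c("alpha", "alpha_bar", "theta_deg") %in% names(records)))
  if ("included" %in% names(records)) records <- records[records$included, ]
  if (nrow(records) == 0) stop("no included cells to summarise")
  groups <- if (is.null(by)) rep("all", nrow(records)) else records[[by]]
  parts <- split(records, groups)
  tibble::tibble(
    group = names(parts),
    n_cells = vapply(parts, nrow, integer(1), USE.NAMES = FALSE),
    p_elongated = vapply(parts, function(d)
      100 * mean(d$alpha_bar >= elong_threshold), numeric(1),
      USE.NAMES = FALSE),
    p_aligned = vapply(parts, function(d)
      100 * mean(d$theta_deg <= align_threshold), numeric(1),
      USE.NAMES = FALSE),
    alpha_mean = vapply(parts, function(d) mean(d$alpha), numeric(1),
                        USE.NAMES = FALSE),
    theta_mean = vapply(parts, function(d) mean(d$theta_deg), numeric(1),
                        USE.NAMES = FALSE)
  )
}

# Shared binned-fraction helper: half-open bins [lo, hi), top edge included
# in the last bin.
.occurrence_bins <- function(values, bin_deg, range_max) {
  if (length(values) == 0) stop("empty input: nothing to bin")
  if (any(!is.finite(values)) || any(values < 0) || any(values > range_max)) {
    stop(sprintf("values must lie in [0, %g]", range_max))
  }
  n_bins <- as.integer(round(range_max / bin_deg))
  if (!isTRUE(all.equal(n_bins * bin_deg, range_max))) {
    stop(sprintf("bin width %g does not tile [0, %g]", bin_deg, range_max))
  }
  idx <- pmin(floor(values / bin_deg) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  edges <- seq(0, range_max, by = bin_deg)
  out <- tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                        fraction = counts / length(values))
  attr(out, "n_samples") <- length(values)
  attr(out, "bin_deg") <- bin_deg
  out
}

#' Alignment-angle occurrence histogram and CDF
#'
#' Bins alignment angles over `[0, 90]` degrees into half-open bins of width
#' `bin_deg` (top edge assigned to the last bin), normalised to fractions
#' that sum to one, and appends the cumulative distribution.
#'
#' @param theta_deg Numeric vector of alignment angles in `[0, 90]`.
#' @param bin_deg Bin width in degrees (default 2, i.e. 45 bins).
#' @return A tibble of `bin_lo`, `bin_hi`, `fraction`, `cum_fraction` with
#'   attributes `n_samples` and `bin_deg`.
#' @export
alignment_histogram <- function(theta_deg, bin_deg = 2) {
  out <- .occurrence_bins(theta_deg, bin_deg, 90)
  out$cum_fraction <- cumsum(out$fraction)
  out
}
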