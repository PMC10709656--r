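# File exchange. All CSVs are comma-separated UTF-8 with "." decimal and a
# mandatory header; angles in degrees, positions in um, times in minutes.
# Trajectory schema: cell_id,t_min,x_um,y_um,condition,on_pattern.
# Outline schema:    cell_id,vertex_index,x_um,y_um  plus a per-cell flags
# file cell_id,condition,flag_mitosis,flag_spans_flat_and_pattern.

#' Write a trajectory table to CSV
#'
#' @param tracks Long trajectory tibble with columns `cell_id`, `t_min`,
#'   `x_um`, `y_um`, `condition`, `on_pattern`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(tracks, path) {
  need <- c("cell_id", "t_min", "x_um", "y_um", "condition", "on_pattern")
  stopifnot(all(need %in% names(tracks)))
  utils::write.csv(as.data.frame(tracks)[, need], path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory table from CSV
#'
#' Validates the header, rejects duplicated (cell, time) rows naming the
#' offending row, sorts each track by time and checks that every track sits
#' on a single regular sampling grid.
#'
#' @param path CSV file with columns `cell_id`, `t_min`, `x_um`, `y_um`,
#'   `condition`, `on_pattern`.
#' @return A long trajectory tibble sorted by cell and time.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "t_min", "x_um", "y_um", "condition", "on_pattern")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop(sprintf("trajectory file is missing columns: %s",
                 paste(miss, collapse = ", ")))
  }
  dup <- duplicated(d[, c("cell_id", "t_min")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicated (cell_id, t_min) row %d: %s at t = %g min",
                 i, d$cell_id[i], d$t_min[i]))
  }
  if (any(!is.finite(d$x_um)) || any(!is.finite(d$y_um))) {
    stop("positions must be finite")
  }
  d <- d[order(d$cell_id, d$t_min), ]
  for (part in split(d$t_min, d$cell_id)) {
    if (length(part) < 2) {
      stop("every track needs at least 2 samples")
    }
    steps <- diff(part)
    if (max(abs(steps - steps[1])) > 1e-6) {
      stop("track times are not on a regular sampling grid")
    }
  }
  d$on_pattern <- as.logical(d$on_pattern)
  tibble::as_tibble(d)
}

# TRUE when the closed polygon has no proper self-intersection between
# non-adjacent edges (vectorised orientation tests over all edge pairs).
.polygon_is_simple <- function(v) {
  n <- nrow(v)
  x1 <- v[, 1]; y1 <- v[, 2]
  nx <- c(x1[-1], x1[1]); ny <- c(y1[-1], y1[1])
  pairs <- which(outer(seq_len(n), seq_len(n),
                       function(i, j) j > i + 1 & !(i == 1 & j == n)),
                 arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  d3 <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  o1 <- d3(x1[i], y1[i], nx[i], ny[i], x1[j], y1[j])
  o2 <- d3(x1[i], y1[i], nx[i], ny[i], nx[j], ny[j])
  o3 <- d3(x1[j], y1[j], nx[j], ny[j], x1[i], y1[i])
  o4 <- d3(x1[j], y1[j], nx[j], ny[j], nx[i], ny[i])
  !any(o1 * o2 < 0 & o3 * o4 < 0)
}

#' Write an outline set to CSV
#'
#' @param outlines An `outline_set`.
#' @param vertices_path Output path of the vertex file.
#' @param flags_path Output path of the per-cell flags file.
#' @return `vertices_path`, invisibly.
#' @export
write_outlines <- function(outlines, vertices_path, flags_path) {
  stopifnot(inherits(outlines, "outline_set"))
  utils::write.csv(as.data.frame(outlines$vertices), vertices_path,
                   row.names = FALSE)
  flags <- as.data.frame(outlines$cells[, c("cell_id", "condition",
                                            "flag_mitosis",
                                            "flag_spans_flat_and_pattern")])
  utils::write.csv(flags, flags_path, row.names = FALSE)
  invisible(vertices_path)
}

#' Read cell outlines from CSV
#'
#' Reads an outline-vertex file and a per-cell flags file, joins them and
#' validates every polygon: at least 3 vertices, strictly positive area and
#' no self-intersection (a bow-tie polygon is rejected, naming the cell).
#' Every cell in the vertex file must have a flags row.
#'
#' @param vertices_path CSV with columns `cell_id`, `vertex_index`, `x_um`,
#'   `y_um`.
#' @param flags_path CSV with columns `cell_id`, `condition`,
#'   `flag_mitosis`, `flag_spans_flat_and_pattern`.
#' @return An `outline_set`.
#' @export
read_outlines <- function(vertices_path, flags_path) {
  for (p in c(vertices_path, flags_path)) {
    if (!file.exists(p)) stop(sprintf("no such file: '%s'", p))
  }
  verts <- utils::read.csv(vertices_path, stringsAsFactors = FALSE)
  need_v <- c("cell_id", "vertex_index", "x_um", "y_um")
  miss <- setdiff(need_v, names(verts))
  if (length(miss) > 0) {
    stop(sprintf("outline file is missing columns: %s",
                 paste(miss, collapse = ", ")))
  }
  flags <- utils::read.csv(flags_path, stringsAsFactors = FALSE)
  need_f <- c("cell_id", "condition", "flag_mitosis",
              "flag_spans_flat_and_pattern")
  miss <- setdiff(need_f, names(flags))
  if (length(miss) > 0) {
    stop(sprintf("flags file is missing columns: %s",
                 paste(miss, collapse = ", ")))
  }
  verts <- verts[order(verts$cell_id, verts$vertex_index), ]
  ids <- unique(verts$cell_id)
  no_flags <- setdiff(ids, flags$cell_id)
  if (length(no_flags) > 0) {
    stop(sprintf("missing flags rows for cells: %s",
                 paste(no_flags, collapse = ", ")))
  }
  for (id in ids) {
    v <- as.matrix(verts[verts$cell_id == id, c("x_um", "y_um")])
    if (nrow(v) < 3) stop(sprintf("outline '%s' has fewer than 3 vertices", id))
    m <- .polygon_moments(v)
    if (abs(m$area_signed) < 1e-9) {
      stop(sprintf("outline '%s' is degenerate (zero area)", id))
    }
    if (!.polygon_is_simple(v)) {
      stop(sprintf("outline '%s' is self-intersecting", id))
    }
  }
  flags <- flags[match(ids, flags$cell_id), ]
  flags$flag_mitosis <- as.logical(flags$flag_mitosis)
  flags$flag_spans_flat_and_pattern <- as.logical(flags$flag_spans_flat_and_pattern)
  structure(list(vertices = tibble::as_tibble(verts),
                 cells = tibble::as_tibble(flags)),
            class = "outline_set")
}
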