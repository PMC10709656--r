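# Substrate conditions: one topographic condition is a groove width (G_w, um),
# a ridge width (R_w, um) and a groove depth (G_D, nm). The groove long axis is
# the +y direction throughout the package; the flat control substrate is
# encoded with all three dimensions zero.

#' Construct a substrate condition
#'
#' A substrate condition describes one periodic line pattern by its groove
#' width, ridge width (both in micrometres) and groove depth (in nanometres).
#' The flat control substrate has all three dimensions equal to zero. The
#' groove long axis is the +y direction by package-wide convention.
#'
#' @param groove_width_um Groove width G_w in micrometres (0 for control).
#' @param ridge_width_um Ridge width R_w in micrometres (0 for control).
#' @param groove_depth_nm Groove depth G_D in nanometres (0 for control).
#' @param label Optional printed label; defaults to the canonical label from
#'   [format_condition_label()].
#' @return An object of class `substrate_condition`: a list with fields
#'   `label`, `groove_width_um`, `ridge_width_um`, `groove_depth_nm` and
#'   `groove_axis` (always the unit +y vector).
#' @seealso [parse_condition_label()], [build_condition_grid()]
#' @export
#' @examples
#' substrate_condition(2, 8, 330)
#' substrate_condition(0, 0, 0)  # flat control
substrate_condition <- function(groove_width_um, ridge_width_um,
                                groove_depth_nm, label = NULL) {
  stopifnot(is.numeric(groove_width_um), length(groove_width_um) == 1L,
            is.numeric(ridge_width_um), length(ridge_width_um) == 1L,
            is.numeric(groove_depth_nm), length(groove_depth_nm) == 1L)
  if (groove_width_um < 0 || ridge_width_um < 0 || groove_depth_nm < 0) {
    stop("substrate dimensions must be nonnegative")
  }
  cond <- structure(
    list(label = "",
         groove_width_um = as.numeric(groove_width_um),
         ridge_width_um = as.numeric(ridge_width_um),
         groove_depth_nm = as.numeric(groove_depth_nm),
         groove_axis = c(0, 1)),
    class = "substrate_condition")
  cond$label <- if (is.null(label)) format_condition_label(cond) else label
  cond
}

#' Test whether a condition is the flat control
#'
#' @param condition A `substrate_condition`.
#' @return `TRUE` when all three substrate dimensions are zero.
#' @export
is_control_condition <- function(condition) {
  stopifnot(inherits(condition, "substrate_condition"))
  condition$groove_width_um == 0 && condition$ridge_width_um == 0 &&
    condition$groove_depth_nm == 0
}

#' Canonical label of a substrate condition
#'
#' Patterned conditions print as `G<G_w>R<R_w>` with an optional `D<G_D>`
#' depth suffix (e.g. `"G2R8D330"`); the flat control prints as `"control"`.
#' Labels round-trip through [parse_condition_label()].
#'
#' @param condition A `substrate_condition`.
#' @return A single character label.
#' @export
format_condition_label <- function(condition) {
  stopifnot(inherits(condition, "substrate_condition"))
  if (is_control_condition(condition)) return("control")
  lbl <- sprintf("G%gR%g", condition$groove_width_um, condition$ridge_width_um)
  if (condition$groove_depth_nm > 0) {
    lbl <- sprintf("%sD%g", lbl, condition$groove_depth_nm)
  }
  lbl
}

#' Parse a substrate-condition label
#'
#' Understands the `G<int>R<int>` grammar used to name ridge/groove patterns
#' (groove width first, ridge width second, both in micrometres), an optional
#' `D<int>` groove-depth suffix in nanometres, and the literal `"control"`
#' for the flat substrate.
#'
#' @param label A single character label, e.g. `"G10R10"`, `"G2R8D330"` or
#'   `"control"`.
#' @return A `substrate_condition`.
#' @export
#' @examples
#' parse_condition_label("G10R10")
#' parse_condition_label("control")
parse_condition_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label)) {
    stop("label must be a single character string")
  }
  if (identical(label, "control")) {
    return(substrate_condition(0, 0, 0))
  }
  m <- regmatches(label,
                  regexec("^G([0-9]+)R([0-9]+)(?:D([0-9]+))?$", label))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("malformed condition label: '%s' (expected 'G<int>R<int>[D<int>]' or 'control')",
                 label))
  }
  depth <- if (m[4] == "") 0 else as.numeric(m[4])
  substrate_condition(as.numeric(m[2]), as.numeric(m[3]), depth, label = label)
}

#' @export
print.substrate_condition <- function(x, ...) {
  cat(sprintf("<substrate_condition> %s: G_w = %g um, R_w = %g um, G_D = %g nm\n",
              x$label, x$groove_width_um, x$ridge_width_um, x$groove_depth_nm))
  invisible(x)
}

# Lateral width series used on the multiplexed chips.
.series_widths <- list(
  G2RN = list(gw = 2,                     rw = c(2, 3, 4, 6, 8, 10)),
  GNR2 = list(gw = c(2, 3, 4, 6, 8),      rw = 2),
  GNRN = list(gw = c(2, 3, 4, 6, 8, 10),  rw = NA)  # rw = gw
)

#' Build the condition grid of a lateral-width series
#'
#' The three chip series fix one lateral dimension and sweep the other:
#' `G2RN` fixes G_w = 2 um and sweeps R_w over 2, 3, 4, 6, 8, 10 um;
#' `GNR2` fixes R_w = 2 um and sweeps G_w over 2, 3, 4, 6, 8 um;
#' `GNRN` sweeps G_w = R_w over 2, 3, 4, 6, 8, 10 um.
#' Every lateral combination is crossed with every requested groove depth.
#'
#' @param series One of `"G2RN"`, `"GNRN"`, `"GNR2"`.
#' @param depths_nm Numeric vector of groove depths in nanometres (the chips
#'   use 330, 725 and 1000 nm). An empty vector yields an empty list.
#' @return A list of `substrate_condition` objects.
#' @export
#' @examples
#' length(build_condition_grid("G2RN", 725))  # 6 conditions
build_condition_grid <- function(series = c("G2RN", "GNRN", "GNR2"),
                                 depths_nm = c(330, 725, 1000)) {
  series <- match.arg(series)
  stopifnot(is.numeric(depths_nm))
  if (length(depths_nm) == 0L) return(list())
  spec <- .series_widths[[series]]
  if (series == "GNRN") {
    lateral <- data.frame(gw = spec$gw, rw = spec$gw)
  } else {
    lateral <- expand.grid(gw = spec$gw, rw = spec$rw)
  }
  out <- vector("list", nrow(lateral) * length(depths_nm))
  k <- 1L
  for (d in depths_nm) {
    for (i in seq_len(nrow(lateral))) {
      out[[k]] <- substrate_condition(lateral$gw[i], lateral$rw[i], d)
      k <- k + 1L
    }
  }
  out
}

#' Tabulate a list of substrate conditions
#'
#' @param conditions A list of `substrate_condition` objects.
#' @return A tibble with one row per condition and columns `label`,
#'   `groove_width_um`, `ridge_width_um`, `groove_depth_nm`.
#' @export
condition_table <- function(conditions) {
  stopifnot(is.list(conditions))
  tibble::tibble(
    label = vapply(conditions, function(c) c$label, character(1)),
    groove_width_um = vapply(conditions, function(c) c$groove_width_um, numeric(1)),
    ridge_width_um = vapply(conditions, function(c) c$ridge_width_um, numeric(1)),
    groove_depth_nm = vapply(conditions, function(c) c$groove_depth_nm, numeric(1))
  )
}
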