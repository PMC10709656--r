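# Filopodia bending-angle model: a filopodium of length l_f anchored at a
# ridge edge and reaching the groove bottom a depth G_D below makes the
# angle theta_f = arcsin(G_D / l_f) with the groove bottom. Larger bending
# angles raise the normal traction component on the filopodial adhesion,
# which rationalises the suppression of lateral protrusions on deeper
# grooves.

#' Filopodia bending angle
#'
#' Computes `theta_f = arcsin(G_D / l_f)` in degrees, with the groove depth
#' in nanometres and the filopodium length in micrometres (units are
#' reconciled internally). The angle is monotone increasing in depth at
#' fixed length, 0 at zero depth and 90 degrees when the depth equals the
#' length; a depth exceeding the length leaves the angle undefined and is
#' an error.
#'
#' @param groove_depth_nm Groove depth G_D in nanometres (nonnegative).
#' @param filopodia_length_um Filopodium length l_f in micrometres
#'   (positive; typical lengths are 1-5 um).
#' @return Bending angle(s) in degrees, in `[0, 90]`. Vectorised with
#'   recycling.
#' @export
#' @examples
#' filopodia_bending_angle(1000, 2)  # 30
filopodia_bending_angle <- function(groove_depth_nm, filopodia_length_um) {
  stopifnot(is.numeric(groove_depth_nm), is.numeric(filopodia_length_um))
  if (any(filopodia_length_um <= 0)) {
    stop("filopodia_length_um must be positive")
  }
  if (any(groove_depth_nm < 0)) stop("groove_depth_nm must be nonnegative")
  ratio <- (groove_depth_nm / 1000) / filopodia_length_um
  bad <- ratio > 1
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "bending angle undefined: groove depth %g nm exceeds filopodium length %g um",
      rep_len(groove_depth_nm, length(ratio))[i],
      rep_len(filopodia_length_um, length(ratio))[i]))
  }
  asin(ratio) * 180 / pi
}

#' Bending-angle table over depth and length grids
#'
#' Tabulates the filopodia bending angle for every combination of groove
#' depth and filopodium length. Combinations with the depth exceeding the
#' length are flagged undefined (`theta_f_deg = NA`, `defined = FALSE`)
#' rather than raising an error.
#'
#' @param depths_nm Numeric vector of groove depths in nanometres.
#' @param lengths_um Numeric vector of filopodium lengths in micrometres.
#' @return A tibble of `groove_depth_nm`, `filopodia_length_um`,
#'   `theta_f_deg`, `defined`.
#' @export
bending_angle_table <- function(depths_nm = c(330, 725, 1000),
                                lengths_um = 1:5) {
  stopifnot(is.numeric(depths_nm), is.numeric(lengths_um))
  if (length(depths_nm) == 0 || length(lengths_um) == 0) {
    return(tibble::tibble(groove_depth_nm = numeric(),
                          filopodia_length_um = numeric(),
                          theta_f_deg = numeric(), defined = logical()))
  }
  grid <- expand.grid(groove_depth_nm = depths_nm,
                      filopodia_length_um = lengths_um,
                      KEEP.OUT.ATTRS = FALSE)
  ratio <- (grid$groove_depth_nm / 1000) / grid$filopodia_length_um
  defined <- ratio <= 1
  theta <- rep(NA_real_, nrow(grid))
  theta[defined] <- asin(ratio[defined]) * 180 / pi
  tibble::tibble(groove_depth_nm = grid$groove_depth_nm,
                 filopodia_length_um = grid$filopodia_length_um,
                 theta_f_deg = theta, defined = defined)
}
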