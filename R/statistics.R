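# Group statistics: Kruskal-Wallis (wrapping stats::kruskal.test), Dunn's
# post hoc with Sidak adjustment, box-plot summaries with the 1.5 IQR
# outlier rule, and multiple linear regression of population fractions on
# the topographic dimensions.

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least 2 groups")
  }
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop("every group must be nonempty")
  }
  groups <- lapply(groups, as.numeric)
  if (sum(lengths(groups)) < 3) stop("need at least 3 observations in total")
  groups
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based H statistic with tie correction and a chi-square tail p-value
#' with k - 1 degrees of freedom (via [stats::kruskal.test()]). When every
#' observation is identical across all groups the statistic is undefined
#' (0/0 tie correction); this case is reported as `H = 0`, `p = 1` with
#' `degenerate = TRUE`.
#'
#' @param groups A list of numeric vectors, one per group.
#' @return A list with `H`, `p_value`, `df`, `n` (group sizes) and
#'   `degenerate`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
kruskal_wallis <- function(groups) {
  groups <- .check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    return(list(H = 0, p_value = 1, df = length(groups) - 1L,
                n = lengths(groups), degenerate = TRUE))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), n = lengths(groups), degenerate = FALSE)
}

#' Dunn's post hoc test with Sidak adjustment
#'
#' Pairwise mean-rank comparisons on the pooled ranking, with the standard
#' tie correction in the variance, two-sided normal p-values and Sidak
#' family-wise adjustment `p_adj = 1 - (1 - p)^m` over the
#' `m = k(k-1)/2` comparisons. Degenerate pairs (zero rank variance, i.e.
#' all observations identical) are reported as `z = 0`, `p = 1`.
#'
#' @param groups A list of numeric vectors, one per group; names are used as
#'   group labels when present.
#' @return A tibble with columns `group_i`, `group_j`, `z`, `p_raw`,
#'   `p_adj`.
#' @export
dunn_sidak_posthoc <- function(groups) {
  groups <- .check_groups(groups)
  k <- length(groups)
  labels <- names(groups)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  values <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  r <- rank(values)
  N <- length(values)
  mean_ranks <- tapply(r, g, mean)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_corr
  m <- k * (k - 1) / 2
  out <- vector("list", m)
  idx <- 1L
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      se2 <- var_base * (1 / lengths(groups)[i] + 1 / lengths(groups)[j])
      if (se2 <= 0) {
        z <- 0; p <- 1
      } else {
        z <- (mean_ranks[i] - mean_ranks[j]) / sqrt(se2)
        p <- 2 * stats::pnorm(-abs(z))
      }
      out[[idx]] <- tibble::tibble(group_i = labels[i], group_j = labels[j],
                                   z = unname(z), p_raw = unname(p))
      idx <- idx + 1L
    }
  }
  tab <- do.call(rbind, out)
  tab$p_adj <- 1 - (1 - tab$p_raw)^m
  tab
}

#' Box-plot summary with the 1.5 IQR outlier rule
#'
#' Median, quartiles and whisker bounds, flagging as outliers every value
#' above `q3 + 1.5 (q3 - q1)` or below `q1 - 1.5 (q3 - q1)`. Whiskers
#' extend to the most extreme data points inside the fences. Quartiles use
#' midpoint linear interpolation of the empirical CDF (R quantile type 5,
#' the convention of the plotting tool the outlier rule comes from);
#' configurable via `type`.
#'
#' @param values Numeric vector, `n >= 1`.
#' @param type Quantile type passed to [stats::quantile()] (default 5).
#' @return A list with `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers` and `quantile_type`.
#' @export
box_summary <- function(values, type = 5) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- values[values >= lo & values <= hi]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(inside), whisker_hi = max(inside),
       outliers = sort(values[values < lo | values > hi]),
       quantile_type = type)
}

#' Regression of population fractions on topographic dimensions
#'
#' Ordinary least squares of a per-condition population fraction on the
#' groove depth, ridge width and groove width and their pairwise products,
#' with an intercept. Control rows carry all predictors equal to zero, so
#' the intercept estimates the control-substrate fraction. Two depth ranges
#' are supported: Case 1 restricts to groove depths of 0-725 nm (where the
#' response trend is monotone); Case 2 uses the full 0-1000 nm range.
#'
#' @param table A data frame with columns `groove_depth_nm`,
#'   `ridge_width_um`, `groove_width_um` and the response column.
#' @param response Name of the response column (default `"p_elongated"`).
#' @param case `"case1"` (depths 0-725 nm) or `"case2"` (0-1000 nm).
#' @param include_threeway Also include the three-way product (default
#'   `FALSE`).
#' @return A list of class `population_regression` with `coefficients`
#'   (tibble of `term`, `estimate`, `p_value`), `r_squared`, `case`,
#'   `n`, and the underlying `lm` fit.
#' @export
population_regression <- function(table, response = "p_elongated",
                                  case = c("case1", "case2"),
                                  include_threeway = FALSE) {
  case <- match.arg(case)
  need <- c("groove_depth_nm", "ridge_width_um", "groove_width_um", response)
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) {
    stop(sprintf("regression table is missing columns: %s",
                 paste(miss, collapse = ", ")))
  }
  max_depth <- if (case == "case1") 725 else 1000
  d <- table[table$groove_depth_nm <= max_depth, , drop = FALSE]
  dat <- data.frame(P = d[[response]],
                    G_D = d$groove_depth_nm,
                    R_w = d$ridge_width_um,
                    G_w = d$groove_width_um)
  form <- P ~ G_D + R_w + G_w + I(G_D * R_w) + I(G_D * G_w) + I(R_w * G_w)
  if (include_threeway) {
    form <- stats::update(form, . ~ . + I(G_D * R_w * G_w))
  }
  n_par <- length(attr(stats::terms(form), "term.labels")) + 1L
  if (nrow(dat) < n_par + 1L) {
    stop(sprintf("need at least %d rows for %d parameters", n_par + 1L, n_par))
  }
  fit <- stats::lm(form, data = dat)
  if (fit$rank < n_par) stop("rank-deficient design matrix")
  sm <- summary(fit)
  # a constant response has zero total variance; report R^2 = 0 rather than
  # the 0/0 (or roundoff-noise) ratio
  sst <- sum((dat$P - mean(dat$P))^2)
  r2 <- if (!is.finite(sm$r.squared) ||
              sst <= 1e-12 * max(1, mean(dat$P)^2) * nrow(dat)) {
    0
  } else {
    sm$r.squared
  }
  coefs <- stats::coef(sm)
  structure(list(
    coefficients = tibble::tibble(term = rownames(coefs),
                                  estimate = unname(coefs[, 1]),
                                  p_value = unname(coefs[, 4])),
    r_squared = r2,
    case = case,
    n = nrow(dat),
    fit = fit
  ), class = "population_regression")
}

#' @export
print.population_regression <- function(x, ...) {
  cat(sprintf("<population_regression> %s (n = %d), R^2 = %.3f\n",
              x$case, x$n, x$r_squared))
  cat("Note: unweighted OLS; main effects plus pairwise products.\n")
  print(x$coefficients)
  invisible(x)
}
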