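#' Local log sensitivity of output to copy number
#'
#' Approximates `d log(POI) / d log(CN)` on a unit-spaced integer
#' copy-number grid with second-order finite differences: a forward stencil
#' at the first point, `cn[1] * (-P3 + 4 P2 - 3 P1) / (2 P1)`; a centered
#' stencil at interior points, `cn_i * (P_{i+1} - P_{i-1}) / (2 P_i)`; and a
#' backward stencil at the last point,
#' `cn_n * (3 P_n - 4 P_{n-1} + P_{n-2}) / (2 P_n)`.
#'
#' @param curve An `eq_transfer_curve` from [dose_response()], or any data
#'   frame with strictly increasing integer `cn` (unit spacing) and strictly
#'   positive `poi`, at least 3 rows.
#' @return A data frame of class `eq_sensitivity` with columns `cn` and
#'   `log_sensitivity`.
#' @examples
#' curve <- data.frame(cn = 1:10, poi = 2 * (1:10))
#' log_sensitivity(curve)$log_sensitivity  # all exactly 1
#' @export
log_sensitivity <- function(curve) {
  if (!is.data.frame(curve) || !all(c("cn", "poi") %in% names(curve))) {
    stop("`curve` must be a data frame with columns `cn` and `poi`",
         call. = FALSE)
  }
  cn <- curve$cn
  poi <- curve$poi
  n <- length(cn)
  if (n < 3) stop("at least 3 grid points are required", call. = FALSE)
  if (!is_count_vector(cn)) {
    stop("`cn` must be integers >= 1", call. = FALSE)
  }
  if (any(diff(cn) != 1)) {
    stop(paste("the stencils require consecutive copy numbers (unit",
               "spacing); evaluate the dose response on a dense grid"),
         call. = FALSE)
  }
  if (any(poi <= 0)) stop("`poi` must be strictly positive", call. = FALSE)

  s <- numeric(n)
  s[1] <- cn[1] * (-poi[3] + 4 * poi[2] - 3 * poi[1]) / (2 * poi[1])
  if (n > 2) {
    i <- 2:(n - 1)
    s[i] <- cn[i] * (poi[i + 1] - poi[i - 1]) / (2 * poi[i])
  }
  s[n] <- cn[n] * (3 * poi[n] - 4 * poi[n - 1] + poi[n - 2]) / (2 * poi[n])

  out <- data.frame(cn = cn, log_sensitivity = s)
  class(out) <- c("eq_sensitivity", "data.frame")
  out
}

#' Dosage-compensation score
#'
#' The inverse magnitude of the local log sensitivity, `1 / |s|`, capped at
#' `cap_max` wherever `|s| < 1/cap_max` (a perfectly flat response has
#' infinite compensation; the cap preserves ranking without infinities).
#' A compensation score of 4 means a 100 % (2x) increase in gene dosage
#' produces only a ~25 % increase in expression; see
#' [implied_expression_change()].
#'
#' @param profile An `eq_sensitivity` data frame from [log_sensitivity()].
#' @param cap_max Upper cap for the score (default 1e3).
#' @return The input with a `compensation` column appended.
#' @export
compensation <- function(profile, cap_max = 1e3) {
  if (!is.data.frame(profile) || !("log_sensitivity" %in% names(profile))) {
    stop("`profile` must contain a `log_sensitivity` column", call. = FALSE)
  }
  s <- abs(profile$log_sensitivity)
  profile$compensation <- ifelse(s < 1 / cap_max, cap_max, 1 / s)
  profile
}

#' Expression change implied by a compensation score
#'
#' For a relative dosage change `dosage_change` (e.g. 1.0 for a 100 %
#' increase), a circuit with compensation score `score` shows an expression
#' change of approximately `dosage_change / score`.
#'
#' @param score Compensation score(s), > 0.
#' @param dosage_change Relative change in gene dosage (1 = +100 %).
#' @return Relative change in expression.
#' @examples
#' implied_expression_change(4, 1)  # 0.25: a 2x dosage rise gives +25 %
#' @export
implied_expression_change <- function(score, dosage_change) {
  if (any(score <= 0)) stop("`score` must be > 0", call. = FALSE)
  dosage_change / score
}

#' Compensation range
#'
#' The widest contiguous copy-number interval whose compensation score is at
#' least `threshold`.
#'
#' @param profile An `eq_sensitivity` data frame; a `compensation` column is
#'   added via [compensation()] if absent.
#' @param threshold Score threshold, >= 1.
#' @param cap_max Passed to [compensation()] when the column is missing.
#' @return A list with `cn_low`, `cn_high` (NA when no point qualifies) and
#'   `width_logs`, the width in log10 units (0 for an empty interval).
#' @export
compensation_range <- function(profile, threshold = 2, cap_max = 1e3) {
  if (!is.numeric(threshold) || threshold < 1) {
    stop("`threshold` must be >= 1", call. = FALSE)
  }
  if (!("compensation" %in% names(profile))) {
    profile <- compensation(profile, cap_max = cap_max)
  }
  ok <- profile$compensation >= threshold
  if (!any(ok)) {
    return(list(cn_low = NA_real_, cn_high = NA_real_, width_logs = 0))
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  # widest run measured in log10 copy-number span
  widths <- log10(profile$cn[ends[runs]] / profile$cn[starts[runs]])
  best <- runs[which.max(widths)]
  list(cn_low = profile$cn[starts[best]],
       cn_high = profile$cn[ends[best]],
       width_logs = max(widths))
}

#' Optimal inducer concentration
#'
#' Scans a doxycycline grid and returns the concentration minimising an
#' aggregate dosage-sensitivity objective over a copy-number grid. The
#' default objective is the mean absolute log sensitivity weighted by the
#' copy-number distribution mass (uniform weights when `dist` is `NULL`);
#' `objective = "population_cv"` instead minimises the simulated population
#' CV from [predict_population()]. Ties are broken toward lower dox.
#'
#' @param network An `eq_network`.
#' @param cn_grid Integer copy-number grid for the sensitivity objective.
#' @param dox_grid Non-empty numeric grid of doxycycline concentrations.
#' @param dist Optional [cn_distribution()] supplying weights (and, for the
#'   CV objective, the sampling distribution).
#' @param objective `"mean_abs_sens"` (default) or `"population_cv"`.
#' @param noise,n,seed Used only by the `"population_cv"` objective.
#' @return A list with `dox` (the optimum), `objective` values per grid
#'   point, and `dox_grid`.
#' @export
optimal_dox <- function(network, cn_grid, dox_grid, dist = NULL,
                        objective = c("mean_abs_sens", "population_cv"),
                        noise = noise_model(), n = 10000, seed = 1) {
  objective <- match.arg(objective)
  if (length(dox_grid) == 0) stop("`dox_grid` is empty", call. = FALSE)
  check_numeric_nonneg(dox_grid, "dox_grid")
  obj <- vapply(dox_grid, function(dox) {
    if (objective == "mean_abs_sens") {
      curve <- dose_response(network, cn_grid, dox)
      s <- abs(log_sensitivity(curve)$log_sensitivity)
      w <- if (is.null(dist)) {
        rep(1, length(s))
      } else {
        cn_pmf(dist, curve$cn)
      }
      sum(w * s) / sum(w)
    } else {
      d <- if (is.null(dist)) default_cn_distribution() else dist
      predict_population(network, d, dox, n = n, noise = noise,
                         seed = seed)$cv
    }
  }, numeric(1))
  ord <- order(obj, dox_grid)  # ties toward lower dox
  list(dox = dox_grid[ord[1]], objective = obj, dox_grid = dox_grid)
}
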