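#' Enumerative sample size for a target precision
#'
#' Iwao's fixed-precision sample-size formula built on the patchiness
#' regression parameters:
#' \deqn{q = \frac{t^2}{d^2}\left[\frac{\alpha + 1}{x} + (\beta - 1)\right]}
#' where x is the anticipated mean density per sampling unit, d the desired
#' precision (standard error of the mean as a proportion of the mean),
#' alpha and beta the patchiness-regression intercept and slope, and t the
#' normal/Student multiplier (1.96 for 5% accuracy). q is rounded to the
#' nearest integer (half up); ceiling rounding does not reproduce standard
#' published sample-number tables built from this formula. The minimum
#' returned size is 1.
#'
#' For beta >= 1 and alpha >= 0 the curve is non-increasing in x and in d,
#' with large-density plateau `t^2/d^2 * (beta - 1)`.
#'
#' @param mean_density anticipated mean density x per sampling unit (> 0);
#'   vectorized.
#' @param beta_slope patchiness-regression slope beta.
#' @param alpha_int patchiness-regression intercept alpha; default 0.
#' @param d desired precision in (0, 1); default 0.2.
#' @param t Student's t multiplier; default 1.96 (P = 0.05).
#' @return integer vector of required sampling-unit numbers.
#' @examples
#' sample_number(100, beta_slope = 1.41, d = 0.20)  # 40
#' sample_number(100, beta_slope = 1.98, d = 0.20)  # 95
#' @export
sample_number <- function(mean_density, beta_slope, alpha_int = 0,
                          d = 0.2, t = 1.96) {
  if (any(mean_density <= 0)) stop("mean_density must be > 0")
  if (d <= 0 || d >= 1) stop("precision d must be in (0, 1)")
  if (t <= 0) stop("t must be > 0")
  q <- (t^2 / d^2) * ((alpha_int + 1) / mean_density + (beta_slope - 1))
  out <- as.integer(floor(q + 0.5))
  if (any(out < 1L)) {
    warning("sample number below 1 for some densities; reporting 1")
    out[out < 1L] <- 1L
  }
  out
}

#' Sample-number curves over a density x precision grid
#'
#' Evaluates [sample_number()] over a grid of anticipated densities,
#' precisions and patchiness parameter sets, the layout used for published
#' sample-number tables (densities as rows; precision x parameter set as
#' columns).
#'
#' @param densities numeric vector of mean densities (> 0).
#' @param precisions numeric vector of precisions in (0, 1).
#' @param params data frame with columns `label`, `beta` and optionally
#'   `alpha` (default 0), one row per parameter set.
#' @param t Student's t multiplier; default 1.96.
#' @param long return long format (one row per cell)? Default `FALSE`
#'   (wide, densities as rows).
#' @return data frame; wide format has one column per precision x label.
#' @examples
#' params <- data.frame(label = c("urban", "rural"), beta = c(1.41, 1.98))
#' sample_number_curve(c(10, 100), 0.2, params)
#' @export
sample_number_curve <- function(densities, precisions, params, t = 1.96,
                                long = FALSE) {
  if (length(densities) == 0L || length(precisions) == 0L ||
      nrow(params) == 0L) stop("empty sample-number grid")
  if (!all(c("label", "beta") %in% names(params))) {
    stop("params needs columns 'label' and 'beta'")
  }
  if (is.null(params$alpha)) params$alpha <- 0
  cells <- expand.grid(density = densities, label = params$label,
                       precision = precisions, stringsAsFactors = FALSE)
  cells <- merge(cells, params, by = "label", sort = FALSE)
  cells$q <- NA_integer_
  for (i in seq_len(nrow(cells))) {
    cells$q[i] <- sample_number(cells$density[i], cells$beta[i],
                                cells$alpha[i], d = cells$precision[i],
                                t = t)
  }
  cells <- cells[order(cells$precision, match(cells$label, params$label),
                       cells$density), c("density", "precision", "label",
                                         "q")]
  rownames(cells) <- NULL
  if (long) return(cells)
  wide <- data.frame(density = sort(unique(densities)))
  for (p in sort(precisions)) {
    for (lab in params$label) {
      col <- cells$q[cells$precision == p & cells$label == lab]
      ord <- order(cells$density[cells$precision == p & cells$label == lab])
      wide[[sprintf("d%.2f_%s", p, lab)]] <- col[ord]
    }
  }
  wide
}

#' Labor cost of servicing traps
#'
#' @param minutes_per_trap minutes of labor per trap per visit (> 0).
#' @param wage_per_hour hourly wage (>= 0).
#' @param n_traps number of traps; default 1.
#' @return cost in currency units, rounded to cents.
#' @examples
#' labor_cost(10, 12.50)              # 2.08 per trap
#' labor_cost(10, 12.50, n_traps = 20)  # 41.67 per visit
#' @export
labor_cost <- function(minutes_per_trap, wage_per_hour, n_traps = 1L) {
  if (minutes_per_trap <= 0) stop("minutes_per_trap must be > 0")
  if (wage_per_hour < 0) stop("wage_per_hour must be >= 0")
  if (n_traps <= 0) stop("n_traps must be > 0")
  round(n_traps * minutes_per_trap / 60 * wage_per_hour, 2)
}
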