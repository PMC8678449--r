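#' Lloyd's mean crowding
#'
#' Mean crowding m* is the mean number of other individuals sharing a
#' sampling unit with a randomly chosen individual:
#' \deqn{m^* = \bar{x} + (s^2/\bar{x} - 1)}
#' with \eqn{\bar{x}} the sample mean density per unit and \eqn{s^2} the
#' sample variance (n-1 denominator). Under a Poisson (random) pattern
#' \eqn{s^2 = \bar{x}} in expectation, so m* equals the mean density; for a
#' negative binomial with size k, \eqn{m^* = m(1 + 1/k)}.
#'
#' @param counts numeric vector of at least two non-negative counts (or
#'   per-area densities) with positive mean.
#' @return mean crowding (scalar).
#' @examples
#' mean_crowding(c(0, 1, 2, 9))   # 7.5556
#' @export
mean_crowding <- function(counts) {
  counts <- check_counts(counts, min_n = 2L, allow_real = TRUE)
  xbar <- mean(counts)
  if (xbar <= 0) stop("mean crowding is undefined for all-zero counts")
  xbar + (stats::var(counts) / xbar - 1)
}

check_counts <- function(counts, min_n = 2L, allow_real = FALSE) {
  counts <- as.numeric(counts)
  if (anyNA(counts)) stop("counts contain NA")
  if (length(counts) < min_n) {
    stop("need at least ", min_n, " counts, got ", length(counts))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!allow_real && any(counts != floor(counts))) {
    stop("counts must be integers")
  }
  counts
}

#' Index-of-dispersion randomness test
#'
#' Computes the index of dispersion \eqn{I = s^2/\bar{x}} and the test
#' statistic \eqn{\chi^2 = I (n - 1)}, compared against the two-sided
#' chi-square limits with n-1 degrees of freedom: values below the
#' `alpha/2` quantile indicate a uniform pattern, above the `1 - alpha/2`
#' quantile an aggregated pattern, otherwise the sample is consistent with
#' a random (Poisson) pattern.
#'
#' @param counts numeric vector of >= 2 non-negative counts, mean > 0.
#' @param alpha two-sided significance level in (0, 1); default 0.05.
#' @return object of class `dispersion_summary`: a list with `n`,
#'   `mean_density`, `variance`, `mean_crowding`, `dispersion_index`,
#'   `chi_square`, `df`, `lower`/`upper` chi-square limits, and
#'   `classification` (`"uniform"`, `"random"` or `"aggregated"`).
#' @examples
#' dispersion_test(c(0, 0, 0, 12))$classification  # "aggregated"
#' @export
dispersion_test <- function(counts, alpha = 0.05) {
  counts <- check_counts(counts, min_n = 2L, allow_real = TRUE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  xbar <- mean(counts)
  if (xbar <= 0) stop("index of dispersion is undefined for mean 0")
  n <- length(counts)
  s2 <- stats::var(counts)
  I <- s2 / xbar
  chi2 <- I * (n - 1)
  lower <- stats::qchisq(alpha / 2, df = n - 1)
  upper <- stats::qchisq(1 - alpha / 2, df = n - 1)
  classification <- if (chi2 < lower) "uniform"
    else if (chi2 > upper) "aggregated" else "random"
  structure(list(
    n = n, mean_density = xbar, variance = s2,
    mean_crowding = xbar + (I - 1),
    dispersion_index = I, chi_square = chi2, df = n - 1L,
    lower = lower, upper = upper, alpha = alpha,
    classification = classification
  ), class = "dispersion_summary")
}

#' @export
print.dispersion_summary <- function(x, ...) {
  cat(sprintf(
    "dispersion: n=%d mean=%.3f var=%.3f m*=%.3f I=%.3f chi2=%.2f [%s]\n",
    x$n, x$mean_density, x$variance, x$mean_crowding, x$dispersion_index,
    x$chi_square, x$classification))
  invisible(x)
}

#' Sticky-band trap surface area
#'
#' Effective trapping area of a sticky band wrapped around a trunk: the
#' foam spacer that stands the film off the bark is added (once) to the
#' tree's diameter at breast height before computing the circumference,
#' which is then multiplied by the exposed band width:
#' \deqn{A = \pi (DBH + foam) \times band}
#'
#' @param dbh_cm diameter at breast height, cm (> 0).
#' @param foam_width_cm foam spacer width, cm (>= 0); default 0.
#' @param band_width_cm exposed sticky band width, cm (> 0).
#' @return trap area in cm^2; vectorized over all arguments.
#' @examples
#' trap_area_cm2(17.6, 2.0, 7.6)  # 467.97 cm^2
#' @export
trap_area_cm2 <- function(dbh_cm, foam_width_cm = 0, band_width_cm) {
  if (any(dbh_cm <= 0)) stop("dbh_cm must be > 0")
  if (any(foam_width_cm < 0)) stop("foam_width_cm must be >= 0")
  if (any(band_width_cm <= 0)) stop("band_width_cm must be > 0")
  pi * (dbh_cm + foam_width_cm) * band_width_cm
}

#' Counts per 1,000 cm^2 of trap area
#'
#' @param count nymph count (>= 0).
#' @param area_cm2 trap area in cm^2 (> 0).
#' @return density per 1,000 cm^2; vectorized.
#' @examples
#' normalize_per_1000cm2(50, 500)  # 100
#' @export
normalize_per_1000cm2 <- function(count, area_cm2) {
  if (any(area_cm2 <= 0)) stop("area_cm2 must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  count * 1000 / area_cm2
}

# Per-trap response on the requested sampling-unit scale.
unit_response <- function(ds, unit) {
  if (unit == "per_trap") return(as.numeric(ds$count))
  needed <- c("dbh_cm", "band_width_cm")
  if (!all(needed %in% names(ds))) {
    stop("per_1000cm2 unit requires columns dbh_cm and band_width_cm")
  }
  foam <- if ("foam_width_cm" %in% names(ds)) ds$foam_width_cm else 0
  foam[is.na(foam)] <- 0
  area <- trap_area_cm2(ds$dbh_cm, foam, ds$band_width_cm)
  normalize_per_1000cm2(ds$count, area)
}

#' Classify dispersion per group
#'
#' Applies [dispersion_test()] to every (site, date, instar) group of a
#' dataset (grouping keys configurable) and tallies how many groups fall in
#' each pattern class per instar. Groups with fewer than two traps are
#' skipped with a warning; groups with mean 0 are reported with
#' classification `"unclassifiable"` rather than dropped.
#'
#' @param ds [trap_data] object.
#' @param unit sampling-unit scale: `"per_trap"` (raw counts) or
#'   `"per_1000cm2"` (counts scaled by [trap_area_cm2()]).
#' @param alpha two-sided significance level; default 0.05.
#' @param group_by character vector of grouping columns; default
#'   `c("site", "date", "instar")`.
#' @return data frame with one row per group (grouping keys, `n`,
#'   `mean_density`, `variance`, `mean_crowding`, `dispersion_index`,
#'   `chi_square`, `classification`), with the per-instar tally of
#'   random/uniform/aggregated groups attached as attribute `"tally"`
#'   (also via [dispersion_tally()]).
#' @export
classify_groups <- function(ds, unit = c("per_trap", "per_1000cm2"),
                            alpha = 0.05,
                            group_by = c("site", "date", "instar")) {
  stopifnot(inherits(ds, "trap_data"))
  unit <- match.arg(unit)
  df <- as.data.frame(ds)
  df$.y <- unit_response(df, unit)
  keys <- interaction(df[group_by], drop = TRUE, lex.order = TRUE)
  pieces <- split(df, keys)
  skipped <- 0L
  rows <- lapply(pieces, function(g) {
    out <- g[1L, group_by, drop = FALSE]
    if (nrow(g) < 2L) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    if (mean(g$.y) <= 0) {
      out$n <- nrow(g); out$mean_density <- 0; out$variance <- 0
      out$mean_crowding <- NA_real_; out$dispersion_index <- NA_real_
      out$chi_square <- NA_real_; out$classification <- "unclassifiable"
      return(out)
    }
    dt <- dispersion_test(g$.y, alpha = alpha)
    out$n <- dt$n; out$mean_density <- dt$mean_density
    out$variance <- dt$variance; out$mean_crowding <- dt$mean_crowding
    out$dispersion_index <- dt$dispersion_index
    out$chi_square <- dt$chi_square
    out$classification <- dt$classification
    out
  })
  if (skipped > 0L) {
    warning(skipped, " group(s) with < 2 sampling units skipped")
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no group with >= 2 sampling units")
  rownames(res) <- NULL
  attr(res, "tally") <- dispersion_tally(res)
  attr(res, "unit") <- unit
  res
}

#' Tally dispersion classifications per instar
#'
#' Marginal counts of groups classified random / uniform / aggregated per
#' instar, the summary layout used for reporting dispersion-test results
#' across many site x date observations.
#'
#' @param summaries data frame from [classify_groups()].
#' @return data frame with columns `instar`, `random`, `uniform`,
#'   `aggregated` (and `unclassifiable` when present).
#' @export
dispersion_tally <- function(summaries) {
  if (!"instar" %in% names(summaries)) summaries$instar <- "combined"
  lv <- c("random", "uniform", "aggregated", "unclassifiable")
  tab <- table(factor(summaries$instar,
                      levels = unique(summaries$instar)),
               factor(summaries$classification, levels = lv))
  out <- as.data.frame.matrix(tab)
  if (all(out$unclassifiable == 0)) out$unclassifiable <- NULL
  cbind(instar = rownames(out), out, row.names = NULL)
}
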