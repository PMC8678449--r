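#' Spearman rank-correlation series of trap catch over time
#'
#' Tracks how stable the ranking of traps by catch is across observation
#' dates: either each date against the first (baseline) date, or each date
#' against the immediately preceding date. Traps are matched by
#' (site, plot, trap_id); traps absent on either date of a pair are
#' dropped pairwise. Ties receive average ranks (the [stats::cor]
#' Spearman convention). Dates sharing fewer than three traps with their
#' reference are reported with `rho = NA`.
#'
#' @param ds [trap_data] object (filter to the records of interest — e.g.
#'   untreated controls and one instar — before calling).
#' @param reference `"baseline"` (default) or `"previous"`.
#' @param instar instar to track; default `"combined"` (derived via
#'   [with_combined_instar()] when not stored).
#' @return data frame of class `correlation_series`: `date`, `rho`,
#'   `n_traps`, `reference`; one row per non-reference date.
#' @export
spearman_series <- function(ds, reference = c("baseline", "previous"),
                            instar = "combined") {
  stopifnot(inherits(ds, "trap_data"))
  reference <- match.arg(reference)
  if (instar == "combined" && !"combined" %in% ds$instar) {
    ds <- with_combined_instar(ds)
  }
  df <- as.data.frame(ds[ds$instar == instar, , drop = FALSE])
  if (nrow(df) == 0L) stop("no records for instar '", instar, "'")
  dates <- sort(unique(df$date))
  if (length(dates) < 2L) stop("need at least 2 observation dates")
  df$.trap <- paste(df$site, df$plot, df$trap_id, sep = "\r")
  by_date <- split(df, df$date)
  rows <- lapply(seq_along(dates)[-1L], function(i) {
    ref_date <- if (reference == "baseline") dates[1L] else dates[i - 1L]
    a <- by_date[[as.character(ref_date)]]
    b <- by_date[[as.character(dates[i])]]
    common <- intersect(a$.trap, b$.trap)
    if (length(common) < 3L) {
      return(data.frame(date = dates[i], rho = NA_real_,
                        n_traps = length(common), reference = reference))
    }
    rho <- stats::cor(a$count[match(common, a$.trap)],
                      b$count[match(common, b$.trap)],
                      method = "spearman")
    data.frame(date = dates[i], rho = rho, n_traps = length(common),
               reference = reference)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("correlation_series", class(res))
  res
}

#' Seasonal decline in mean catch
#'
#' Negative binomial regression of per-plot total catch on observation
#' date as a factor, reporting the fitted marginal mean per date with a
#' Wald 95% confidence interval on the response scale. Because date is the
#' only term, the fitted means equal the per-date sample means of the
#' plot totals; the NB model supplies the interval width. When the counts
#' show no overdispersion the NB fit is replaced by a Poisson fit with a
#' warning.
#'
#' @param ds [trap_data] object (filter to untreated controls before
#'   calling, if applicable).
#' @param instar instar to summarize; default `"combined"`.
#' @param level confidence level; default 0.95.
#' @return data frame: `date`, `n_plots`, `mean` (fitted marginal mean),
#'   `lwr`, `upr`. Dates with a single plot are dropped with a warning.
#' @export
seasonal_decline <- function(ds, instar = "combined", level = 0.95) {
  stopifnot(inherits(ds, "trap_data"))
  if (instar == "combined" && !"combined" %in% ds$instar) {
    ds <- with_combined_instar(ds)
  }
  df <- as.data.frame(ds[ds$instar == instar, , drop = FALSE])
  if (nrow(df) == 0L) stop("no records for instar '", instar, "'")
  totals <- stats::aggregate(count ~ site + plot + date, data = df,
                             FUN = sum)
  nplot <- table(totals$date)
  single <- names(nplot)[nplot < 2L]
  if (length(single) > 0L) {
    warning("dropping date(s) with a single plot: ",
            paste(single, collapse = ", "))
    totals <- totals[!as.character(totals$date) %in% single, , drop = FALSE]
  }
  if (nrow(totals) == 0L) stop("no date with >= 2 plots")
  totals$fdate <- factor(totals$date)
  overdisp <- stats::var(totals$count) > mean(totals$count)
  fit <- if (overdisp) {
    try(suppressWarnings(MASS::glm.nb(count ~ fdate, data = totals)),
        silent = TRUE)
  } else "skip"
  if (!inherits(fit, "negbin")) {
    if (!identical(fit, "skip")) {
      warning("negative binomial fit failed; falling back to Poisson")
    } else {
      warning("no overdispersion in plot totals; using a Poisson fit")
    }
    fit <- stats::glm(count ~ fdate, data = totals,
                      family = stats::poisson())
  }
  nd <- data.frame(fdate = levels(totals$fdate))
  pr <- stats::predict(fit, newdata = nd, type = "link", se.fit = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  res <- data.frame(
    date = as.Date(nd$fdate),
    n_plots = as.integer(table(totals$fdate)),
    mean = exp(pr$fit),
    lwr = exp(pr$fit - z * pr$se.fit),
    upr = exp(pr$fit + z * pr$se.fit))
  rownames(res) <- NULL
  res
}
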