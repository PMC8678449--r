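#' Iwao patchiness regression
#'
#' Ordinary least-squares regression of mean crowding m* on mean density m
#' across samples (site x date groups). The slope measures aggregation: a
#' slope of 1 is the Poisson (random) benchmark, significantly above 1
#' indicates aggregation, below 1 a uniform pattern. The through-origin
#' variant uses the no-intercept estimator (slope = sum(xy)/sum(x^2)); its
#' R-squared is computed against the uncentered total sum of squares, the
#' standard convention for no-intercept fits (which is why forced fits can
#' report slightly higher R-squared than the corresponding free fits).
#'
#' @param mean_density numeric vector of group mean densities (x), or a
#'   two-column data frame/matrix of (mean_density, mean_crowding).
#' @param mean_crowding numeric vector of group mean crowding values (y);
#'   omit when `mean_density` holds both columns.
#' @param through_origin force the line through (0, 0)? Default `FALSE`.
#' @return object of class `iwao_fit`: list with `slope`, `slope_se`,
#'   `intercept`, `intercept_se` (`NA` when through origin), `r_squared`,
#'   `f_value`, `p_value`, `df` (residual), `n_points`, `through_origin`.
#' @examples
#' iwao_fit(c(1, 2, 3), c(2.1, 3.9, 6.0))$slope       # 1.95
#' iwao_fit(c(1, 2, 3), c(2, 4, 6), through_origin = TRUE)$slope  # 2
#' @export
iwao_fit <- function(mean_density, mean_crowding = NULL,
                     through_origin = FALSE) {
  if (is.null(mean_crowding)) {
    stopifnot(ncol(mean_density) >= 2L)
    mean_crowding <- as.numeric(mean_density[[2L]])
    mean_density <- as.numeric(mean_density[[1L]])
  }
  x <- as.numeric(mean_density)
  y <- as.numeric(mean_crowding)
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  min_n <- if (through_origin) 2L else 3L
  if (n < min_n) {
    stop("need at least ", min_n, " points, got ", n)
  }
  if (!through_origin && length(unique(x)) < 2L) {
    stop("singular fit: all mean densities identical")
  }
  fit <- if (through_origin) stats::lm(y ~ x + 0) else stats::lm(y ~ x)
  sm <- summary(fit)
  ct <- sm$coefficients
  fstat <- sm$fstatistic
  structure(list(
    slope = unname(ct["x", "Estimate"]),
    slope_se = unname(ct["x", "Std. Error"]),
    intercept = if (through_origin) 0 else unname(ct["(Intercept)", "Estimate"]),
    intercept_se = if (through_origin) NA_real_
      else unname(ct["(Intercept)", "Std. Error"]),
    r_squared = sm$r.squared,
    f_value = if (is.null(fstat)) NA_real_ else unname(fstat[1L]),
    p_value = if (is.null(fstat)) NA_real_ else
      unname(stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)),
    df = unname(fit$df.residual),
    n_points = n,
    through_origin = through_origin
  ), class = "iwao_fit")
}

#' @export
print.iwao_fit <- function(x, ...) {
  cat(sprintf(
    "Iwao patchiness regression (%s): slope %.3f +/- %.3f, intercept %s, R2 %.3f, F %.1f (df %d), p %.3g, n %d\n",
    if (x$through_origin) "through origin" else "with intercept",
    x$slope, x$slope_se,
    if (x$through_origin) "0 (forced)" else sprintf("%.3f +/- %.3f",
                                                    x$intercept,
                                                    x$intercept_se),
    x$r_squared, x$f_value, x$df, x$p_value, x$n_points))
  invisible(x)
}

#' Aggregation inference from a patchiness slope
#'
#' Two-sided t-test of H0: slope = 1 against the patchiness-regression
#' benchmark. A slope significantly above 1 classifies the population as
#' aggregated, significantly below 1 as uniform, otherwise random.
#'
#' @param fit [iwao_fit] object (or any list with `slope`, `slope_se`,
#'   `df`).
#' @param alpha significance level; default 0.05.
#' @return list with `classification` (`"aggregated"`, `"random"`,
#'   `"uniform"`), `t_value`, `p_value`, `df`.
#' @examples
#' f <- list(slope = 1.41, slope_se = 0.03, df = 25)
#' aggregation_inference(f)$classification  # "aggregated"
#' @export
aggregation_inference <- function(fit, alpha = 0.05) {
  if (!is.finite(fit$slope_se) || fit$slope_se <= 0) {
    stop("degenerate fit: slope SE must be positive")
  }
  tval <- (fit$slope - 1) / fit$slope_se
  pval <- 2 * stats::pt(abs(tval), df = fit$df, lower.tail = FALSE)
  classification <- if (pval < alpha && tval > 0) "aggregated"
    else if (pval < alpha && tval < 0) "uniform" else "random"
  list(classification = classification, t_value = tval, p_value = pval,
       df = fit$df, alpha = alpha)
}

#' Mean density / mean crowding points per group
#'
#' Forms the regression points for [iwao_fit()]: one
#' (mean density, mean crowding) pair per group of traps.
#'
#' @inheritParams classify_groups
#' @return data frame with the grouping keys plus `n`, `mean_density`,
#'   `mean_crowding`. Groups with < 2 traps or mean 0 are dropped.
#' @export
iwao_points <- function(ds, unit = c("per_trap", "per_1000cm2"),
                        group_by = c("site", "date", "instar")) {
  stopifnot(inherits(ds, "trap_data"))
  unit <- match.arg(unit)
  df <- as.data.frame(ds)
  df$.y <- unit_response(df, unit)
  keys <- interaction(df[group_by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(df, keys), function(g) {
    if (nrow(g) < 2L || mean(g$.y) <= 0) return(NULL)
    out <- g[1L, group_by, drop = FALSE]
    out$n <- nrow(g)
    out$mean_density <- mean(g$.y)
    out$mean_crowding <- mean_crowding(g$.y)
    out
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no usable group for patchiness points")
  rownames(res) <- NULL
  res
}

#' Patchiness regressions over named dataset subsets
#'
#' Fits one patchiness regression per named subset of the records — e.g.
#' pretreatment dates only, pretreatment plus untreated controls, or the
#' whole study — to compare aggregation before and after interventions.
#'
#' @param ds [trap_data] object.
#' @param subsets named list; each element is either a logical vector of
#'   `nrow(ds)` or a function taking the data frame and returning one.
#' @param unit sampling-unit scale, as in [classify_groups()].
#' @param through_origin force fits through the origin? Default `FALSE`.
#' @param group_by grouping columns defining one regression point.
#' @return data frame with one row per subset: `subset`, `n_points`,
#'   `slope`, `slope_se`, `intercept`, `intercept_se`, `r_squared`,
#'   `f_value`, `p_value`, `df`; fits attached as attribute `"fits"`.
#' @export
fit_by_subset <- function(ds, subsets, unit = c("per_trap", "per_1000cm2"),
                          through_origin = FALSE,
                          group_by = c("site", "date", "instar")) {
  stopifnot(inherits(ds, "trap_data"), length(subsets) > 0L,
            !is.null(names(subsets)))
  unit <- match.arg(unit)
  df <- as.data.frame(ds)
  fits <- lapply(names(subsets), function(nm) {
    sel <- subsets[[nm]]
    if (is.function(sel)) sel <- sel(df)
    if (!is.logical(sel) || length(sel) != nrow(df)) {
      stop("subset '", nm, "' must select rows of the dataset")
    }
    if (!any(sel)) stop("subset '", nm, "' selects no records")
    sub <- trap_data(df[sel, , drop = FALSE])
    pts <- iwao_points(sub, unit = unit, group_by = group_by)
    min_n <- if (through_origin) 2L else 3L
    if (nrow(pts) < min_n) {
      stop("subset '", nm, "' yields only ", nrow(pts),
           " regression point(s); need ", min_n)
    }
    iwao_fit(pts$mean_density, pts$mean_crowding,
             through_origin = through_origin)
  })
  names(fits) <- names(subsets)
  res <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(subset = nm, n_points = f$n_points, slope = f$slope,
               slope_se = f$slope_se, intercept = f$intercept,
               intercept_se = f$intercept_se, r_squared = f$r_squared,
               f_value = f$f_value, p_value = f$p_value, df = f$df,
               stringsAsFactors = FALSE)
  }))
  attr(res, "fits") <- fits
  res
}
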