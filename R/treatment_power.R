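#' Log-scale shift for a proportional reduction
#'
#' A treatment that reduces mean counts by a proportion r shifts the mean
#' of log counts by \deqn{j = \log(1 - r) \le 0.} This is the effect used
#' when sizing experiments on the log scale.
#'
#' @param reduction_r proportional decrease in mean count, in \[0, 1).
#' @return log-scale shift j (<= 0); vectorized.
#' @examples
#' log_effect_shift(0.5)  # -0.693
#' @export
log_effect_shift <- function(reduction_r) {
  if (any(reduction_r < 0 | reduction_r >= 1)) {
    stop("reduction_r must be in [0, 1)")
  }
  log(1 - reduction_r)
}

#' Standard deviation of log(count + 1)
#'
#' Between-plot SD of log-transformed counts, with 1 added to every count
#' so that empty sampling units remain defined. This is the noise scale
#' entering [replicates_required()].
#'
#' @param counts numeric vector of >= 2 non-negative counts.
#' @return sample SD (n-1 denominator) of `log(counts + 1)`.
#' @examples
#' log_scale_sd(c(1, 3, 7))  # 0.693 (log 2)
#' @export
log_scale_sd <- function(counts) {
  counts <- check_counts(counts, min_n = 2L, allow_real = TRUE)
  stats::sd(log(counts + 1))
}

#' Replicates required to detect a proportional reduction
#'
#' Smallest per-group sample size n such that a two-sample pooled-variance
#' t-test (equal group sizes, one-sided, treated mean lower) detects a
#' log-scale shift of `log(1 - reduction_r)` against noise `sigma_log` with
#' the requested power. Solved through the noncentral-t power function
#' ([stats::power.t.test]) and rounded up, so the returned n meets or
#' exceeds the target power.
#'
#' @param reduction_r proportional decrease in mean count, in (0, 1).
#' @param sigma_log SD of log(count + 1) across plots (> 0).
#' @param alpha one-sided significance level; default 0.05.
#' @param power target power; default 0.80.
#' @return integer replicates per group (>= 2).
#' @examples
#' # standardized effect 0.5 at 80% power, one-sided 5%:
#' replicates_required(1 - exp(-0.5), sigma_log = 1)  # 51
#' @export
replicates_required <- function(reduction_r, sigma_log, alpha = 0.05,
                                power = 0.80) {
  if (length(reduction_r) != 1L || reduction_r <= 0 || reduction_r >= 1) {
    stop("reduction_r must be a single value in (0, 1); r = 0 implies infinite n")
  }
  if (sigma_log <= 0) stop("sigma_log must be > 0")
  delta <- abs(log_effect_shift(reduction_r))
  sol <- stats::power.t.test(delta = delta, sd = sigma_log,
                             sig.level = alpha, power = power,
                             type = "two.sample",
                             alternative = "one.sided")
  max(2L, as.integer(ceiling(sol$n - 1e-9)))
}

#' Replication-requirement table per date
#'
#' For each observation date, estimates the log-scale SD from the untreated
#' control counts and computes the replicates required to detect each
#' candidate proportional reduction, reporting alongside the date's
#' raw-scale mean and SD and a normal quantile-quantile correlation of the
#' log counts (a numerical stand-in for the usual visual normality check:
#' values near 1 support the log-normal working assumption).
#'
#' @param control_counts data frame with columns `date` and `count`
#'   (control plots only), or a [trap_data] object (filtered by the caller
#'   to control records).
#' @param reductions numeric vector of proportional reductions in (0, 1).
#' @param alpha one-sided significance level; default 0.05.
#' @param power target power; default 0.80.
#' @return data frame with one row per date: `date`, `n_plots`,
#'   `mean_count`, `sd_count`, `sigma_log`, `qq_cor`, then one `r_XX`
#'   column per reduction giving replicates per group (`NA` with a warning
#'   where the date's counts have zero log-scale spread).
#' @export
power_table <- function(control_counts, reductions,
                        alpha = 0.05, power = 0.80) {
  df <- as.data.frame(control_counts)
  if (!all(c("date", "count") %in% names(df))) {
    stop("control_counts needs columns 'date' and 'count'")
  }
  if (any(reductions <= 0 | reductions >= 1)) {
    stop("reductions must be in (0, 1)")
  }
  pieces <- split(df, df$date)
  rows <- lapply(pieces, function(g) {
    if (nrow(g) < 2L) {
      warning("date ", g$date[1L], " has < 2 control plots; skipped")
      return(NULL)
    }
    lg <- sort(log(g$count + 1))
    out <- data.frame(date = g$date[1L], n_plots = nrow(g),
                      mean_count = mean(g$count),
                      sd_count = stats::sd(g$count),
                      sigma_log = log_scale_sd(g$count),
                      qq_cor = if (stats::sd(lg) > 0)
                        stats::cor(lg, stats::qnorm(stats::ppoints(length(lg))))
                      else NA_real_)
    for (r in reductions) {
      col <- sprintf("r_%02d", round(100 * r))
      out[[col]] <- if (out$sigma_log > 0) {
        replicates_required(r, out$sigma_log, alpha = alpha, power = power)
      } else NA_integer_
    }
    if (out$sigma_log <= 0) {
      warning("date ", g$date[1L],
              " has zero log-scale spread; replicates undefined (NA)")
    }
    out
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no date with >= 2 control plots")
  rownames(res) <- NULL
  res[order(res$date), , drop = FALSE]
}
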