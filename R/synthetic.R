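#' Synthetic trap-count configuration
#'
#' Parameters of the seeded generator that emulates the statistical
#' structure of nymph trap-count surveys: negative binomial aggregation
#' across traps, an exponential seasonal decline in mean catch, latent
#' per-trap multipliers with AR(1) persistence across dates (the source of
#' between-date rank correlation), a static instar mixture, and an
#' optional multiplicative treatment effect.
#'
#' With `trap_sd = 0` the latent multipliers are identically 1 and counts
#' at each date are exactly negative binomial with size `nb_size_k`, so
#' closed-form identities hold (mean crowding `m(1 + 1/k)`, patchiness
#' slope `1 + 1/k`). With `trap_sd > 0` counts gain persistent trap-level
#' heterogeneity: rank correlations between dates decay with lag at rate
#' `trap_autocorr` per step, mimicking field behaviour.
#'
#' @param n_sites number of sites; default 6.
#' @param traps_per_site traps per site; default 15.
#' @param dates ordered `Date` vector; default 14 dates, 3 days apart,
#'   starting 2020-06-11 (a typical nymph-season sampling calendar).
#' @param baseline_mean expected count per trap at the first date (> 0);
#'   default 100.
#' @param nb_size_k NB size (quadratic parameterization, var =
#'   mu(1 + mu/k)); smaller is more aggregated; default 2 (patchiness
#'   slope 1.5).
#' @param decline_rate per-day exponential decay of the mean (>= 0);
#'   default 0.06 (about a 20-fold decline over a 50-day season).
#' @param trap_autocorr AR(1) coefficient of the latent log multiplier
#'   across consecutive dates, in \[0, 1); default 0.8.
#' @param trap_sd marginal SD of the latent log multiplier (>= 0);
#'   default 0.5.
#' @param treatment_effect_r proportional reduction applied to treated
#'   traps, in \[0, 1); default 0.
#' @param treated_fraction fraction of plots treated, in \[0, 1\];
#'   default 0.
#' @param instar_mixture four proportions (instars 1-4) summing to 1;
#'   default `c(0.4, 0.3, 0.2, 0.1)` (an early-season stage mix).
#' @param dbh_mean,dbh_sd tree DBH distribution (cm); defaults 17.6 and
#'   4.7.
#' @param band_width_cm,foam_width_cm trap geometry (cm); defaults 7.6
#'   and 2.
#' @param seed integer seed; default 1.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 6L, traps_per_site = 15L,
                             dates = as.Date("2020-06-11") + 3 * (0:13),
                             baseline_mean = 100, nb_size_k = 2,
                             decline_rate = 0.06, trap_autocorr = 0.8,
                             trap_sd = 0.5, treatment_effect_r = 0,
                             treated_fraction = 0,
                             instar_mixture = c(0.4, 0.3, 0.2, 0.1),
                             dbh_mean = 17.6, dbh_sd = 4.7,
                             band_width_cm = 7.6, foam_width_cm = 2,
                             seed = 1L) {
  stopifnot(n_sites >= 1, traps_per_site >= 1, length(dates) >= 1,
            !is.unsorted(dates), baseline_mean > 0, nb_size_k > 0,
            decline_rate >= 0, trap_autocorr >= 0, trap_autocorr < 1,
            trap_sd >= 0, treatment_effect_r >= 0, treatment_effect_r < 1,
            treated_fraction >= 0, treated_fraction <= 1)
  if (length(instar_mixture) != 4L ||
      abs(sum(instar_mixture) - 1) > 1e-9 || any(instar_mixture < 0)) {
    stop("instar_mixture must be 4 non-negative proportions summing to 1")
  }
  structure(list(
    n_sites = as.integer(n_sites),
    traps_per_site = as.integer(traps_per_site),
    dates = as.Date(dates), baseline_mean = baseline_mean,
    nb_size_k = nb_size_k, decline_rate = decline_rate,
    trap_autocorr = trap_autocorr, trap_sd = trap_sd,
    treatment_effect_r = treatment_effect_r,
    treated_fraction = treated_fraction,
    instar_mixture = instar_mixture,
    dbh_mean = dbh_mean, dbh_sd = dbh_sd,
    band_width_cm = band_width_cm, foam_width_cm = foam_width_cm,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic trap-count dataset
#'
#' Draws a full survey dataset from a [synthetic_config()]. For trap i at
#' date t the expected count is
#' `baseline_mean * exp(-decline_rate * days_since_first) * u[i, t]`
#' (times `1 - treatment_effect_r` on treated plots), where `log u[i, .]`
#' is a stationary AR(1) process with coefficient `trap_autocorr` and
#' marginal SD `trap_sd`, mean-corrected so `E[u] = 1`. Counts are NB
#' draws with size `nb_size_k`, split multinomially into the four instars.
#' Each trap is its own plot (one trap per plot). Fully reproducible from
#' `config$seed`.
#'
#' @param config [synthetic_config()] object.
#' @return [trap_data] object with per-instar rows (derive totals with
#'   [with_combined_instar()]).
#' @examples
#' ds <- generate_trap_data(synthetic_config(n_sites = 2,
#'                                           traps_per_site = 4,
#'                                           dates = as.Date("2020-06-11")
#'                                                   + c(0, 3)))
#' head(ds)
#' @export
generate_trap_data <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_traps <- config$n_sites * config$traps_per_site
  site <- rep(sprintf("S%02d", seq_len(config$n_sites)),
              each = config$traps_per_site)
  trap <- sprintf("T%03d", seq_len(n_traps))
  dbh <- pmax(5, stats::rnorm(n_traps, config$dbh_mean, config$dbh_sd))
  treated <- stats::runif(n_traps) < config$treated_fraction
  days <- as.numeric(config$dates - config$dates[1L])
  n_dates <- length(days)
  # stationary AR(1) latent log multiplier, E[multiplier] = 1
  s <- config$trap_sd
  a <- config$trap_autocorr
  logu <- matrix(0, nrow = n_traps, ncol = n_dates)
  if (s > 0) {
    logu[, 1L] <- stats::rnorm(n_traps, 0, s)
    if (n_dates > 1L) {
      innov_sd <- s * sqrt(1 - a^2)
      for (t in 2:n_dates) {
        logu[, t] <- a * logu[, t - 1L] +
          stats::rnorm(n_traps, 0, innov_sd)
      }
    }
  }
  u <- exp(logu - s^2 / 2)
  rows <- vector("list", n_dates)
  for (t in seq_len(n_dates)) {
    mu <- config$baseline_mean * exp(-config$decline_rate * days[t]) *
      u[, t]
    mu[treated] <- mu[treated] * (1 - config$treatment_effect_r)
    total <- stats::rnbinom(n_traps, size = config$nb_size_k, mu = mu)
    split_counts <- vapply(total, function(x) {
      if (x == 0L) return(c(0L, 0L, 0L, 0L))
      as.integer(stats::rmultinom(1L, x, config$instar_mixture))
    }, integer(4L))
    rows[[t]] <- data.frame(
      site = rep(site, each = 4L),
      plot = rep(trap, each = 4L),
      trap_id = rep(trap, each = 4L),
      date = config$dates[t],
      instar = rep(c("1", "2", "3", "4"), times = n_traps),
      count = as.integer(split_counts),
      dbh_cm = rep(dbh, each = 4L),
      band_width_cm = config$band_width_cm,
      foam_width_cm = config$foam_width_cm,
      treatment = rep(ifelse(treated, "treated", "control"), each = 4L),
      stringsAsFactors = FALSE)
  }
  trap_data(do.call(rbind, rows),
            metadata = list(generator = "trapdisp synthetic",
                            seed = config$seed))
}

#' Correlated pretreatment / posttreatment plot counts
#'
#' Fixture generator matching the design-simulator projection model:
#' pretreatment counts are NB draws, and each posttreatment (null,
#' untreated) count is an NB draw with mean `projection_slope * pre` and
#' quadratic dispersion `projection_k`. As `projection_k` grows the
#' posttreatment count concentrates on `projection_slope * pre`.
#'
#' @param n_plots number of plots (even for downstream design
#'   assignment).
#' @param init_mean,init_dispersion pretreatment NB1 mean and dispersion
#'   (var = mu(1 + phi)); defaults 50 and 49 (coefficient of variation 1).
#' @param projection_slope slope beta; default 0.8.
#' @param projection_k quadratic projection dispersion; default 3.
#' @param seed integer seed; default 1.
#' @return data frame with columns `pre` and `post`.
#' @export
generate_pretreatment_pairs <- function(n_plots, init_mean = 50,
                                        init_dispersion = 49,
                                        projection_slope = 0.8,
                                        projection_k = 3, seed = 1L) {
  stopifnot(n_plots >= 2, n_plots %% 2 == 0)
  set.seed(seed)
  pre <- rnbinom_param(n_plots, rep(init_mean, n_plots), init_dispersion,
                       "linear")
  post <- project_posttreatment(pre, rep(FALSE, n_plots),
                                projection_slope, projection_k,
                                reduction_r = 0,
                                parameterization = "quadratic")
  data.frame(pre = pre, post = post)
}
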