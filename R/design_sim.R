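#' Fit a negative binomial distribution to counts
#'
#' Intercept-only maximum-likelihood fit under either parameterization of
#' the negative binomial variance:
#' \describe{
#'   \item{linear (NB1)}{var = mu (1 + phi); `dispersion` is phi.}
#'   \item{quadratic (NB2)}{var = mu (1 + mu / k); `dispersion` is the size
#'     k.}
#' }
#' Both are fitted by direct optimization of the NB log-likelihood over
#' (log mu, log dispersion); under NB1 the size parameter is mu / phi.
#' Near-Poisson samples (variance <= mean) pin the overdispersion near the
#' boundary and warn.
#'
#' @param counts integer vector of >= 5 non-negative counts.
#' @param parameterization `"linear"` (NB1) or `"quadratic"` (NB2).
#' @return object of class `nb_fit`: list with `mean`, `dispersion`,
#'   `parameterization`, `variance` (implied), `loglik`, `n`.
#' @examples
#' set.seed(1)
#' fit_nb(rnbinom(500, mu = 50, size = 12.5), "linear")
#' @export
fit_nb <- function(counts, parameterization = c("linear", "quadratic")) {
  parameterization <- match.arg(parameterization)
  counts <- check_counts(counts, min_n = 5L, allow_real = FALSE)
  xbar <- mean(counts)
  s2 <- stats::var(counts)
  if (xbar <= 0) stop("cannot fit NB to all-zero counts")
  overdisp <- s2 > xbar
  if (!overdisp) {
    warning("sample variance <= mean; dispersion pinned near 0 ",
            "(counts look Poisson or underdispersed)")
  }
  # moment starting values
  start_disp <- if (parameterization == "linear") {
    max(s2 / xbar - 1, 0.05)
  } else {
    max(xbar^2 / max(s2 - xbar, xbar * 0.05), 0.05)
  }
  nll <- function(par) {
    mu <- exp(par[1L]); disp <- exp(par[2L])
    size <- if (parameterization == "linear") mu / disp else disp
    -sum(stats::dnbinom(counts, size = size, mu = mu, log = TRUE))
  }
  opt <- stats::optim(c(log(xbar), log(start_disp)), nll,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  mu <- exp(opt$par[1L]); disp <- exp(opt$par[2L])
  variance <- if (parameterization == "linear") mu * (1 + disp)
    else mu * (1 + mu / disp)
  structure(list(mean = mu, dispersion = disp,
                 parameterization = parameterization,
                 variance = variance, loglik = -opt$value,
                 n = length(counts)),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf(
    "NB fit (%s): mean %.3f, dispersion %.3f (implied var %.3f), n %d\n",
    x$parameterization, x$mean, x$dispersion, x$variance, x$n))
  invisible(x)
}

# One NB draw vector under either parameterization; mean 0 -> 0 exactly.
rnbinom_param <- function(n, mu, dispersion, parameterization) {
  out <- integer(n)
  pos <- mu > 0
  if (any(pos)) {
    size <- if (parameterization == "linear") mu[pos] / dispersion
      else rep_len(dispersion, sum(pos))
    out[pos] <- stats::rnbinom(sum(pos), size = size, mu = mu[pos])
  }
  out
}

#' Assign plots to treatment under CRD and blocked designs
#'
#' Completely random design (CRD): a uniformly random split of the 2n
#' plots into two equal arms. Blocked design (RCBD): plots are sorted from
#' highest to lowest pretreatment abundance, consecutive plots are paired
#' into blocks, and within each pair one plot is randomly assigned to
#' treatment. Ties are broken by stable (input) order before the
#' within-pair randomization.
#'
#' @param init_counts pretreatment abundance per plot (even length).
#' @return list with `crd` (logical treated flag per plot), `rcbd`
#'   (logical treated flag) and `block` (integer block id per plot,
#'   1 = highest-abundance pair).
#' @examples
#' set.seed(1)
#' assign_designs(c(10, 9, 8, 7))$block  # plots 1,2 in block 1; 3,4 in 2
#' @export
assign_designs <- function(init_counts) {
  n2 <- length(init_counts)
  if (n2 < 2L || n2 %% 2L != 0L) {
    stop("need an even number (>= 2) of plots, got ", n2)
  }
  n <- n2 %/% 2L
  crd <- rep(FALSE, n2)
  crd[sample.int(n2, n)] <- TRUE
  ord <- order(-init_counts)           # stable for ties
  block <- integer(n2)
  block[ord] <- rep(seq_len(n), each = 2L)
  rcbd <- logical(n2)
  for (b in seq_len(n)) {
    pair <- ord[c(2L * b - 1L, 2L * b)]
    rcbd[pair[sample.int(2L, 1L)]] <- TRUE
  }
  list(crd = crd, rcbd = rcbd, block = block)
}

#' Project posttreatment counts from pretreatment abundance
#'
#' Each plot's posttreatment count is a negative binomial draw with mean
#' `projection_slope * N_init`, additionally multiplied by
#' `(1 - reduction_r)` for treated plots, and variance set by
#' `projection_dispersion` under the chosen parameterization (default
#' quadratic: var = mu (1 + mu / k)). Plots with `N_init = 0` get count 0
#' deterministically.
#'
#' @param init_counts pretreatment abundance per plot.
#' @param treated logical vector, `TRUE` for treated plots.
#' @param projection_slope slope beta of the posttreatment-on-pretreatment
#'   regression (> 0).
#' @param projection_dispersion NB dispersion of the projection (> 0).
#' @param reduction_r proportional reduction for treated plots, in
#'   \[0, 1\].
#' @param parameterization `"quadratic"` (default) or `"linear"`.
#' @return integer vector of posttreatment counts.
#' @export
project_posttreatment <- function(init_counts, treated, projection_slope,
                                  projection_dispersion, reduction_r,
                                  parameterization = c("quadratic",
                                                       "linear")) {
  parameterization <- match.arg(parameterization)
  if (projection_slope <= 0) stop("projection_slope must be > 0")
  if (projection_dispersion <= 0) stop("projection_dispersion must be > 0")
  if (reduction_r < 0 || reduction_r > 1) {
    stop("reduction_r must be in [0, 1]")
  }
  stopifnot(length(treated) == length(init_counts))
  mu <- projection_slope * init_counts
  mu[treated] <- mu[treated] * (1 - reduction_r)
  rnbinom_param(length(mu), mu, projection_dispersion, parameterization)
}

#' Test for a treatment reduction in one simulated experiment
#'
#' Overdispersed count regression of posttreatment count on the treatment
#' indicator — plus a block term for the blocked design — with a one-tailed
#' test (treated mean lower) on the treatment coefficient. With only an
#' intercept, a treatment indicator and (optionally) block factors on a log
#' link, the fitted treatment coefficient is the log ratio of
#' (block-adjusted) arm means under every variant below; the variants
#' differ in how the dispersion entering the test is estimated:
#' \describe{
#'   \item{`"quasi_f"` (default)}{quasi-Poisson regression; the one-tailed
#'     criterion is the signed root of the quasi-likelihood F statistic
#'     (deviance drop for treatment over the Pearson dispersion), referred
#'     to a t distribution with the residual degrees of freedom. The
#'     moment dispersion estimate keeps the one-sided size close to
#'     nominal at small replicate numbers, and the deviance-based
#'     statistic stays informative when one arm is all zeros (where Wald
#'     statistics collapse under separation).}
#'   \item{`"nb_wald"`}{NB2 regression ([MASS::glm.nb]); Wald ratio on the
#'     treatment coefficient, referred to t with the residual df. Liberal
#'     at small n under strong overdispersion because the ML size
#'     parameter underestimates dispersion.}
#'   \item{`"nb_random"`}{blocked design only: NB2 regression with a
#'     random block intercept via `glmmTMB` (Wald z). Closest to the
#'     original field-trial analysis, but slow and also liberal at small
#'     n; available when `glmmTMB` is installed.}
#' }
#' Blocks enter as fixed factor effects for `"quasi_f"`/`"nb_wald"`.
#' Fits that fail or have vanishing dispersion (e.g. both arms all zero)
#' are flagged degenerate and counted as non-significant.
#'
#' @param post_counts posttreatment counts.
#' @param treated logical treatment flag per plot.
#' @param block integer block ids (required for `design = "rcbd"`).
#' @param design `"crd"` or `"rcbd"`.
#' @param alpha one-sided significance level; default 0.05.
#' @param test `"quasi_f"`, `"nb_wald"` or `"nb_random"`.
#' @return list with `significant` (logical), `estimate` (treatment
#'   coefficient, log scale), `p_value` (one-tailed), `degenerate`.
#' @export
analyze_experiment <- function(post_counts, treated, block = NULL,
                               design = c("crd", "rcbd"), alpha = 0.05,
                               test = c("quasi_f", "nb_wald",
                                        "nb_random")) {
  design <- match.arg(design)
  test <- match.arg(test)
  stopifnot(length(post_counts) == length(treated))
  if (!any(treated) || all(treated)) stop("both arms must be non-empty")
  dat <- data.frame(y = as.numeric(post_counts),
                    trt = factor(treated, levels = c(FALSE, TRUE)))
  degenerate_result <- list(significant = FALSE, estimate = NA_real_,
                            p_value = NA_real_, degenerate = TRUE)
  if (design == "rcbd") {
    if (is.null(block)) stop("rcbd analysis requires block ids")
    dat$block <- factor(block)
  }
  if (test == "nb_random") {
    if (design != "rcbd") stop("test = 'nb_random' applies to the rcbd design")
    if (!requireNamespace("glmmTMB", quietly = TRUE)) {
      stop("test = 'nb_random' requires the glmmTMB package")
    }
    fit <- try(suppressWarnings(
      glmmTMB::glmmTMB(y ~ trt + (1 | block), data = dat,
                       family = glmmTMB::nbinom2())), silent = TRUE)
    if (inherits(fit, "try-error")) return(degenerate_result)
    sm <- try(summary(fit)$coefficients$cond, silent = TRUE)
    if (inherits(sm, "try-error") || !"trtTRUE" %in% rownames(sm) ||
        !is.finite(sm["trtTRUE", "Std. Error"])) {
      return(degenerate_result)
    }
    est <- sm["trtTRUE", "Estimate"]
    p <- stats::pnorm(sm["trtTRUE", "z value"])   # one-tailed, lower
    return(list(significant = isTRUE(p < alpha && est < 0),
                estimate = est, p_value = p, degenerate = FALSE))
  }
  form1 <- if (design == "rcbd") y ~ trt + block else y ~ trt
  form0 <- if (design == "rcbd") y ~ block else y ~ 1
  if (test == "nb_wald") {
    fit <- try(suppressWarnings(MASS::glm.nb(form1, data = dat)),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(degenerate_result)
    ct <- try(suppressWarnings(summary(fit)$coefficients), silent = TRUE)
    if (inherits(ct, "try-error") || !"trtTRUE" %in% rownames(ct) ||
        !is.finite(ct["trtTRUE", 2L]) || ct["trtTRUE", 2L] <= 0) {
      return(degenerate_result)
    }
    est <- ct["trtTRUE", 1L]
    p <- stats::pt(est / ct["trtTRUE", 2L],
                   df = max(1L, fit$df.residual))
    return(list(significant = isTRUE(p < alpha && est < 0),
                estimate = est, p_value = p, degenerate = FALSE))
  }
  # quasi_f
  f1 <- try(suppressWarnings(stats::glm(form1, data = dat,
                                        family = stats::quasipoisson())),
            silent = TRUE)
  f0 <- try(suppressWarnings(stats::glm(form0, data = dat,
                                        family = stats::quasipoisson())),
            silent = TRUE)
  if (inherits(f1, "try-error") || inherits(f0, "try-error")) {
    return(degenerate_result)
  }
  ct <- suppressWarnings(summary(f1)$coefficients)
  if (!"trtTRUE" %in% rownames(ct)) return(degenerate_result)
  est <- ct["trtTRUE", 1L]
  df <- max(1L, f1$df.residual)
  disp <- sum(stats::residuals(f1, type = "pearson")^2) / df
  if (!is.finite(disp) || disp <= 1e-10 || !is.finite(est)) {
    return(degenerate_result)
  }
  fstat <- (stats::deviance(f0) - stats::deviance(f1)) / disp
  p <- stats::pt(sign(est) * sqrt(max(fstat, 0)), df = df)
  list(significant = isTRUE(p < alpha && est < 0), estimate = est,
       p_value = p, degenerate = FALSE)
}

#' Simulation scenario for the design comparison
#'
#' Bundles the generative parameters of one simulated field experiment:
#' the NB fit describing pretreatment abundance, the projection of
#' posttreatment from pretreatment counts, the treatment reduction and the
#' experiment size.
#'
#' @param n_replicates plots per arm (>= 2).
#' @param reduction_r proportional reduction in \[0, 1).
#' @param init_mean,init_dispersion pretreatment NB mean and dispersion;
#'   defaults 50 and 49 (linear parameterization), i.e. a coefficient of
#'   variation of 1 — the between-plot variability level printed for
#'   mid-season sticky-trap surveys of aggregated nymph populations.
#' @param init_parameterization parameterization of the pretreatment NB;
#'   default `"linear"` (var = mu(1 + phi)).
#' @param projection_slope slope of posttreatment mean on pretreatment
#'   count; default 0.8 (a short-lag seasonal decline).
#' @param projection_dispersion NB dispersion of the projection; default 3
#'   (quadratic size k, putting the correlation between pretreatment and
#'   posttreatment counts near 0.8, the short-lag rank correlation typical
#'   of repeated trap surveys).
#' @param projection_parameterization default `"quadratic"`
#'   (var = mu(1 + mu/k)).
#' @param n_sims Monte-Carlo repetitions; default 300.
#' @param alpha one-sided significance level; default 0.05.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_replicates, reduction_r,
                         init_mean = 50, init_dispersion = 49,
                         init_parameterization = "linear",
                         projection_slope = 0.8,
                         projection_dispersion = 3,
                         projection_parameterization = "quadratic",
                         n_sims = 300L, alpha = 0.05) {
  stopifnot(n_replicates >= 2, reduction_r >= 0, reduction_r < 1,
            init_mean > 0, init_dispersion > 0, projection_slope > 0,
            projection_dispersion > 0, n_sims >= 1)
  structure(list(
    n_replicates = as.integer(n_replicates), reduction_r = reduction_r,
    init_mean = init_mean, init_dispersion = init_dispersion,
    init_parameterization = match.arg(init_parameterization,
                                      c("linear", "quadratic")),
    projection_slope = projection_slope,
    projection_dispersion = projection_dispersion,
    projection_parameterization = match.arg(projection_parameterization,
                                            c("quadratic", "linear")),
    n_sims = as.integer(n_sims), alpha = alpha
  ), class = "sim_scenario")
}

# One simulated experiment under both designs; returns named logical.
simulate_one <- function(sc, test = "quasi_f") {
  n2 <- 2L * sc$n_replicates
  init <- rnbinom_param(n2, rep(sc$init_mean, n2), sc$init_dispersion,
                        sc$init_parameterization)
  asg <- assign_designs(init)
  post_crd <- project_posttreatment(init, asg$crd, sc$projection_slope,
                                    sc$projection_dispersion,
                                    sc$reduction_r,
                                    sc$projection_parameterization)
  post_rcbd <- project_posttreatment(init, asg$rcbd, sc$projection_slope,
                                     sc$projection_dispersion,
                                     sc$reduction_r,
                                     sc$projection_parameterization)
  res_crd <- analyze_experiment(post_crd, asg$crd, design = "crd",
                                alpha = sc$alpha,
                                test = if (test == "nb_random") "quasi_f"
                                       else test)
  res_rcbd <- analyze_experiment(post_rcbd, asg$rcbd, block = asg$block,
                                 design = "rcbd", alpha = sc$alpha,
                                 test = test)
  c(crd = res_crd$significant, rcbd = res_rcbd$significant,
    crd_degenerate = res_crd$degenerate,
    rcbd_degenerate = res_rcbd$degenerate)
}

#' Monte-Carlo power of one scenario
#'
#' Runs `n_sims` simulated experiments of a scenario and estimates power
#' under both designs as the fraction of one-tailed significant results.
#'
#' @param scenario [sim_scenario] object.
#' @param seed integer seed (the single source of randomness).
#' @param test analysis variant, see [analyze_experiment()]; default
#'   `"quasi_f"`.
#' @return data frame with one row per design: `design`, `power`, `mc_se`
#'   (binomial Monte-Carlo standard error), `n_degenerate`, plus scenario
#'   descriptors.
#' @export
estimate_power <- function(scenario, seed = NULL, test = "quasi_f") {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  hits <- matrix(FALSE, nrow = scenario$n_sims, ncol = 4L)
  for (i in seq_len(scenario$n_sims)) {
    hits[i, ] <- simulate_one(scenario, test = test)
  }
  p <- colMeans(hits[, 1:2, drop = FALSE])
  data.frame(
    design = c("crd", "rcbd"),
    n_replicates = scenario$n_replicates,
    reduction_r = scenario$reduction_r,
    power = as.numeric(p),
    mc_se = sqrt(p * (1 - p) / scenario$n_sims),
    n_degenerate = as.integer(colSums(hits[, 3:4, drop = FALSE])),
    n_sims = scenario$n_sims,
    stringsAsFactors = FALSE)
}

#' Power grid over replicates x reduction
#'
#' Estimates Monte-Carlo power for every combination of replicate number
#' and proportional reduction, under both the completely random and the
#' blocked design, from one seeded generator (cells consume random draws
#' in a fixed row-major order, so the full grid is reproducible from the
#' seed).
#'
#' @param n_replicates integer vector of plots per arm.
#' @param reductions numeric vector of proportional reductions in \[0, 1).
#' @param seed integer seed.
#' @param test analysis variant passed to [analyze_experiment()];
#'   default `"quasi_f"`.
#' @param ... scenario parameters passed to [sim_scenario()]
#'   (`init_mean`, `init_dispersion`, `projection_slope`,
#'   `projection_dispersion`, `n_sims`, `alpha`, ...).
#' @return data frame of class `power_grid`: long format with one row per
#'   (n_replicates, reduction_r, design) holding `power`, `mc_se` and the
#'   degenerate-fit tally.
#' @seealso [power_threshold()] for the smallest detectable reduction per
#'   design at a power cutoff.
#' @export
power_grid <- function(n_replicates, reductions, seed = 1L,
                       test = "quasi_f", ...) {
  stopifnot(length(n_replicates) > 0L, length(reductions) > 0L)
  set.seed(seed)
  out <- list()
  for (n in n_replicates) {
    for (r in reductions) {
      sc <- sim_scenario(n_replicates = n, reduction_r = r, ...)
      out[[length(out) + 1L]] <- estimate_power(sc, seed = NULL,
                                                test = test)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("power_grid", class(res))
  attr(res, "seed") <- seed
  res
}

#' Smallest reliably detectable reduction per design
#'
#' For each (replicates, design) cell of a [power_grid()], reports the
#' smallest proportional reduction whose estimated power reaches the
#' cutoff (default 0.80), and classifies each (replicates, reduction) cell
#' by which design(s) reach the cutoff (`both`, `blocked_only`,
#' `random_only`, `neither`).
#'
#' @param grid [power_grid()] result.
#' @param cutoff power cutoff; default 0.80.
#' @return list with `threshold` (data frame: `design`, `n_replicates`,
#'   `min_detectable_r`, `NA` when never reached) and `cells` (data
#'   frame: `n_replicates`, `reduction_r`, `category`).
#' @export
power_threshold <- function(grid, cutoff = 0.80) {
  stopifnot(all(c("design", "n_replicates", "reduction_r", "power")
                %in% names(grid)))
  thr <- do.call(rbind, lapply(
    split(grid, list(grid$design, grid$n_replicates), drop = TRUE),
    function(g) {
      hit <- g$reduction_r[g$power >= cutoff]
      data.frame(design = g$design[1L], n_replicates = g$n_replicates[1L],
                 min_detectable_r = if (length(hit)) min(hit) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  rownames(thr) <- NULL
  wide <- merge(
    grid[grid$design == "crd", c("n_replicates", "reduction_r", "power")],
    grid[grid$design == "rcbd", c("n_replicates", "reduction_r", "power")],
    by = c("n_replicates", "reduction_r"), suffixes = c("_crd", "_rcbd"))
  wide$category <- ifelse(
    wide$power_crd >= cutoff & wide$power_rcbd >= cutoff, "both",
    ifelse(wide$power_rcbd >= cutoff, "blocked_only",
           ifelse(wide$power_crd >= cutoff, "random_only", "neither")))
  list(threshold = thr[order(thr$design, thr$n_replicates), ],
       cells = wide[order(wide$n_replicates, wide$reduction_r),
                    c("n_replicates", "reduction_r", "category")])
}
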