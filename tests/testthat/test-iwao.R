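test_that("patchiness regression recovers exact and closed-form lines", {
  # noiseless line through origin
  f <- suppressWarnings(iwao_fit(c(1, 2, 3), c(2, 4, 6), through_origin = TRUE))
  expect_equal(f$slope, 2)
  expect_equal(f$r_squared, 1)
  expect_equal(f$intercept, 0)
  # the same line recovered with a free intercept
  f2 <- suppressWarnings(iwao_fit(c(1, 2, 3), c(2, 4, 6)))
  expect_equal(f2$slope, 2, tolerance = 1e-10)
  expect_equal(f2$intercept, 0, tolerance = 1e-10)
  # closed-form OLS: slope = Sxy/Sxx = 3.9/2, intercept = ybar - b*xbar
  f3 <- iwao_fit(c(1, 2, 3), c(2.1, 3.9, 6.0))
  expect_equal(f3$slope, 1.95, tolerance = 1e-10)
  expect_equal(f3$intercept, 0.10, tolerance = 1e-10)
  # two-column input form
  f4 <- iwao_fit(data.frame(x = c(1, 2, 3), y = c(2.1, 3.9, 6.0)))
  expect_equal(f4$slope, f3$slope)
})

test_that("through-origin slope equals sum(xy)/sum(x^2) on arbitrary data", {
  set.seed(2)
  for (i in 1:10) {
    x <- runif(sample(2:30, 1), 1, 100)
    y <- 1.5 * x + rnorm(length(x), 0, 5)
    f <- iwao_fit(x, y, through_origin = TRUE)
    expect_equal(f$slope, sum(x * y) / sum(x^2), tolerance = 1e-10)
  }
})

test_that("fit contracts: too few or degenerate points error", {
  expect_error(iwao_fit(c(1, 2), c(1, 2)), "at least 3")
  expect_error(iwao_fit(c(2, 2, 2), c(1, 2, 3)), "singular")
  f <- suppressWarnings(iwao_fit(c(1, 2, 3), c(2, 4, 6), through_origin = TRUE))
  f$slope_se <- 0
  expect_error(aggregation_inference(f), "SE")
})

test_that("aggregation inference tests the slope against 1", {
  agg <- aggregation_inference(list(slope = 1.41, slope_se = 0.03,
                                    df = 25))
  expect_equal(agg$classification, "aggregated")
  expect_equal(aggregation_inference(list(slope = 1.0, slope_se = 0.1,
                                          df = 25))$classification,
               "random")
  unif <- aggregation_inference(list(slope = 0.5, slope_se = 0.05,
                                     df = 20))
  expect_equal(unif$classification, "uniform")
  # oracle: |t| compared against the t quantile
  expect_equal(unif$t_value, (0.5 - 1) / 0.05)
  expect_true(abs(unif$t_value) > qt(0.975, 20))
})

test_that("slope on NB-generated groups recovers 1 + 1/k", {
  # pure NB counts (no latent heterogeneity): m* = m(1 + 1/k) exactly
  cfg <- synthetic_config(n_sites = 5, traps_per_site = 30,
                          dates = as.Date("2020-06-11") + 3 * (0:9),
                          baseline_mean = 60, nb_size_k = 2,
                          decline_rate = 0.05, trap_sd = 0, seed = 99)
  ds <- with_combined_instar(generate_trap_data(cfg))
  pts <- iwao_points(ds)
  pts <- pts[pts$instar == "combined", ]
  f <- iwao_fit(pts$mean_density, pts$mean_crowding)
  expect_equal(f$slope, 1.5, tolerance = 2 * f$slope_se / 1.5 + 0.02)
  expect_lt(abs(f$slope - 1.5), 2 * f$slope_se)
})

test_that("Poisson-like data yields slope near 1", {
  set.seed(8)
  means <- runif(60, 2, 60)
  pts <- t(vapply(means, function(m) {
    x <- rpois(40, m)
    c(mean(x), mean_crowding(x))
  }, numeric(2)))
  f <- iwao_fit(pts[, 1], pts[, 2])
  expect_equal(f$slope, 1, tolerance = 0.05)
})

test_that("fit_by_subset fits named record filters and is self-consistent", {
  cfg <- synthetic_config(n_sites = 6, traps_per_site = 20,
                          dates = as.Date("2020-06-11") + 3 * (0:7),
                          baseline_mean = 50, nb_size_k = 2,
                          decline_rate = 0.04, trap_sd = 0, seed = 7)
  ds <- with_combined_instar(generate_trap_data(cfg))
  first_half <- as.Date("2020-06-11") + 3 * (0:3)
  res <- fit_by_subset(ds, subsets = list(
    all = function(d) d$instar == "combined",
    early = function(d) d$instar == "combined" & d$date %in% first_half,
    late = function(d) d$instar == "combined" & !d$date %in% first_half))
  expect_equal(nrow(res), 3L)
  # homogeneous generator: subset slopes agree within joint 2 SE
  se_joint <- sqrt(res$slope_se[2]^2 + res$slope_se[3]^2)
  expect_lt(abs(res$slope[2] - res$slope[3]), 2.5 * se_joint)
  # contracts
  expect_error(fit_by_subset(ds, subsets = list(none = function(d)
    rep(FALSE, nrow(d)))), "selects no records")
  one_group <- function(d) d$instar == "combined" &
    d$date == as.Date("2020-06-11") & d$site == "S01"
  expect_error(fit_by_subset(ds, subsets = list(one = one_group)),
               "regression point")
})
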