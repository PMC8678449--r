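test_that("generation is deterministic in the seed", {
  cfg <- synthetic_config(n_sites = 2, traps_per_site = 5, seed = 123)
  d1 <- generate_trap_data(cfg)
  d2 <- generate_trap_data(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- generate_trap_data(synthetic_config(n_sites = 2, traps_per_site = 5,
                                            seed = 124))
  expect_false(identical(d1$count, d3$count))
  pp1 <- generate_pretreatment_pairs(50, seed = 9)
  pp2 <- generate_pretreatment_pairs(50, seed = 9)
  expect_identical(pp1, pp2)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(instar_mixture = c(0.5, 0.5, 0.1, 0.1)),
               "instar_mixture")
  expect_error(synthetic_config(trap_autocorr = 1), "trap_autocorr")
  expect_error(synthetic_config(baseline_mean = 0), "baseline_mean")
})

test_that("stationary configuration keeps per-date means level", {
  cfg <- synthetic_config(n_sites = 1, traps_per_site = 400,
                          dates = as.Date("2020-06-11") + 3 * (0:3),
                          baseline_mean = 50, nb_size_k = 4,
                          decline_rate = 0, trap_autocorr = 0,
                          trap_sd = 0, seed = 5)
  ds <- with_combined_instar(generate_trap_data(cfg))
  m <- tapply(ds$count[ds$instar == "combined"],
              ds$date[ds$instar == "combined"], mean)
  expect_true(all(abs(m - 50) / 50 < 0.08))
})

test_that("treatment effect halves the grand mean", {
  base <- synthetic_config(n_sites = 1, traps_per_site = 3000,
                           dates = as.Date("2020-06-11"),
                           baseline_mean = 40, nb_size_k = 2,
                           decline_rate = 0, trap_sd = 0, seed = 10)
  trt <- synthetic_config(n_sites = 1, traps_per_site = 3000,
                          dates = as.Date("2020-06-11"),
                          baseline_mean = 40, nb_size_k = 2,
                          decline_rate = 0, trap_sd = 0,
                          treated_fraction = 1, treatment_effect_r = 0.5,
                          seed = 10)
  m0 <- mean(with_combined_instar(generate_trap_data(base))$count[
    rep(c(FALSE, FALSE, FALSE, FALSE, TRUE), 3000)])
  ds1 <- with_combined_instar(generate_trap_data(trt))
  m1 <- mean(ds1$count[ds1$instar == "combined"])
  expect_equal(m1 / m0, 0.5, tolerance = 0.05)
})

test_that("variance-to-mean ratio follows the NB quadratic law", {
  cfg <- synthetic_config(n_sites = 1, traps_per_site = 5000,
                          dates = as.Date("2020-06-11"),
                          baseline_mean = 30, nb_size_k = 2,
                          decline_rate = 0, trap_sd = 0, seed = 20)
  ds <- with_combined_instar(generate_trap_data(cfg))
  y <- ds$count[ds$instar == "combined"]
  expect_equal(var(y) / mean(y), 1 + mean(y) / 2, tolerance = 0.06)
  # instar split preserves the total
  tot <- tapply(ds$count[ds$instar != "combined"],
                ds$trap_id[ds$instar != "combined"], sum)
  comb <- tapply(ds$count[ds$instar == "combined"],
                 ds$trap_id[ds$instar == "combined"], sum)
  expect_equal(as.numeric(tot), as.numeric(comb))
  # instar mixture proportions recovered
  prop <- tapply(ds$count[ds$instar != "combined"],
                 ds$instar[ds$instar != "combined"], sum)
  expect_equal(as.numeric(prop / sum(prop)), c(0.4, 0.3, 0.2, 0.1),
               tolerance = 0.02)
})

test_that("pretreatment pairs are positively correlated and identity-limited", {
  pp <- generate_pretreatment_pairs(1000, seed = 2)
  expect_gt(cor(pp$pre, pp$post, method = "spearman"), 0.5)
  # slope 1, near-deterministic projection: post close to pre
  pp2 <- generate_pretreatment_pairs(400, projection_slope = 1,
                                     projection_k = 1e6, seed = 3)
  expect_equal(mean(pp2$post / pmax(pp2$pre, 1)), 1, tolerance = 0.02)
  expect_error(generate_pretreatment_pairs(7), "n_plots")
})

test_that("aggregated generated data is classified aggregated end-to-end", {
  cfg <- synthetic_config(n_sites = 4, traps_per_site = 30,
                          dates = as.Date("2020-06-11") + 3 * (0:4),
                          baseline_mean = 60, nb_size_k = 2,
                          decline_rate = 0.02, trap_sd = 0, seed = 30)
  ds <- with_combined_instar(generate_trap_data(cfg))
  res <- classify_groups(ds)
  comb <- res[res$instar == "combined", ]
  expect_gte(mean(comb$classification == "aggregated"), 0.9)
})
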