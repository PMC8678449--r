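test_that("fit_nb recovers parameters under both parameterizations", {
  set.seed(31)
  # NB1: mu = 50, phi = 4 -> size = mu/phi = 12.5, var = 250
  x <- rnbinom(3000, size = 12.5, mu = 50)
  f1 <- fit_nb(x, "linear")
  expect_equal(f1$mean, 50, tolerance = 0.05)
  expect_equal(f1$dispersion, 4, tolerance = 0.25)
  # NB2 on the same draws: implied variance must agree with NB1's
  f2 <- fit_nb(x, "quadratic")
  expect_equal(f2$mean, f1$mean, tolerance = 1e-3)
  expect_equal(f2$variance / f1$variance, 1, tolerance = 0.02)
  # cross-check NB2 against the independent MASS::glm.nb ML route
  g <- suppressWarnings(MASS::glm.nb(x ~ 1))
  expect_equal(f2$mean, unname(exp(coef(g)[1])), tolerance = 1e-3)
  expect_equal(f2$dispersion, g$theta, tolerance = 0.02 * g$theta)
  # boundary: near-Poisson data warns and pins dispersion low
  y <- rpois(500, 10)
  if (var(y) <= mean(y)) {
    expect_warning(fb <- fit_nb(y, "linear"), "pinned")
    expect_lt(fb$dispersion, 0.2)
  }
  expect_error(fit_nb(c(1L, 2L, 3L), "linear"), "at least 5")
  expect_error(fit_nb(c(1.5, 2, 3, 4, 5), "linear"), "integers")
})

test_that("design assignment builds sorted pairs and balanced arms", {
  set.seed(41)
  a <- assign_designs(c(10, 9, 8, 7))
  # blocks are {10,9} and {8,7} in every run
  expect_equal(a$block, c(1L, 1L, 2L, 2L))
  for (i in 1:20) {
    init <- rnbinom(12, size = 1, mu = 30)
    a <- assign_designs(init)
    expect_equal(sum(a$crd), 6L)
    expect_equal(sum(a$rcbd), 6L)
    # exactly one treated plot per block
    expect_true(all(tapply(a$rcbd, a$block, sum) == 1L))
    # blocks are contiguous in sorted order
    ord <- order(-init)
    expect_equal(a$block[ord], rep(1:6, each = 2))
  }
  # each plot treated about half the time under both designs
  hits <- replicate(3000, {
    a <- assign_designs(c(5, 4, 3, 2))
    c(a$crd, a$rcbd)
  })
  expect_true(all(abs(rowMeans(hits) - 0.5) < 0.04))
  expect_error(assign_designs(c(1, 2, 3)), "even")
})

test_that("posttreatment projection has the right moments and edge cases", {
  set.seed(51)
  # r = 1: all treated counts exactly 0
  post <- project_posttreatment(c(10, 20, 30, 40), c(TRUE, TRUE, FALSE, FALSE),
                                0.8, 3, reduction_r = 1)
  expect_equal(post[1:2], c(0L, 0L))
  # N_init = 0 -> deterministically 0
  expect_equal(project_posttreatment(c(0, 0), c(FALSE, TRUE), 0.8, 3, 0.5),
               c(0L, 0L))
  # moment check: control mean = slope * N_init
  draws <- replicate(40, mean(project_posttreatment(
    rep(100, 250), rep(FALSE, 250), 0.8, 5, 0)))
  expect_equal(mean(draws), 80, tolerance = 0.01)
  # r = 0: treated and control draws are exchangeable
  big <- project_posttreatment(rep(50, 4000), rep(c(TRUE, FALSE), 2000),
                               0.9, 3, reduction_r = 0)
  ks <- suppressWarnings(ks.test(big[c(TRUE, FALSE)], big[c(FALSE, TRUE)]))
  expect_gt(ks$p.value, 0.01)
  expect_error(project_posttreatment(1, TRUE, 0, 3, 0.5), "slope")
})

test_that("experiment analysis detects separation and respects identical arms", {
  # treated counts all 0, control large -> significant
  res <- analyze_experiment(c(35, 40, 52, 31, 28, 44, 39, 50,
                              0, 0, 0, 0, 0, 0, 0, 0),
                            rep(c(FALSE, TRUE), each = 8))
  expect_false(res$degenerate)
  expect_true(res$significant)
  # identical arms -> not significant
  y <- rep(c(10, 20, 30, 40), 2)
  res2 <- analyze_experiment(y, rep(c(FALSE, TRUE), each = 4))
  expect_false(res2$significant)
  # all-zero everything -> degenerate, counted non-significant
  res3 <- analyze_experiment(rep(0, 8), rep(c(FALSE, TRUE), each = 4))
  expect_true(res3$degenerate)
  expect_false(res3$significant)
  # rcbd needs blocks
  expect_error(analyze_experiment(y, rep(c(FALSE, TRUE), each = 4),
                                  design = "rcbd"), "block")
  expect_error(analyze_experiment(y, rep(TRUE, 8)), "arms")
})

test_that("type-I error of the default CRD analysis is near nominal", {
  set.seed(61)
  rej <- replicate(400, {
    init <- rnbinom(16, size = 50 / 49, mu = 50)
    trt <- sample(rep(c(FALSE, TRUE), 8))
    post <- project_posttreatment(init, trt, 0.8, 3, reduction_r = 0)
    analyze_experiment(post, trt)$significant
  })
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})

test_that("power grids are seed-reproducible and structurally complete", {
  g1 <- power_grid(n_replicates = c(4, 8), reductions = c(0, 0.8),
                   seed = 77, n_sims = 40)
  g2 <- power_grid(n_replicates = c(4, 8), reductions = c(0, 0.8),
                   seed = 77, n_sims = 40)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  expect_equal(nrow(g1), 8L)  # 2 n x 2 r x 2 designs
  expect_true(all(table(g1$design, g1$n_replicates, g1$reduction_r) == 1))
  # sanity: a large effect with decent replication is usually detected
  expect_true(all(g1$power[g1$reduction_r == 0.8 &
                             g1$n_replicates == 8] > 0.6))
  thr <- power_threshold(g1)
  expect_equal(nrow(thr$threshold), 4L)
  expect_true(all(thr$cells$category %in%
                    c("both", "blocked_only", "random_only", "neither")))
})
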