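test_that("shuffle_pairing preserves both marginals exactly and is seed-deterministic", {
  for (i in 1:25) {
    p <- oracle_point_set(i + 500, n_max = 60)
    s <- shuffle_pairing(p, seed = i)
    expect_identical(sort(s$x), sort(p$x))
    expect_identical(sort(s$y), sort(p$y))
    expect_identical(as.data.frame(shuffle_pairing(p, seed = i)),
                     as.data.frame(s))
  }
  # only two pairings exist for two points
  p2 <- point_set(c(1, 2), c(10, 20))
  s2 <- shuffle_pairing(p2, seed = 3)
  expect_true(identical(sort(s2$y[order(s2$x)]), c(10, 20)))
  # the seeded path must not disturb the caller's RNG stream
  set.seed(99); before <- .Random.seed
  shuffle_pairing(p2, seed = 1)
  expect_identical(.Random.seed, before)
})

test_that("build_null is reproducible, bounded, and self-consistent across seeds", {
  p <- gen_independent(100, seed = 11)
  a <- build_null(p, "A", n_perm = 199, seed = 5)
  b <- build_null(p, "A", n_perm = 199, seed = 5)
  expect_identical(a$q_values, b$q_values)
  expect_length(a$q_values, 199)
  expect_true(all(a$q_values >= 0 & a$q_values < 1))
  expect_equal(a$mean, mean(a$q_values))
  expect_equal(a$sd, sd(a$q_values))
  expect_identical(a$seed, 5L)

  # two independent nulls for the same data agree within Monte-Carlo error
  c2 <- build_null(p, "A", n_perm = 500, seed = 77)
  d2 <- build_null(p, "A", n_perm = 500, seed = 78)
  se <- sqrt(c2$sd^2 / 500 + d2$sd^2 / 500)
  expect_lt(abs(c2$mean - d2$mean), 3 * se)

  expect_error(build_null(p, "A", n_perm = 1), "n_perm")
})

test_that("z_statistic follows the (Q_obs - mean)/sd definition with degenerate guards", {
  null <- structure(list(mean = 0.10, sd = 0.05), class = "null_dist")
  expect_equal(z_statistic(0.10, null), 0)
  expect_equal(z_statistic(0.15, null), 1)
  expect_equal(z_statistic(0.30, null), 4)
  flat <- structure(list(mean = 0.2, sd = 0), class = "null_dist")
  expect_equal(z_statistic(0.2, flat), 0)
  expect_warning(zi <- z_statistic(0.5, flat), "infinite")
  expect_identical(zi, Inf)
})

test_that("p_value is the upper normal tail and strictly decreasing", {
  expect_equal(p_value(0), 0.5)
  expect_equal(p_value(1.6448536), 0.05, tolerance = 1e-6)
  expect_equal(p_value(-1), stats::pnorm(1), tolerance = 1e-12)
  z <- seq(-4, 8, by = 0.25)
  expect_true(all(diff(p_value(z)) < 0))
})

test_that("empirical_p uses the add-one estimator with ties counted against Q_obs", {
  null999 <- structure(list(q_values = seq(0, 0.5, length.out = 999),
                            n_perm = 999L), class = "null_dist")
  expect_equal(empirical_p(0.6, null999), 1 / 1000)
  expect_equal(empirical_p(0, null999), 1)
  med9 <- structure(list(q_values = (1:9) / 10, n_perm = 9L),
                    class = "null_dist")
  expect_equal(empirical_p(0.5, med9), 6 / 10)
  # never increases as Q_obs increases
  q <- seq(0, 0.7, by = 0.05)
  expect_true(all(diff(vapply(q, empirical_p, numeric(1), null = null999)) <= 0))
})

test_that("significance stars follow the ladder and are configurable", {
  expect_identical(stars(1e-12), "*****")
  expect_identical(stars(0.0009), "**")
  expect_identical(stars(0.2), "NS")
  expect_identical(stars(c(1e-7, 1e-5, 4e-3, 0.03)),
                   c("****", "***", "*", "n.s.-gap"))
  expect_identical(stars(0.03, thresholds = c(0.01, 0.05),
                         labels = c("sig", "weak")), "weak")
})

test_that("run_zone_tests reports one consistent row per zone, deterministically", {
  p <- gen_independent(60, seed = 21)
  res <- run_zone_tests(p, zones = "all", n_perm = 99, seed = 4)
  expect_s3_class(res, "zone_test_result")
  expect_identical(res$zone, c("A", "B", "C", "D"))
  expect_identical(names(res),
                   c("zone", "n_points", "Q_obs", "mean_null", "sd_null",
                     "Z", "p_z", "p_emp", "stars", "n_perm", "seed"))
  expect_true(all(res$n_points == 60))
  expect_equal(res$Z, (res$Q_obs - res$mean_null) / res$sd_null)
  expect_equal(res$p_z, p_value(res$Z))

  res2 <- run_zone_tests(p, zones = "all", n_perm = 99, seed = 4)
  expect_identical(res, res2)

  # a zone's result does not depend on which other zones are requested
  only_b <- run_zone_tests(p, zones = "B", n_perm = 99, seed = 4)
  expect_equal(as.data.frame(only_b),
               as.data.frame(res[res$zone == "B", ]),
               ignore_attr = TRUE)
  expect_equal(only_b$Q_obs, res$Q_obs[2])
  expect_equal(only_b$Z, res$Z[2])
})

test_that("a constraint above the diagonal scores higher for zone A than zone D", {
  # points hugging y = x from below: upper-left empty, lower-right filled
  p <- gen_triangular(150, strength = 1, seed = 31)
  res <- run_zone_tests(p, zones = c("A", "D"), n_perm = 199, seed = 8)
  expect_gt(res$Z[res$zone == "A"], res$Z[res$zone == "D"])
  expect_lt(res$p_z[res$zone == "A"], 1e-6)
})

test_that("Bonferroni flag multiplies p by the number of zones, capped at 1", {
  p <- gen_independent(50, seed = 41)
  raw <- run_zone_tests(p, zones = "all", n_perm = 99, seed = 2)
  adj <- run_zone_tests(p, zones = "all", n_perm = 99, seed = 2,
                        bonferroni = TRUE)
  expect_equal(adj$p_z, pmin(1, raw$p_z * 4))
  expect_equal(adj$p_emp, pmin(1, raw$p_emp * 4))
})

test_that("run_zone_tests rejects scatters that cannot carry the statistic", {
  expect_error(run_zone_tests(point_set(c(0, 1), c(0, 1)), zones = "A",
                              n_perm = 9, seed = 1),
               class = "zoneperm_insufficient_error")
  expect_error(run_zone_tests(point_set(c(1, 1, 1), c(1, 2, 3)),
                              zones = "A", n_perm = 9, seed = 1),
               class = "zoneperm_degenerate_error")
})

test_that("leave-one-out Z scores match a direct loop and handle degeneracy", {
  null <- structure(list(q_values = c(1, 2, 3), n_perm = 3L),
                    class = "null_dist")
  z <- permutation_self_z(null)
  expect_equal(z[3], (3 - 1.5) / sd(c(1, 2)), tolerance = 1e-12)
  expect_equal(z[3], 2.1213, tolerance = 1e-4)

  flat <- structure(list(q_values = rep(0.25, 10), n_perm = 10L),
                    class = "null_dist")
  expect_identical(permutation_self_z(flat), rep(0, 10))

  spike <- structure(list(q_values = c(0, 0, 3), n_perm = 3L),
                     class = "null_dist")
  expect_warning(zs <- permutation_self_z(spike), "infinite")
  expect_identical(zs[3], Inf)

  rnd <- build_null(gen_independent(40, seed = 3), "A", n_perm = 50, seed = 9)
  expect_equal(permutation_self_z(rnd), oracle_loo_z(rnd$q_values),
               tolerance = 1e-9)
})
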