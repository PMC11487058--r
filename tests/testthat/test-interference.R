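test_that("pair bookkeeping reproduces the worked three-chromosome case", {
  # counts (1, 2, 3): mean pair count 4/3, regardless of positions
  ds_broad <- chromosome_dataset(list(0.5, c(0.2, 0.8), c(0.1, 0.5, 0.9)),
                                 length_L = 1)
  ps <- pair_statistics(ds_broad)
  expect_identical(ps$n_obs_pair, 4 / 3)
  expect_identical(ps$mean_count, 2)
  expect_identical(ps$n_noint_pair, 2)

  # counts (2, 2, 2): mean pair count 1, phi = 1/2
  ds_narrow <- chromosome_dataset(list(c(0.2, 0.8), c(0.3, 0.7),
                                       c(0.1, 0.9)), length_L = 1)
  ps2 <- pair_statistics(ds_narrow)
  expect_identical(ps2$n_obs_pair, 1)
  expect_identical(ps2$phi, 0.5)
  expect_identical(ps2$n_mis_pair, 1)
})

test_that("interference length matches the hand-computed example", {
  ds <- chromosome_dataset(list(c(0.2, 0.8), 0.5, c(0.1, 0.9)),
                           length_L = 1)
  ps <- pair_statistics(ds)
  expect_equal(ps$phi, 12 / 25)
  expect_equal(ps$d_obs, 0.7)
  expect_equal(ps$d_noint, 0.44)
  fit <- interference_length(ds)
  expect_equal(fit$l_int, 0.416, tolerance = 1e-12)
  expect_equal(fit$l_int_norm, 0.416 * (5 / 3) / 1, tolerance = 1e-12)
  # reproducible from the bookkeeping
  expect_equal(fit$l_int,
               ps$phi * (ps$d_obs - ps$d_noint) +
                 (1 - ps$phi) * (1 - ps$d_noint))
  # when no pairs are missing-negative, Eq-style weighted average agrees
  expect_equal(fit$l_int, ps$d_int - ps$d_noint)
  expect_equal(coef(fit), c(L_int = 0.416, L_int_norm = 0.416 * 5 / 3),
               tolerance = 1e-12)
})

test_that("identical single positions give the degenerate maximum L", {
  ds <- chromosome_dataset(rep(list(7.3), 50), length_L = 21)
  ps <- pair_statistics(ds)
  expect_identical(ps$phi, 0)
  expect_identical(ps$d_noint, 0)
  expect_true(is.na(ps$d_obs))
  fit <- interference_length(ds)
  expect_identical(fit$l_int, 21)
})

test_that("degenerate inputs are refused", {
  empty <- chromosome_dataset(list(numeric(), numeric()), length_L = 1)
  expect_error(pair_statistics(empty), "<N> = 0")
  expect_error(interference_length(empty), "<N> = 0")
  single <- chromosome_dataset(list(0.5, numeric()), length_L = 1)
  expect_error(pair_statistics(single), "fewer than two")
})

test_that("excess pairs relative to the Poisson null warn about clustering", {
  # counts (0, 0, 4): <N> = 4/3, observed pairs 2 > expected 8/9
  ds <- chromosome_dataset(list(numeric(), numeric(),
                                c(0.1, 0.2, 0.3, 0.4)), length_L = 1)
  ps <- pair_statistics(ds)
  expect_lt(ps$n_mis_pair, 0)
  expect_true(is.na(ps$d_int))
  expect_warning(fit <- interference_length(ds), "clustering")
  expect_true(is.finite(fit$l_int))
})

test_that("the estimator is scale equivariant", {
  set.seed(5)
  ds <- simulate_crossovers("renewal", 400, mean_count = 3, shape = 4)
  c_scale <- 3.7
  ds_c <- chromosome_dataset(lapply(ds$positions, `*`, c_scale),
                             length_L = ds$length_L * c_scale)
  f1 <- interference_length(ds)
  f2 <- interference_length(ds_c)
  expect_equal(f2$l_int, c_scale * f1$l_int, tolerance = 1e-12)
  expect_equal(f2$pair_stats$d_obs, c_scale * f1$pair_stats$d_obs,
               tolerance = 1e-12)
  expect_equal(f2$pair_stats$d_noint, c_scale * f1$pair_stats$d_noint,
               tolerance = 1e-12)
  expect_equal(f2$pair_stats$phi, f1$pair_stats$phi, tolerance = 1e-14)
  expect_equal(f2$l_int_norm, f1$l_int_norm, tolerance = 1e-12)
})

test_that("L_int is bounded by L - d_noInt when phi is a proper fraction", {
  set.seed(9)
  for (model in c("obligate", "regular", "renewal")) {
    ds <- simulate_crossovers(model, 300, mean_count = 3, shape = 6)
    fit <- suppressWarnings(interference_length(ds))
    ps <- fit$pair_stats
    if (ps$phi >= 0 && ps$phi <= 1) {
      expect_lte(fit$l_int, ps$L - ps$d_noint + 1e-12)
      if (ps$phi == 0) {
        expect_equal(fit$l_int, ps$L - ps$d_noint)
      }
    }
  }
  # phi = 0 attains the bound exactly
  ob <- simulate_crossovers("obligate", 500, seed = 2)
  fit <- interference_length(ob)
  expect_equal(fit$l_int, fit$L - fit$pair_stats$d_noint)
})

test_that("bivalent correction doubles the count in the normalization only", {
  ds <- simulate_crossovers("poisson", 500, mean_count = 2, seed = 3)
  f0 <- suppressWarnings(interference_length(ds))
  f2 <- suppressWarnings(interference_length(ds,
                                             bivalent_correction = TRUE))
  expect_identical(f2$l_int, f0$l_int)
  expect_equal(f2$l_int_norm, 2 * f0$l_int_norm)
})

test_that("the null simulator reproduces the fitted mean and density", {
  ds <- simulate_crossovers("poisson", 2000, mean_count = 2, seed = 4,
                            position_density = "bimodal")
  fit <- suppressWarnings(interference_length(ds))
  sims <- simulate(fit, nsim = 3, seed = 99)
  expect_length(sims, 3)
  counts <- vapply(sims, function(s) mean(co_counts(s)), numeric(1))
  expect_equal(mean(counts), fit$pair_stats$mean_count, tolerance = 0.05)
  # null draws come from the pooled observed positions
  expect_true(all(unlist(sims[[1]]$positions) %in%
                    unlist(ds$positions)))
  # determinism
  sims2 <- simulate(fit, nsim = 3, seed = 99)
  expect_identical(sims, sims2)
})
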