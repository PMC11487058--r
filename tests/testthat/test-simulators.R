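test_that("simulation is a deterministic function of config and seed", {
  for (model in c("poisson", "obligate", "regular", "fixed", "renewal")) {
    d1 <- simulate_crossovers(model, 200, mean_count = 2, shape = 4,
                              seed = 41)
    d2 <- simulate_crossovers(model, 200, mean_count = 2, shape = 4,
                              seed = 41)
    expect_identical(d1, d2)
  }
  # long aliases map onto the same models
  expect_identical(simulate_crossovers("poisson_null", 50, seed = 1),
                   simulate_crossovers("poisson", 50, seed = 1))
  expect_identical(simulate_crossovers("regular_placement", 50,
                                       mean_count = 3, seed = 1),
                   simulate_crossovers("regular", 50, mean_count = 3,
                                       seed = 1))
})

test_that("fixed and regular placements are exact constructions", {
  fx <- simulate_crossovers("fixed", 20, length_L = 8, seed = 42)
  expect_true(all(vapply(fx$positions, identical, logical(1), 4)))

  rg <- simulate_crossovers("regular", 500, mean_count = 3, seed = 43)
  expect_true(all(co_counts(rg) == 3L))
  gaps <- vapply(rg$positions, diff, numeric(2))
  expect_equal(as.vector(gaps), rep(1 / 3, 1000), tolerance = 1e-12)
  # first CO uniform on [0, L/N]
  firsts <- vapply(rg$positions, `[`, numeric(1), 1)
  expect_true(all(firsts >= 0 & firsts <= 1 / 3))
  expect_error(simulate_crossovers("regular", 10, mean_count = 2.5),
               "integer")
})

test_that("regular placement has a uniform marginal CO density", {
  rg <- simulate_crossovers("regular", 10000, mean_count = 3, seed = 44)
  pos <- unlist(rg$positions)
  ks <- suppressWarnings(ks.test(pos, "punif", 0, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("the Poisson null has Poisson count moments", {
  ds <- simulate_crossovers("poisson", 1e5, mean_count = 2, seed = 45)
  counts <- co_counts(ds)
  expect_equal(mean(counts), 2, tolerance = 0.02)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.02)
})

test_that("bimodal density concentrates COs at the chromosome ends", {
  ds <- simulate_crossovers("poisson", 5000, mean_count = 2,
                            position_density = "bimodal", seed = 46)
  pos <- unlist(ds$positions)
  expect_gt(mean(pos < 0.33 | pos > 0.67), 0.75)
  # custom density functions are accepted and validated
  ds2 <- simulate_crossovers("obligate", 100,
                             position_density = function(m) rep(0.5, m),
                             seed = 47)
  expect_true(all(unlist(ds2$positions) == 0.5))
  expect_error(simulate_crossovers("obligate", 10,
                                   position_density = function(m) {
                                     rep(2, m)
                                   }),
               "outside")
})

test_that("the stationary renewal process hits its target intensity", {
  ds <- simulate_crossovers("renewal", 20000, mean_count = 2, shape = 5,
                            seed = 48)
  expect_equal(mean(co_counts(ds)), 2, tolerance = 0.03)
  # shape 1 is the Poisson process: interference length vanishes
  ds1 <- simulate_crossovers("renewal", 50000, mean_count = 2, shape = 1,
                             seed = 49)
  counts <- co_counts(ds1)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.03)
  expect_lt(abs(lint_of(ds1)), 0.015)
})

test_that("binomial thinning behaves at the boundaries and in the mean", {
  ds <- simulate_crossovers("poisson", 10000, mean_count = 4, seed = 50)
  expect_identical(subsample_crossovers(ds, 1, seed = 1)$positions,
                   ds$positions)
  thin0 <- subsample_crossovers(ds, 0, seed = 1)
  expect_true(all(co_counts(thin0) == 0L))
  expect_length(thin0$positions, length(ds$positions))

  thin <- subsample_crossovers(ds, 0.5, seed = 51)
  expect_equal(mean(co_counts(thin)), 2, tolerance = 0.06)
  expect_error(subsample_crossovers(ds, 1.2), "probability")
  # determinism
  expect_identical(subsample_crossovers(ds, 0.5, seed = 52),
                   subsample_crossovers(ds, 0.5, seed = 52))
})

test_that("thinning keeps class labels attached to surviving COs", {
  ds <- chromosome_dataset(
    list(crossover_sample("a", c(0.1, 0.4, 0.8),
                          classes = c("I", "II", "I"))),
    length_L = 1)
  thin <- subsample_crossovers(ds, 0.5, seed = 53)
  keep <- thin$positions[[1]]
  expect_equal(thin$classes[[1]],
               ds$classes[[1]][match(keep, ds$positions[[1]])])
})
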