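test_that("CoC is flat near 1 without interference", {
  ds <- simulate_crossovers("poisson", 50000, mean_count = 2, seed = 31)
  cc <- coc_curve(ds, bin_count = 15)
  expect_length(cc$coc_values, 14)
  expect_true(all(abs(cc$coc_values - 1) < 0.15))
  expect_lt(abs(mean(cc$coc_values) - 1), 0.03)
  expect_identical(cc$d_coc, 0)  # curve starts above 0.5
})

test_that("one CO per sample yields zero coincidence everywhere", {
  ds <- simulate_crossovers("obligate", 2000, seed = 32)
  cc <- coc_curve(ds, bin_count = 10)
  expect_true(all(cc$coc_values == 0))
  expect_true(is.na(suppressWarnings(interference_distance(cc))))
  expect_warning(interference_distance(cc), "never reaches")
})

test_that("interference suppresses close double-COs in the CoC curve", {
  ds <- simulate_crossovers("renewal", 20000, mean_count = 2, shape = 5,
                            seed = 33)
  cc <- coc_curve(ds, bin_count = 15)
  expect_lt(cc$coc_values[1], 0.2)     # near 0 at short separation
  k <- length(cc$coc_values)
  expect_gt(mean(cc$coc_values[(k - 3):k]), 0.75)  # recovers toward 1
  expect_true(is.finite(cc$d_coc) && cc$d_coc > 0)
})

test_that("the 0.5-crossing is interpolated linearly", {
  mk <- function(s, v) structure(list(separations = s, coc_values = v,
                                      n_pairs = rep(1L, length(s)),
                                      bin_count = length(s) + 1L, L = 1,
                                      d_coc = NA_real_),
                                 class = "coc_curve")
  expect_equal(interference_distance(mk(c(0.1, 0.2), c(0.25, 0.75))),
               0.15)
  expect_identical(interference_distance(mk(c(0.1, 0.2), c(1, 1))), 0)
  expect_true(is.na(suppressWarnings(
    interference_distance(mk(c(0.1, 0.2), c(0.1, 0.2))))))
  expect_error(interference_distance(mk(numeric(), numeric())), "empty")
})

test_that("coc_curve validates its inputs", {
  ds <- simulate_crossovers("poisson", 100, mean_count = 2, seed = 34)
  expect_error(coc_curve(ds, bin_count = 1), ">= 2")
  empty <- chromosome_dataset(list(numeric(), numeric()), length_L = 1)
  expect_error(coc_curve(empty, 10), "no crossovers")
})

test_that("gamma fit recovers the shape of simulated adjacent distances", {
  set.seed(35)
  # exponential gaps: gamma with shape 1
  g1 <- gamma_shape(gaps_dataset(rexp(1e4, rate = 2)))
  expect_equal(g1$shape_nu, 1, tolerance = 0.1)
  expect_equal(g1$shape_nu * g1$scale, 0.5, tolerance = 0.05)  # mean gap

  g5 <- gamma_shape(gaps_dataset(rgamma(1e4, shape = 5, rate = 10)))
  expect_equal(g5$shape_nu, 5, tolerance = 0.3)

  expect_error(gamma_shape(gaps_dataset(rexp(9))), "insufficient data")
})

test_that("profile-likelihood gamma MLE agrees with MASS::fitdistr", {
  skip_if_not_installed("MASS")
  set.seed(36)
  x <- rgamma(500, shape = 3.2, rate = 4)
  ours <- gamma_shape(gaps_dataset(x))
  ref <- MASS::fitdistr(x, "gamma")
  expect_equal(ours$shape_nu, unname(ref$estimate["shape"]),
               tolerance = 1e-3)
  expect_equal(1 / ours$scale, unname(ref$estimate["rate"]),
               tolerance = 1e-3)
})

test_that("zero distances are jittered, constant distances refused", {
  ds <- gaps_dataset(c(rep(0, 5), rexp(20)))
  expect_silent(g <- gamma_shape(ds))
  expect_true(is.finite(g$shape_nu))
  expect_error(gamma_shape(gaps_dataset(rep(1, 20))), "constant")
})

test_that("interference-poor Poisson data fit a gamma shape near 1", {
  # denser simulation (mean count 6) keeps end-censoring bias small
  ds <- simulate_crossovers("poisson", 2500, mean_count = 6, seed = 37)
  g <- gamma_shape(ds)
  expect_gt(g$n_distances, 1e4)
  expect_equal(g$shape_nu, 1, tolerance = 0.15)
})

test_that("all three measures rank interference strengths identically", {
  shapes <- c(1, 3, 6, 10)
  lint <- dcoc <- nu <- numeric(length(shapes))
  for (i in seq_along(shapes)) {
    ds <- simulate_crossovers("renewal", 10000, mean_count = 5,
                              shape = shapes[i], seed = 380 + i)
    lint[i] <- lint_of(ds)
    cc <- coc_curve(ds, bin_count = 15)
    dcoc[i] <- if (is.na(cc$d_coc)) 0 else cc$d_coc
    nu[i] <- gamma_shape(ds)$shape_nu
  }
  expect_identical(order(lint), order(shapes))
  expect_identical(order(nu), order(shapes))
  # d_CoC is non-decreasing in the true interference strength
  expect_true(all(diff(dcoc) > -0.02))
  expect_gt(dcoc[4], dcoc[1])
})
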