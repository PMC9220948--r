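test_that("pair-distance density is a proper density on [0, 2R]", {
  for (R in c(1, 12.3, 1e3, 1e4)) { # 1 nm to 10 um
    expect_identical(pair_distance_pdf(-1, R), 0)
    expect_identical(pair_distance_pdf(2 * R, R), 0)
    expect_identical(pair_distance_pdf(2 * R + 1e-9 * R, R), 0)
    expect_true(all(pair_distance_pdf(seq(0, 2 * R, length.out = 101), R) >= 0))
    nrm <- expected_kernel_value(R, function(r) rep(1, length(r)))
    expect_lt(abs(nrm - 1), 1e-8)
  }
  expect_error(pair_distance_pdf(1, -2), "positive")
})

test_that("density obeys the scale covariance p(r; R) = p(r/R; 1)/R", {
  R <- 37.5
  r <- seq(0.01, 2 * R, length.out = 200)
  expect_equal(pair_distance_pdf(r, R), pair_distance_pdf(r / R, 1) / R,
    tolerance = 1e-12
  )
})

test_that("closed-form CDF matches cumulative integration of the density", {
  R <- 5
  r <- seq(0, 2 * R, length.out = 2001)
  dens <- ref_disk_pdf(r, R)
  cum <- c(0, cumsum(diff(r) * (utils::head(dens, -1) + utils::tail(dens, -1)) / 2))
  expect_equal(pair_distance_cdf(r, R), cum, tolerance = 1e-5)
  expect_equal(pair_distance_cdf(2 * R, R), 1, tolerance = 1e-12)
  expect_equal(pair_distance_cdf(0, R), 0, tolerance = 1e-12)
})

test_that("quadrature mean matches the closed form and the Monte-Carlo oracle", {
  R <- 20
  mean_quad <- expected_kernel_value(R, function(r) r)
  expect_equal(mean_quad, 128 * R / (45 * pi), tolerance = 1e-8)
  expect_equal(mean_quad, mean_pair_distance(R), tolerance = 1e-8)
  n <- 1e6
  d <- sample_pair_distances(R, n, seed = 7L)
  se <- stats::sd(d) / sqrt(n)
  expect_lt(abs(mean(d) - mean_quad), 3 * se)
})

test_that("kernel expectations reduce to known cases", {
  R <- 15
  expect_equal(
    expected_kernel_value(R, function(r) rep(2.5, length(r))), 2.5,
    tolerance = 1e-8
  )
  # the lower cutoff removes probability mass: constant kernel < 1
  expect_lt(expected_kernel_value(R, function(r) rep(1, length(r)), r_lo = 1), 1)
  expect_identical(expected_kernel_value(R, function(r) r, r_lo = 2 * R), 0)
})

test_that("singular r^-3 expectation is finite, cutoff-monotone and matches a dense grid", {
  R <- 50
  vals <- vapply(
    c(0.5, 1, 2, 4),
    function(d) expected_kernel_value(R, function(r) r^-3, r_lo = d),
    numeric(1)
  )
  expect_true(all(is.finite(vals)))
  expect_true(all(diff(vals) < 0)) # strictly decreasing in the cutoff
  # independent dense-grid trapezoid oracle
  d <- 1
  r <- exp(seq(log(d), log(2 * R), length.out = 2e5))
  brute <- trapz(r, ref_disk_pdf(r, R) * r^-3)
  expect_equal(vals[2], brute, tolerance = 1e-6)
  # without a cutoff the integral diverges and the quadrature must say so
  expect_error(expected_kernel_value(R, function(r) r^-3, r_lo = 0))
})

test_that("pair-distance sampling is seeded, bounded and distributed per the analytic CDF", {
  R <- 8
  d1 <- sample_pair_distances(R, 1e4, seed = 11L)
  d2 <- sample_pair_distances(R, 1e4, seed = 11L)
  expect_identical(d1, d2)
  expect_true(all(d1 >= 0 & d1 <= 2 * R))
  d3 <- sample_pair_distances(R, 1e4, seed = 12L)
  expect_false(identical(d1, d3))
  ks <- max(abs(stats::ecdf(d1)(sort(d1)) - pair_distance_cdf(sort(d1), R)))
  expect_lt(ks, 0.02) # 1e4 samples; the full 1e6-sample bound is asserted elsewhere
  expect_error(sample_pair_distances(R, 0), "positive")
})

test_that("sampling leaves the caller's RNG state untouched", {
  set.seed(999)
  before <- .Random.seed
  invisible(sample_pair_distances(5, 100, seed = 3L))
  expect_identical(.Random.seed, before)
})
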