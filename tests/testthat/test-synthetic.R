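test_that("noise-free observations all equal the model prediction", {
  p <- bilayer_params()
  obs <- generate_noisy_domain_observations(1, p, n = 8, noise_sd_log = 0, seed = 5L)
  expect_length(obs$radii_nm, 8)
  expect_true(all(obs$radii_nm == obs$R_star_nm))
})

test_that("radius generator is a pure function of its seed", {
  p <- bilayer_params()
  a <- generate_noisy_domain_observations(1, p, 20, 0.1, seed = 3L)
  b <- generate_noisy_domain_observations(1, p, 20, 0.1, seed = 3L)
  expect_identical(a$radii_nm, b$radii_nm)
  c <- generate_noisy_domain_observations(1, p, 20, 0.1, seed = 4L)
  expect_false(identical(a$radii_nm, c$radii_nm))
})

test_that("geometric mean of lognormal radii concentrates on the prediction", {
  p <- bilayer_params()
  sd_log <- 0.1
  n <- 1e4
  obs <- generate_noisy_domain_observations(1, p, n, sd_log, seed = 21L)
  gm <- exp(mean(log(obs$radii_nm)))
  expect_lt(abs(log(gm) - log(obs$R_star_nm)), 3 * sd_log / sqrt(n))
})

test_that("tension recovery round-trips exactly on noise-free data", {
  p <- bilayer_params()
  obs <- generate_noisy_domain_observations(0.9, p, n = 1, noise_sd_log = 0, seed = 2L)
  rec <- recover_line_tension_experiment(obs, n_boot = 20)
  expect_lt(abs(rec$sigma_hat_pN - 0.9) / 0.9, 0.01)
  expect_error(
    recover_line_tension_experiment(list(radii_nm = numeric(0))),
    "noisy_domain_observations"
  )
})

test_that("affinity generator is collinear without noise and seed-reproducible", {
  ds <- generate_affinity_dataset(n = 10, noise_sd = 0, seed = 9L)
  lk <- log10(ds$kd_M)
  expect_equal(ds$p_tcr, ds$intercept_tcr + ds$true_slope_tcr * lk,
    tolerance = 1e-12
  )
  ds2 <- generate_affinity_dataset(n = 10, noise_sd = 0, seed = 9L)
  expect_identical(ds$kd_M, ds2$kd_M)
  ds3 <- generate_affinity_dataset(n = 10, noise_sd = 0, seed = 10L)
  expect_false(identical(ds$kd_M, ds3$kd_M))
  expect_true(all(ds$kd_M >= 1e-9 & ds$kd_M <= 1e-5))
  expect_error(generate_affinity_dataset(n = 2), "at least 3")
  expect_error(generate_affinity_dataset(kd_range_M = c(1e-5, 1e-9)), "increasing")
})

test_that("response fits recover the generating slopes and sign pattern", {
  ds <- generate_affinity_dataset(n = 24, noise_sd = 0, seed = 1L)
  fit <- fit_affinity_response(ds)
  expect_equal(fit$tcr$slope, ds$true_slope_tcr, tolerance = 1e-10)
  expect_equal(fit$stat5$slope, ds$true_slope_stat5, tolerance = 1e-10)
  expect_equal(fit$tcr$r_squared, 1, tolerance = 1e-10)
  # phospho-TCR rises and phospho-STAT5 falls as affinity rises (Kd falls)
  expect_true(fit$sign_tcr_negative)
  expect_true(fit$sign_stat5_positive)
  expect_true(fit$sign_pattern_matches)
})

test_that("fits reject degenerate affinity panels", {
  ds <- generate_affinity_dataset(n = 5, seed = 1L)
  ds$kd_M <- rep(1e-8, 5)
  expect_error(fit_affinity_response(ds), "zero variance")
})

test_that("shuffled responses show no spurious affinity relation", {
  set.seed(77)
  r2 <- replicate(100, {
    ds <- generate_affinity_dataset(
      n = 200, noise_sd = 8,
      seed = sample.int(1e6, 1)
    )
    ds$p_tcr <- sample(ds$p_tcr)
    fit_affinity_response(ds)$tcr$r_squared
  })
  expect_gte(mean(r2 < 0.05), 0.95)
})

test_that("serialised datasets round-trip through CSV plus sidecar", {
  ds <- generate_affinity_dataset(n = 6, seed = 13L)
  path <- file.path(tempdir(), "affinity_test.csv")
  write_affinity_dataset(ds, path)
  back <- utils::read.csv(path)
  expect_equal(back$kd_M, ds$kd_M, tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(side$seed, 13L)
  expect_identical(side$n, 6L)
  unlink(c(path, paste0(path, ".json")))
})
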