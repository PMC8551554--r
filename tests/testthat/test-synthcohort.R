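test_that("expected_plv matches an independent Bessel series oracle", {
  for (k in c(0.5, 1, 2, 5, 10))
    expect_equal(expected_plv(k), bessel_ratio_oracle(k), tolerance = 1e-10)
  expect_identical(expected_plv(0), 0)
  ## large-kappa asymptotic branch: locking limit
  expect_gt(expected_plv(1e6), 1 - 1e-6)
  expect_lt(expected_plv(1e6), 1)
  expect_error(expected_plv(-1), "kappa")
})

test_that("simulation specs validate their inputs", {
  expect_error(simulation_spec(duration = 5, seed = 1), ">= 10")
  expect_error(simulation_spec(duration = -1, seed = 1), "positive")
  expect_error(simulation_spec(duration = 20, seed = 1,
                               coupling = data.frame(i = 1, j = 2,
                                                     band = "beta2",
                                                     kappa = -1)),
               "kappa")
  expect_error(simulation_spec(duration = 20, seed = 1,
                               coupling = data.frame(i = 1, j = 1,
                                                     band = "beta2",
                                                     kappa = 2)),
               "distinct")
  ## non-star coupling (triangle without a common reference) is rejected
  tri <- data.frame(i = c(1, 2), j = c(2, 3), band = "beta2", kappa = 2)
  expect_error(simulate_coupled_sources(
    simulation_spec(n_regions = 4, duration = 10, fs = 200, coupling = tri,
                    seed = 1)),
    "star")
})

test_that("same seed gives bit-identical sources, different seeds differ", {
  a <- tiny_sources(seed = 7)$sources
  b <- tiny_sources(seed = 7)$sources
  c <- tiny_sources(seed = 8)$sources
  expect_identical(a$data, b$data)
  expect_false(isTRUE(all.equal(a$data, c$data)))
})

test_that("ground truth records the closed-form PLV for coupled pairs", {
  cp <- data.frame(i = c(1, 1), j = c(2, 3), band = "beta2", kappa = c(2, 5))
  gt <- tiny_sources(coupling = cp, seed = 2)$ground_truth
  tab <- gt$expected_plv
  expect_equal(tab$expected_plv[tab$i == 1 & tab$j == 2], expected_plv(2))
  expect_equal(tab$expected_plv[tab$i == 1 & tab$j == 3], expected_plv(5))
  ## leaf-leaf pair: product of the two Bessel ratios
  expect_equal(tab$expected_plv[tab$i == 2 & tab$j == 3],
               expected_plv(2) * expected_plv(5))
})

test_that("toy lead field is deterministic, full rank, and well formed", {
  lf1 <- make_toy_lead_field(32, 68, seed = 3)
  lf2 <- make_toy_lead_field(32, 68, seed = 3)
  expect_identical(lf1$gain, lf2$gain)
  expect_equal(dim(lf1$gain), c(32L, 68L))
  expect_true(all(colSums(abs(lf1$gain)) > 0))
  ## rank via independent SVD check
  expect_equal(sum(svd(lf1$gain)$d > 1e-10), 32)
  sq <- make_toy_lead_field(68, 68, seed = 1)
  expect_equal(sum(svd(sq$gain)$d > 1e-10 * svd(sq$gain)$d[1]), 68)
  expect_error(make_toy_lead_field(2, 68), "n_sensors")
})

test_that("sensor projection is linear and reproduces the covariance", {
  sim <- tiny_sources(n_regions = 8, seed = 5)
  lf <- make_toy_lead_field(12, 8, seed = 1)
  rec <- project_to_sensors(sim$sources, lf, sensor_noise_sd = 0)
  ## noiseless: sensor covariance equals G Cov(src) G' (direct matrix oracle)
  cs <- stats::cov(t(sim$sources$data))
  expect_equal(unname(stats::cov(t(rec$data))), lf$gain %*% cs %*% t(lf$gain),
               tolerance = 1e-8)
  ## doubling all gains doubles the sensor amplitudes
  lf2 <- lf; lf2$gain <- 2 * lf$gain
  rec2 <- project_to_sensors(sim$sources, lf2, sensor_noise_sd = 0)
  expect_equal(rec2$data, 2 * rec$data)
  ## identity gain passes sources through unchanged
  lfi <- lf
  lfi$gain <- diag(8); lfi$sensor_labels <- sprintf("S%03d", 1:8)
  lfi$sensor_positions <- lf$sensor_positions[1:8, ]
  expect_equal(unname(project_to_sensors(sim$sources, lfi)$data),
               unname(sim$sources$data))
  expect_error(project_to_sensors(sim$sources, make_toy_lead_field(12, 9)),
               "mismatch")
})

test_that("group study enforces the paired design and group sizes", {
  specs <- default_study_specs(duration = 10, fs = 200, n_regions = 12, seed = 1)
  expect_error(simulate_group_study(specs$hc, specs$pd_off, specs$pd_on,
                                    n_hc = 1, n_pd = 4), ">= 2")
  bad_on <- specs$pd_on; bad_on$seed <- bad_on$seed + 1L
  expect_error(simulate_group_study(specs$hc, specs$pd_off, bad_on,
                                    n_hc = 2, n_pd = 2), "share the same seed")
  st <- simulate_group_study(specs$hc, specs$pd_off, specs$pd_on,
                             n_hc = 2, n_pd = 3)
  expect_length(st$hc, 2)
  expect_length(st$pd_off, 3)
  ## identical specs for both groups: all planted effect ratios are 1
  st0 <- simulate_group_study(specs$hc, specs$hc, specs$hc, n_hc = 2, n_pd = 2)
  expect_true(all(st0$ground_truth$expected_band_power_ratio == 1))
  ## paired background sharing: OFF and ON differ only through the planted
  ## coupling, so uncoupled regions are bit-identical across conditions
  planted_regions <- unique(as.vector(specs$planted_edges))
  off1 <- st$pd_off[[1]]$data
  on1 <- st$pd_on[[1]]$data
  untouched <- setdiff(seq_len(12), planted_regions)
  expect_identical(off1[untouched, ], on1[untouched, ])
  expect_false(isTRUE(all.equal(off1[planted_regions[2], ],
                                on1[planted_regions[2], ])))
})

test_that("planted theta amplitude gain realizes the squared power ratio", {
  ## power scales with amplitude^2: planted 1.5x amplitude => ratio 2.25
  specs <- default_study_specs(duration = 60, fs = 200, seed = 11)
  n <- 12
  pow <- function(spec, k) {
    s <- spec
    s$seed <- eegsourcenet:::derive_seed(spec$seed, paste0("subject:", k))
    src <- simulate_coupled_sources(s)$sources
    mean(band_power(welch_psd(src$data, src$fs), "theta"))
  }
  hc <- vapply(seq_len(n), function(k) pow(specs$hc, k), numeric(1))
  pd <- vapply(seq_len(n), function(k) pow(specs$pd_off, k), numeric(1))
  ratio <- mean(pd) / mean(hc)
  expect_gt(ratio, 2.25 * 0.9)
  expect_lt(ratio, 2.25 * 1.1)
})

test_that("cohorts round-trip through the TSV + JSON container", {
  specs <- default_study_specs(duration = 10, fs = 200, n_regions = 12, seed = 3)
  st <- simulate_group_study(specs$hc, specs$pd_off, specs$pd_on,
                             n_hc = 2, n_pd = 2)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(st, dir)
  expect_equal(nrow(manifest), 6)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_subject(file.path(dir, manifest$file[1]))
  expect_equal(unname(back$data), unname(st$hc[[1]]$data), tolerance = 1e-12)
  expect_equal(back$fs, 200)
})
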