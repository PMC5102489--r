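test_that("layer generation is deterministic in the seed and respects invariants", {
  a <- generate_layers(1, 64, 64)
  b <- generate_layers(1, 64, 64)
  expect_identical(a, b)
  c <- generate_layers(2, 64, 64)
  expect_false(identical(a$continuous$rainfall, c$continuous$rainfall))

  expect_true(all(a$continuous$footprint[a$valid] >= 0))
  expect_true(all(a$sampling <= a$valid))  # sampling subset of valid
  for (nm in names(a$categorical))
    expect_true(all(a$categorical[[nm]] %in%
                      attr(a$categorical[[nm]], "classes")))
  expect_error(generate_layers(1, 8, 8), "16")
})

test_that("continuous layers are spatially autocorrelated (neighbor-pair oracle)", {
  st <- generate_layers(7, 128, 128)
  r <- st$continuous$rainfall
  # brute-force lag-1 neighbor correlation, horizontal and vertical pairs
  horiz <- cor(as.numeric(r[, -ncol(r)]), as.numeric(r[, -1]))
  vert <- cor(as.numeric(r[-nrow(r), ]), as.numeric(r[-1, ]))
  expect_gt(horiz, 0.5)
  expect_gt(vert, 0.5)
})

test_that("sightings are proportional to suitability, one record per cell", {
  st <- tiny_stack(n = 16)
  flat <- matrix(0.5, 16, 16)
  truth_u <- truth_model(st, suitability = flat)
  # n = all valid cells -> every cell exactly once
  all_cells <- generate_sightings(st, truth_u, sum(st$valid), bias = FALSE,
                                  seed = 1)
  expect_setequal(all_cells$cell, valid_cells(st))
  expect_error(generate_sightings(st, truth_u, sum(st$valid) + 1,
                                  bias = FALSE, seed = 1), "infeasible")

  # two-level suitability: high half 0.8, low half 0.2
  st2 <- tiny_stack(n = 64)
  suit <- matrix(0.2, 64, 64)
  suit[, 33:64] <- 0.8
  truth_2 <- truth_model(st2, suitability = suit)
  set.seed(42)
  share <- replicate(500, {
    s <- generate_sightings(st2, truth_2, 100, bias = FALSE)
    mean(s$col > 32)
  })
  # weighted-sampling expectation: 0.8 of draws from the high half
  expect_lt(abs(mean(share) - 0.8), 0.01)
})

test_that("camera-trap simulator hits its analytic detection expectation", {
  st <- grid_stations()
  # saturated detection: centres on stations, g0 ~ 1, sigma huge -> everyone
  # seen every occasion (at the nearest station at least)
  tr_hi <- truth_model(tiny_stack(), n_population = 20, g0 = 0.9999,
                       sigma_km = 1e4, het_sd = 0)
  ctr <- data.frame(x_km = rep_len(st$x_km, 20),
                    y_km = rep_len(st$y_km, 20))
  sim <- simulate_cmr(tr_hi, st, occasions = 5, seed = 3, centres = ctr)
  eh <- build_encounter_history(sim$detections, 1, total_nights = 5)
  expect_equal(nrow(eh$X), 20)
  expect_true(all(eh$X == 1))

  # zero detection -> empty record set
  tr_0 <- truth_model(tiny_stack(), n_population = 20, g0 = 0,
                      sigma_km = 2, het_sd = 0)
  expect_equal(nrow(simulate_cmr(tr_0, st, 5, seed = 3)$detections), 0)
  expect_error(truth_model(tiny_stack(), g0 = 0.5, sigma_km = -1), "sigma")

  # analytic expectation of distinct individuals observed
  tr <- truth_model(tiny_stack(), n_population = 60, g0 = 0.3,
                    sigma_km = 2, het_sd = 0)
  t_occ <- 10
  obs <- exp_an <- numeric(200)
  for (r in seq_len(200)) {
    sim <- simulate_cmr(tr, st, t_occ, seed = 100 + r)
    obs[r] <- length(unique(sim$detections$individual))
    d2 <- outer(sim$individuals$x_km, st$x_km, "-")^2 +
      outer(sim$individuals$y_km, st$y_km, "-")^2
    p <- tr$g0 * exp(-d2 / (2 * tr$sigma_km^2))
    exp_an[r] <- sum(1 - apply((1 - p)^t_occ, 1, prod))
  }
  mc_se <- sd(obs - exp_an) / sqrt(200)
  expect_lt(abs(mean(obs) - mean(exp_an)), 3 * mc_se + 1e-9)
})

test_that("transect counts follow the Poisson log-rate model", {
  st <- tiny_stack(n = 16)
  # flat footprint effect: b = 0, a = log(0.5), L = 100 -> mean 50
  sp <- data.frame(species = "x", guild = "mammal", mass_kg = 1,
                   gregarious = FALSE, group_lambda = 0,
                   a = log(0.5), b = 0)
  tr <- truth_model(st, species = sp)
  set.seed(1)
  counts <- replicate(500, {
    s <- simulate_transects(st, tr, sites = 1, km_per_site = 100, km_sd = 0)
    nrow(s$contacts)
  })
  expect_lt(abs(mean(counts) - 50), 3 * sqrt(50 / 500))

  # zero effort -> zero contacts
  s0 <- simulate_transects(st, tr, sites = 5, km_per_site = 0, km_sd = 0,
                           seed = 1)
  expect_equal(nrow(s0$contacts), 0)

  # contacts carry positions within [0, L]
  s1 <- simulate_transects(st, tr, sites = 3, km_per_site = 50, seed = 2)
  expect_true(all(s1$contacts$km_position >= 0 &
                    s1$contacts$km_position <= s1$contacts$total_km))
})

test_that("raster round-trips through the ASCII grid format", {
  m <- matrix(rnorm(30), 5, 6)
  m[2, 3] <- NA
  f <- tempfile(fileext = ".asc")
  write_asc(m, f, cell_km = 0.5)
  back <- read_asc(f)
  expect_equal(back$mat, unname(m), tolerance = 1e-6)
  expect_equal(back$cell_km, 0.5)
  unlink(f)
})
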