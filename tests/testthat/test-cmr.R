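test_that("encounter histories group nights into occasions correctly", {
  det <- data.frame(individual = 1, station = "S1",
                    night = seq(1, 90, by = 1))
  eh <- build_encounter_history(det, 9, total_nights = 90)
  expect_equal(eh$occasions, 10)
  expect_equal(as.integer(eh$X[1, ]), rep(1L, 10))

  # hand-built toy: 7 detections, 3 individuals, 4 occasions of 2 nights
  toy <- data.frame(
    individual = c("A", "A", "B", "B", "C", "C", "A"),
    station = "S1",
    night = c(1, 4, 2, 8, 3, 5, 6))
  eh2 <- build_encounter_history(toy, 2, total_nights = 8)
  truth <- rbind(A = c(1, 1, 1, 0), B = c(1, 0, 0, 1), C = c(0, 1, 1, 0))
  expect_equal(eh2$X, truth)

  st <- grid_stations()
  bad <- data.frame(individual = 1, station = "NOPE", night = 1)
  expect_error(build_encounter_history(bad, 1, stations = st), "station")
})

test_that("M0 estimator matches the brute-force likelihood grid search", {
  # boundary: everyone captured on every occasion
  X_all <- matrix(1L, 5, 3)
  est <- estimate_m0(X_all)
  expect_equal(est$N_hat, 5)
  expect_equal(est$p_hat, 1)
  expect_true(est$boundary)

  # t = 2, n1 = 10, n2 = 8, overlap 4 (Lincoln-Petersen value 20)
  X <- rbind(matrix(rep(c(1, 1), 4), ncol = 2, byrow = TRUE),
             matrix(rep(c(1, 0), 6), ncol = 2, byrow = TRUE),
             matrix(rep(c(0, 1), 4), ncol = 2, byrow = TRUE))
  est2 <- estimate_m0(X)
  expect_lt(abs(est2$N_hat - m0_grid_oracle(X)), 1)
  expect_lt(abs(est2$N_hat - 20), 2)

  # property: continuous MLE agrees with integer grid search whenever
  # M_{t+1} <= 30, and never drops below M_{t+1}
  set.seed(21)
  for (k in 1:15) {
    X <- sim_history(sample(8:30, 1), runif(1, 0.15, 0.5), sample(3:8, 1))
    if (nrow(X) < 2 || sum(X) == length(X)) next
    g <- m0_grid_oracle(X, n_max = 2000)
    if (g >= 1999) next
    est <- estimate_m0(X)
    expect_gte(est$N_hat, nrow(X))
    expect_lt(abs(est$N_hat - g), 1)
  }
})

test_that("Mh jackknife reproduces the published closed forms", {
  # f1 = 0 collapses the first-order estimator to M_{t+1}
  X <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))  # everyone caught twice
  est <- estimate_mh_jackknife(X, max_order = 1)
  expect_equal(est$N_hat, 3)

  # t = 5, f = (4, 3, 2, 0, 0): frozen values from the published
  # coefficient table evaluated by hand at t = 5
  X2 <- rbind(
    matrix(rep(c(1, 0, 0, 0, 0), 4), ncol = 5, byrow = TRUE),
    matrix(rep(c(1, 1, 0, 0, 0), 3), ncol = 5, byrow = TRUE),
    matrix(rep(c(1, 1, 1, 0, 0), 2), ncol = 5, byrow = TRUE))
  expect_equal(capture_freq_oracle(X2), c(4, 3, 2, 0, 0))
  est2 <- estimate_mh_jackknife(X2)
  expect_equal(est2$orders$N_hat[1], 12.2)              # 9 + (4/5)*4
  expect_equal(est2$orders$N_hat[2], 13.25)
  expect_equal(est2$orders$N_hat[3], 13.6166667, tolerance = 1e-6)
  expect_equal(est2$orders$N_hat[4], 13.75)
  expect_equal(est2$orders$se[1], 2.4)                  # sqrt(5.76)
  # sequential test: first increment not significant -> order 1 selected
  expect_equal(est2$order, 1)
  expect_equal(est2$N_hat, 12.2)
  expect_gte(est2$N_hat, est2$M)
})

test_that("MMDM follows the multi-station exclusion rule", {
  # all single-station individuals: undefined
  det1 <- data.frame(individual = c(1, 1, 2), station = c("A", "A", "B"),
                     x_km = c(0, 0, 3), y_km = c(0, 0, 0))
  expect_error(compute_mmdm(det1), "undefined MMDM")

  # two qualifying individuals with maxima 6 and 8 km -> 7 km
  det2 <- data.frame(
    individual = c(1, 1, 2, 2, 3),
    station = c("A", "B", "C", "D", "E"),
    x_km = c(0, 6, 0, 8, 99), y_km = 0)
  expect_equal(as.numeric(compute_mmdm(det2)), 7)
  expect_equal(attr(compute_mmdm(det2), "n_individuals"), 2)

  # all-pairs oracle on a synthetic constellation
  set.seed(3)
  det3 <- data.frame(individual = rep(1:5, each = 4),
                     station = paste0("S", 1:20),
                     x_km = runif(20, 0, 10), y_km = runif(20, 0, 10))
  oracle <- mean(vapply(split(det3, det3$individual), function(d) {
    mx <- 0
    for (i in 1:(nrow(d) - 1)) for (j in (i + 1):nrow(d))
      mx <- max(mx, sqrt((d$x_km[i] - d$x_km[j])^2 +
                           (d$y_km[i] - d$y_km[j])^2))
    mx
  }, 0.0))
  expect_equal(as.numeric(compute_mmdm(det3)), oracle)
})

test_that("effective area matches closed-form and rasterized dilation", {
  sq <- data.frame(x_km = c(0, 10, 10, 0), y_km = c(0, 0, 10, 10))
  expect_equal(effective_area(sq, 0), 100)
  for (b in c(0.5, 2, 3.7))
    expect_equal(effective_area(sq, b), 100 + 40 * b + pi * b^2,
                 tolerance = 1e-6 / 100)

  expect_error(effective_area(sq[1:2, ], 1), "degenerate")
  coll <- data.frame(x_km = c(0, 1, 2), y_km = c(0, 1, 2))
  expect_error(effective_area(coll, 1), "degenerate")

  # rasterization oracle: random 12-station set, 3.3-km buffer
  set.seed(14)
  stn <- data.frame(x_km = runif(12, 0, 10), y_km = runif(12, 0, 10))
  b <- 3.3
  area <- effective_area(stn, b)
  h <- 0.02
  hull <- stn[chull(stn$x_km, stn$y_km), ]
  gx <- seq(min(stn$x_km) - b - h, max(stn$x_km) + b + h, by = h)
  gy <- seq(min(stn$y_km) - b - h, max(stn$y_km) + b + h, by = h)
  pts <- expand.grid(x = gx, y = gy)
  # independent point-to-polygon distance: inside (mgcv) or near an edge
  inside <- mgcv::in.out(as.matrix(rbind(hull, hull[1, ])),
                         as.matrix(pts))
  seg_d <- rep(Inf, nrow(pts))
  nv <- nrow(hull)
  for (k in seq_len(nv)) {
    j <- if (k == nv) 1 else k + 1
    ex <- hull$x_km[j] - hull$x_km[k]; ey <- hull$y_km[j] - hull$y_km[k]
    tt <- pmin(1, pmax(0, ((pts$x - hull$x_km[k]) * ex +
                             (pts$y - hull$y_km[k]) * ey) / (ex^2 + ey^2)))
    seg_d <- pmin(seg_d, sqrt((pts$x - hull$x_km[k] - tt * ex)^2 +
                                (pts$y - hull$y_km[k] - tt * ey)^2))
  }
  rast_area <- sum(inside | seg_d <= b) * h^2
  expect_lt(abs(area - rast_area) / rast_area, 0.005)
})

test_that("density arithmetic and buffer monotonicity hold", {
  est <- structure(list(N_hat = 0, se = 0), class = "population_estimate")
  expect_equal(cmr_density(est, 100)$density, 0)

  est2 <- structure(list(N_hat = 10, se = 3), class = "population_estimate")
  d_half <- cmr_density(est2, effective_area(grid_stations(), 3.3))
  d_full <- cmr_density(est2, effective_area(grid_stations(), 6.6))
  expect_gt(d_half$density, d_full$density)
  expect_equal(d_half$density, 100 * 10 / d_half$area_km2)
  expect_equal(d_half$upper - d_half$lower, 100 * 6 / d_half$area_km2)
})

test_that("accumulation curves are monotone step series", {
  # first sightings on nights 1, 1, 5, 12
  det <- data.frame(individual = c(1, 2, 1, 3, 4),
                    station = "S1",
                    night = c(1, 1, 3, 5, 12))
  ac <- accumulation_curve(det, n_stations = 2)
  expect_equal(ac$individuals[c(1, 4, 5, 12)], c(2, 2, 3, 4))
  expect_equal(ac$station_nights, 2 * seq_len(12))
  expect_equal(attr(ac, "saturation_night"), 12)
  expect_true(all(diff(ac$individuals) >= 0))

  empty <- accumulation_curve(det[0, ])
  expect_equal(nrow(empty), 0)
})
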