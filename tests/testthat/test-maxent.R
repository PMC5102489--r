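test_that("feature construction counts and indicator sums are right", {
  st <- tiny_stack(n = 16)
  # continuous-only stack: 2 features per layer
  s1 <- layer_stack(continuous = st$continuous[c("rainfall", "altitude",
                                                 "dem", "agb")])
  expect_equal(build_features(s1)$n_features, 8)

  # constant layer dropped with a warning
  s2 <- layer_stack(continuous = list(rainfall = st$continuous$rainfall,
                                      flat = matrix(3, 16, 16)))
  expect_warning(sc2 <- build_features(s2), "constant")
  expect_equal(sc2$n_features, 2)

  # 2 continuous + 1 categorical with 5 classes -> 9 features, and each
  # indicator column sums to that class's cell count
  s3 <- layer_stack(continuous = st$continuous[c("rainfall", "altitude")],
                    categorical = st$categorical["geology"])
  sc3 <- build_features(s3)
  expect_equal(sc3$n_features, 4 + length(unique(as.vector(
    st$categorical$geology))))
  F <- feature_matrix(sc3, s3, valid_cells(s3))
  for (cl in sort(unique(as.vector(st$categorical$geology))))
    expect_equal(sum(F[, paste0("geology=", cl)]),
                 sum(st$categorical$geology == cl))
  expect_true(all(F[, 1:4] >= 0 & F[, 1:4] <= 1))
})

test_that("uniform presences with strong regularization give a flat model", {
  st <- tiny_stack(n = 24)
  sc <- build_features(st)
  vc <- valid_cells(st)
  F_bg <- feature_matrix(sc, st, vc)
  set.seed(5)
  F_pr <- F_bg[sample(nrow(F_bg), 200), ]
  ft <- fit_maxent(F_bg, F_pr, reg_multiplier = 50)
  kl <- sum(ft$raw * log(ft$raw * nrow(F_bg)))
  expect_lt(kl, 1e-3)
  expect_lt(max(abs(ft$lambda)), 0.1)
})

test_that("single-feature weight matches brute-force likelihood grid search", {
  set.seed(9)
  Fb <- matrix(rbinom(2000, 1, 0.5), ncol = 1)
  Fp <- matrix(rbinom(200, 1, 0.9), ncol = 1)
  ft <- fit_maxent(Fb, Fp, beta = 0, beta_floor = 0)
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, function(l)
    mean(Fp) * l - log(mean(exp(l * Fb[, 1]))), 0.0)
  expect_equal(unname(ft$lambda), grid[which.max(ll)], tolerance = 1e-3)
})

test_that("fit records the documented convergence settings and invariants", {
  st <- tiny_stack(n = 24)
  truth <- truth_model(st)
  sg <- generate_sightings(st, truth, 150, bias = FALSE, seed = 2)
  m <- fit_sdm(st, sg, bias = FALSE, bootstrap_reps = 0, seed = 3)
  expect_equal(m$settings$tol, 1e-5)
  expect_equal(m$settings$max_iter, 5000)
  expect_equal(m$settings$split, 0.75)
  expect_true(m$fit$converged)
  # raw distribution sums to 1 over background
  expect_lt(abs(sum(m$fit$raw) - 1), 1e-9)
  # KKT feature-expectation bounds at convergence
  F_bg <- feature_matrix(m$schema, st, m$background)
  e <- colSums(m$fit$raw * F_bg)
  expect_true(all(abs(e - m$fit$pbar) <= m$fit$beta + 1e-6))
})

test_that("logistic output is the entropy-anchored transform", {
  # synthetic fitted object exercising the algebra directly
  fake <- structure(list(lambda = c(f = 1), entropy = 2.3, log_z = 0.7),
                    class = "maxent_fit")
  # raw(x) = exp(-H) <=> eta - log_z = -H  =>  logistic = 0.5
  F_half <- matrix((0.7 - 2.3) / 1, 1, 1, dimnames = list(NULL, "f"))
  expect_equal(logistic_output(fake, F_half), 0.5)
  # raw -> 0  =>  logistic -> 0
  F_lo <- matrix(-60, 1, 1)
  expect_lt(logistic_output(fake, F_lo), 1e-20)
  # ranking by logistic equals ranking by raw on a real fitted model
  st <- tiny_stack(n = 24)
  m <- fit_sdm(st, generate_sightings(st, truth_model(st), 100,
                                      bias = FALSE, seed = 1),
               bias = FALSE, bootstrap_reps = 0, seed = 2)
  F <- feature_matrix(m$schema, st, sample(valid_cells(st), 50))
  raw_rank <- rank(as.numeric(F %*% m$fit$lambda))
  expect_equal(rank(logistic_output(m$fit, F)), raw_rank)
})

test_that("AUC equals exhaustive pair counting, with the tie convention", {
  expect_equal(evaluate_auc(c(3, 4), c(1, 2)), 1.0)
  expect_equal(evaluate_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  # worked example: 9 wins, no ties, 12 pairs
  p <- c(0.9, 0.7, 0.4); b <- c(0.8, 0.5, 0.3, 0.1)
  expect_equal(evaluate_auc(p, b), auc_pair_oracle(p, b))
  expect_equal(evaluate_auc(p, b), 9 / 12)
  # property: equality with the pair-count oracle on random inputs
  set.seed(11)
  for (k in 1:10) {
    p <- sample(seq(0, 1, 0.05), sample(3:80, 1), replace = TRUE)
    b <- sample(seq(0, 1, 0.05), sample(3:120, 1), replace = TRUE)
    expect_equal(evaluate_auc(p, b), auc_pair_oracle(p, b))
  }
})

test_that("null-model test flags a separable model and ranks the 95th null", {
  st <- tiny_stack(n = 24)
  nm <- null_model_test(st, 60, observed_auc = 1.0, seed = 4, reps = 99,
                        bias = FALSE)
  expect_equal(nm$n_fitted, 99)
  expect_false(nm$degraded)
  expect_true(nm$significant)
  expect_lte(nm$p_value, 0.01)
  expect_equal(nm$threshold, sort(nm$null_auc)[95])
})

test_that("jackknife importance ranks the true driver first", {
  st <- tiny_stack(n = 32)
  # truth driven by rainfall only
  tr <- truth_model(st, weights = c(rain = 2.5, rain2 = -1))
  sg <- generate_sightings(st, tr, 250, bias = FALSE, seed = 6)
  ji <- jackknife_importance(st, sg, bias = FALSE)
  expect_equal(ji$variable[which.max(ji$gain_alone)], "rainfall")

  # a duplicated variable leaves the without-gain at the full-model gain,
  # and a pure-noise variable alone has near-zero gain
  set.seed(8)
  noise <- matrix(rnorm(32 * 32), 32, 32)
  st2 <- layer_stack(continuous = list(rainfall = st$continuous$rainfall,
                                       rain_copy = st$continuous$rainfall,
                                       noise = noise))
  ji2 <- jackknife_importance(st2, sg, bias = FALSE)
  full_gain <- attr(ji2, "full_gain")
  wo_copy <- ji2$gain_without[ji2$variable == "rain_copy"]
  expect_lt(abs(wo_copy - full_gain), 0.05 * max(full_gain, 0.1))
  expect_lt(ji2$gain_alone[ji2$variable == "noise"], 0.05)
})

test_that("projection is exact on the training stack and robust off it", {
  st <- tiny_stack(n = 24)
  tr <- truth_model(st)
  m <- fit_sdm(st, generate_sightings(st, tr, 120, bias = FALSE, seed = 2),
               bias = FALSE, bootstrap_reps = 0, seed = 3)
  pr <- project_sdm(m, st)
  # training-background cells reproduce the fit's own logistic scores
  expect_equal(pr[m$background],
               logistic_output(m$fit, feature_matrix(m$schema, st,
                                                     m$background)))
  # all-masked stack -> empty raster, no error
  st_empty <- st
  st_empty$valid[] <- FALSE
  st_empty$sampling[] <- FALSE
  expect_true(all(is.na(project_sdm(m, st_empty))))
  # unseen categorical class: zero indicators, score finite, and equal to
  # a manual feature-vector evaluation
  st_new <- st
  st_new$categorical$geology[1, 1] <- 99
  attr(st_new$categorical$geology, "classes") <-
    c(attr(st$categorical$geology, "classes"), 99)
  pr_new <- project_sdm(m, st_new)
  expect_true(is.finite(pr_new[1, 1]))
  fv <- feature_matrix(m$schema, st_new, 1L)
  expect_equal(sum(fv[, grepl("^geology=", colnames(fv))]), 0)
  expect_equal(pr_new[1, 1], unname(logistic_output(m$fit, fv)))
})

test_that("projected suitability recovers a known truth surface", {
  st <- generate_layers(7, 64, 64, sampling_km = 1e6)
  truth <- truth_model(st)
  sg <- generate_sightings(st, truth, 300, bias = FALSE, seed = 2)
  m <- fit_sdm(st, sg, bias = FALSE, bootstrap_reps = 0, seed = 3)
  pr <- project_sdm(m, st)
  rho <- cor(pr[st$valid], truth$suitability[st$valid], method = "spearman")
  expect_gt(rho, 0.8)
})
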