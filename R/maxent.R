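# Presence-only maximum-entropy suitability modelling.
#
# The model is the Gibbs distribution raw(x) ~ exp(sum_j lambda_j f_j(x))
# over background cells whose feature expectations match the presence-sample
# means to within per-feature regularization bounds beta_j.  Fitting
# maximizes the beta-penalized presence log-likelihood (see src/maxent_cd.cpp
# for the optimizer).  Suitability is reported through the logistic
# transform with implicit prevalence 0.5.

#' Fit a regularized maxent model (matrix interface)
#'
#' @param F_bg numeric feature matrix over background cells (rows =
#'   background cells).
#' @param F_pres numeric feature matrix over presence cells.
#' @param reg_multiplier multiplier on the default regularization
#'   `beta_j = s_j / sqrt(m)` (presence-sample sd over presence count).
#' @param tol convergence threshold on the largest weight update (default
#'   1e-5).
#' @param max_iter iteration cap (default 5000).
#' @param beta optional explicit per-feature regularization vector,
#'   overriding the default.
#' @param beta_floor lower bound keeping every `beta_j` strictly positive
#'   for numerical stability (default 1e-6).
#' @return object of class `maxent_fit`: `lambda`, `entropy`, `log_z`,
#'   `raw` (probabilities over background, summing to 1), `beta`,
#'   `converged`, `iterations`, `final_delta`.
#' @export
fit_maxent <- function(F_bg, F_pres, reg_multiplier = 1, tol = 1e-5,
                       max_iter = 5000, beta = NULL, beta_floor = 1e-6) {
  stopifnot(is.matrix(F_bg), is.matrix(F_pres),
            ncol(F_bg) == ncol(F_pres))
  if (nrow(F_bg) < 2) stop("need at least 2 background cells")
  m <- nrow(F_pres)
  pbar <- colMeans(F_pres)
  if (is.null(beta)) {
    s <- apply(F_pres, 2, sd)
    beta <- reg_multiplier * s / sqrt(m)
  }
  beta <- pmax(beta, beta_floor)
  res <- maxent_fit_cpp(F_bg, pbar, beta, tol, as.integer(max_iter))
  structure(list(lambda = setNames(as.numeric(res$lambda), colnames(F_bg)),
                 entropy = res$entropy, log_z = res$log_z,
                 raw = as.numeric(res$raw), beta = beta, pbar = pbar,
                 tol = tol, max_iter = max_iter,
                 converged = res$converged, iterations = res$iterations,
                 final_delta = res$final_delta),
            class = "maxent_fit")
}

#' Logistic suitability from a fitted maxent model
#'
#' `logistic(x) = e^H raw(x) / (1 + e^H raw(x))`, with `H` the entropy of
#' the fitted raw distribution — strictly increasing in `raw(x)` and equal
#' to 0.5 at a cell of typical (entropy-level) suitability.
#'
#' @param fit a [fit_maxent()] object.
#' @param F optional feature matrix of cells to score; default scores the
#'   background cells of the fit.
#' @return suitability values in `[0, 1]`.
#' @export
logistic_output <- function(fit, F = NULL) {
  if (!inherits(fit, "maxent_fit")) stop("state error: model not fitted")
  log_raw <- if (is.null(F)) log(pmax(fit$raw, 1e-300)) else
    as.numeric(F %*% fit$lambda) - fit$log_z
  plogis(fit$entropy + log_raw)
}

#' Rank-based AUC of presence vs background scores
#'
#' The probability that a randomly chosen test presence outscores a randomly
#' chosen background cell, ties counted 1/2 — the normalized Mann-Whitney
#' statistic.
#'
#' @param presence_scores scores of test presences (>= 1).
#' @param background_scores scores of background cells (>= 2).
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np < 1) stop("no data: empty test set")
  if (nb < 2) stop("need at least 2 background cells")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Fit the full presence-only suitability model for a landscape
#'
#' High-level wrapper: builds features, selects the background (the sampling
#' mask when `bias = TRUE`, operationalizing training restricted to the
#' surveyed areas; all cells when `<= background_max`, else a seeded uniform
#' subsample of `background_n`), splits presences 75/25 into training and
#' test, fits the regularized maxent model (optionally averaging bootstrap
#' replicates that resample training presences with replacement), and
#' evaluates the test AUC against the background.
#'
#' @param stack a [layer_stack()].
#' @param presences data.frame with a `cell` column (or `row`/`col`), one
#'   row per grid cell; >= 10 rows.
#' @param bias restrict the training background to the sampling mask?
#' @param reg_multiplier,tol,max_iter passed to [fit_maxent()].
#' @param split training fraction (default 0.75).
#' @param bootstrap_reps bootstrap replicates (default 10; 0 disables).
#' @param background_max,background_n background-size policy (see above).
#' @param seed integer seed controlling the split, the background subsample
#'   and the bootstrap.
#' @return object of class `sdm_model`: the main `fit`, `replicates`,
#'   `schema`, `background` cells, `train`/`test` presence cells, `auc`.
#' @export
fit_sdm <- function(stack, presences, bias = TRUE, reg_multiplier = 1,
                    tol = 1e-5, max_iter = 5000, split = 0.75,
                    bootstrap_reps = 10, background_max = 20000,
                    background_n = 10000, seed = NULL) {
  cells <- presence_cells(stack, presences)
  if (length(cells) < 10) stop("need at least 10 presence cells")
  mask_cells <- if (bias) sampling_cells(stack) else valid_cells(stack)
  if (!all(cells %in% valid_cells(stack)))
    stop("inconsistent input: presences outside the valid mask")
  schema <- build_features(stack)
  with_seed(seed, {
    background <- if (length(mask_cells) <= background_max) mask_cells else
      sort(sample(mask_cells, background_n))
    m <- length(cells)
    tr_idx <- sample(m, max(1, floor(split * m)))
    train <- cells[tr_idx]
    test <- if (length(tr_idx) < m) cells[-tr_idx] else cells[tr_idx]
    F_bg <- feature_matrix(schema, stack, background)
    F_tr <- feature_matrix(schema, stack, train)
    fit <- fit_maxent(F_bg, F_tr, reg_multiplier, tol, max_iter)
    reps <- list()
    if (bootstrap_reps > 0)
      reps <- lapply(seq_len(bootstrap_reps), function(b) {
        idx <- sample(length(train), replace = TRUE)
        fit_maxent(F_bg, F_tr[idx, , drop = FALSE],
                   reg_multiplier, tol, max_iter)
      })
    F_te <- feature_matrix(schema, stack, test)
    auc <- evaluate_auc(as.numeric(F_te %*% fit$lambda),
                        as.numeric(F_bg %*% fit$lambda))
    structure(list(fit = fit, replicates = reps, schema = schema,
                   background = background, train = train, test = test,
                   bias = bias, auc = auc,
                   settings = list(reg_multiplier = reg_multiplier,
                                   tol = tol, max_iter = max_iter,
                                   split = split,
                                   bootstrap_reps = bootstrap_reps)),
              class = "sdm_model")
  })
}

#' @export
print.sdm_model <- function(x, ...) {
  cat("sdm_model:", x$schema$n_features, "features,",
      length(x$train), "train /", length(x$test), "test presences,",
      length(x$background), "background cells\n")
  cat("  test AUC:", round(x$auc, 3),
      " converged:", x$fit$converged,
      " iterations:", x$fit$iterations, "\n")
  invisible(x)
}

presence_cells <- function(stack, presences) {
  if (is.numeric(presences) && is.null(dim(presences)))
    return(unique(as.integer(presences)))
  if (!is.null(presences$cell)) return(unique(as.integer(presences$cell)))
  if (!is.null(presences$row) && !is.null(presences$col))
    return(unique((presences$col - 1L) * stack$dims[1] + presences$row))
  if (!is.null(presences$x_km) && !is.null(presences$y_km)) {
    r <- pmin(stack$dims[1], pmax(1, ceiling(presences$y_km / stack$cell_km)))
    c <- pmin(stack$dims[2], pmax(1, ceiling(presences$x_km / stack$cell_km)))
    return(unique((c - 1L) * stack$dims[1] + r))
  }
  stop("presences must provide cell, row/col, or x_km/y_km")
}

#' Project suitability over a landscape
#'
#' Scores every valid cell of `stack` with the fitted model's logistic
#' output (mean over bootstrap replicates when present).  Categorical
#' classes unseen at training contribute zero indicators; continuous values
#' outside the training range are clamped to the rescaled `[0, 1]` bounds.
#'
#' @param model an [fit_sdm()] model.
#' @param stack a [layer_stack()] carrying the training layers.
#' @return matrix of suitability in `[0, 1]` (`NA` outside the valid mask).
#' @export
project_sdm <- function(model, stack) {
  vc <- valid_cells(stack)
  out <- matrix(NA_real_, stack$dims[1], stack$dims[2])
  if (length(vc) == 0) return(out)
  F <- feature_matrix(model$schema, stack, vc)
  fits <- if (length(model$replicates)) model$replicates else list(model$fit)
  sc <- rowMeans(vapply(fits, function(f) logistic_output(f, F),
                        numeric(nrow(F))))
  out[vc] <- sc
  out
}

#' Null-model significance test for presence-only model accuracy
#'
#' Fits `reps` (default 99) models to presences drawn uniformly at random
#' without replacement from the study mask, each evaluated exactly like the
#' observed model (same split, background, and settings), and compares the
#' observed AUC to the 95th-ranked null AUC: the model is significant at
#' p < 0.05 when it exceeds that order statistic.  The rank-based p-value
#' uses the +1 permutation convention, `p = (1 + #{null >= observed}) /
#' (reps + 1)`.
#'
#' @param stack a [layer_stack()].
#' @param n_presences number of random presences per replicate.
#' @param observed_auc AUC of the model under test.
#' @param seed integer seed.
#' @param reps null replicates (default 99).
#' @param bias,reg_multiplier,tol,max_iter,split as in [fit_sdm()].
#' @return object of class `null_model_result`: `observed_auc`, `null_auc`
#'   (length `reps`), `threshold` (95th-ranked null AUC for `reps = 99`),
#'   `significant`, `p_value`, `n_fitted`.
#' @export
null_model_test <- function(stack, n_presences, observed_auc, seed = NULL,
                            reps = 99, bias = TRUE, reg_multiplier = 1,
                            tol = 1e-5, max_iter = 5000, split = 0.75) {
  mask_cells <- if (bias) sampling_cells(stack) else valid_cells(stack)
  if (n_presences > length(mask_cells))
    stop("n_presences exceeds available cells")
  schema <- build_features(stack)
  background <- mask_cells  # nulls reuse the full mask as background
  F_bg <- feature_matrix(schema, stack, background)
  with_seed(seed, {
    null_auc <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      cells <- sample(mask_cells, n_presences)
      tr_idx <- sample(n_presences, max(1, floor(split * n_presences)))
      Fp <- feature_matrix(schema, stack, cells)
      ft <- try(fit_maxent(F_bg[, , drop = FALSE],
                           Fp[tr_idx, , drop = FALSE],
                           reg_multiplier, tol, max_iter), silent = TRUE)
      if (inherits(ft, "try-error")) next
      te <- if (length(tr_idx) < n_presences) setdiff(seq_len(n_presences),
                                                      tr_idx) else tr_idx
      null_auc[r] <- evaluate_auc(
        as.numeric(Fp[te, , drop = FALSE] %*% ft$lambda),
        as.numeric(F_bg %*% ft$lambda))
    }
    ok <- !is.na(null_auc)
    degraded <- sum(ok) < reps
    nulls <- sort(null_auc[ok])
    # threshold: 95th order statistic (1-based ascending) for 99 replicates
    k <- ceiling(0.95 * (length(nulls) + 1))
    threshold <- nulls[min(k, length(nulls))]
    structure(list(observed_auc = observed_auc, null_auc = null_auc,
                   threshold = threshold,
                   significant = observed_auc > threshold,
                   p_value = (1 + sum(nulls >= observed_auc)) /
                     (length(nulls) + 1),
                   n_fitted = sum(ok), degraded = degraded),
              class = "null_model_result")
  })
}

#' @export
print.null_model_result <- function(x, ...) {
  cat("null-model test:", x$n_fitted, "null fits\n")
  cat("  observed AUC:", round(x$observed_auc, 3),
      " threshold (95th null):", round(x$threshold, 3),
      " p:", round(x$p_value, 3),
      if (x$significant) " *significant*" else "", "\n")
  invisible(x)
}

#' Jackknife variable importance
#'
#' For each environmental variable, refits the model twice — once using only
#' that variable's features, once using all features except them — and
#' reports training gain (regularized log-likelihood above the uniform
#' log-likelihood, per presence) and AUC for each refit.
#'
#' @param stack a [layer_stack()].
#' @param presences presence specification as in [fit_sdm()].
#' @param bias,reg_multiplier,tol,max_iter as in [fit_sdm()].
#' @return data.frame with one row per variable: `gain_alone`,
#'   `gain_without`, `auc_alone`, `auc_without`, plus a `full_gain`
#'   attribute; `gain_without`/`auc_without` are `NA` (flagged) when only
#'   one variable is available.
#' @export
jackknife_importance <- function(stack, presences, bias = TRUE,
                                 reg_multiplier = 1, tol = 1e-5,
                                 max_iter = 5000) {
  cells <- presence_cells(stack, presences)
  schema <- build_features(stack)
  mask_cells <- if (bias) sampling_cells(stack) else valid_cells(stack)
  F_bg <- feature_matrix(schema, stack, mask_cells)
  F_pr <- feature_matrix(schema, stack, cells)
  fv <- feature_variable(schema)
  vars <- unique(fv)
  if (length(vars) < 2)
    warning("jackknife 'without' runs undefined for a single variable")
  uniform_ll <- -log(nrow(F_bg))
  gain_of <- function(cols) {
    ft <- fit_maxent(F_bg[, cols, drop = FALSE], F_pr[, cols, drop = FALSE],
                     reg_multiplier, tol, max_iter)
    ll <- sum(ft$pbar * ft$lambda) - ft$log_z -
      sum(ft$beta * abs(ft$lambda))
    list(gain = ll - uniform_ll,
         auc = evaluate_auc(
           as.numeric(F_pr[, cols, drop = FALSE] %*% ft$lambda),
           as.numeric(F_bg[, cols, drop = FALSE] %*% ft$lambda)))
  }
  full <- gain_of(seq_along(fv))
  out <- lapply(vars, function(v) {
    alone <- gain_of(which(fv == v))
    wo <- if (length(vars) >= 2) gain_of(which(fv != v)) else
      list(gain = NA_real_, auc = NA_real_)
    data.frame(variable = v, gain_alone = alone$gain,
               gain_without = wo$gain, auc_alone = alone$auc,
               auc_without = wo$auc)
  })
  out <- do.call(rbind, out)
  attr(out, "full_gain") <- full$gain
  attr(out, "full_auc") <- full$auc
  out
}
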