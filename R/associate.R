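# Cross-site association analyses: pairwise correlations with uncorrected
# p-values (the study's reporting convention) and an ensemble-regression
# (random forest) association between modelled suitability and
# habitat-structure variables scored by out-of-bag prediction correlation.

#' Pairwise correlation across sites
#'
#' Product-moment correlation (rank-based by option) with a two-sided
#' uncorrected p-value from the t reference distribution.  Incomplete pairs
#' are dropped and counted.
#'
#' @param x,y paired site values (>= 3 complete cases).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return object of class `association_result`: `r`, `p`, `n`,
#'   `n_dropped`, `method`.
#' @export
correlate_sites <- function(x, y, method = "pearson") {
  ok <- complete.cases(x, y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete cases")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- cor.test(x, y, method = method, exact = FALSE)
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 n_dropped = n_dropped, method = method,
                 tag = "pairwise-correlation"),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: r = %.3f, p(uncorr.) = %.4g, n = %d\n",
              x$tag, x$r, x$p, x$n))
  invisible(x)
}

#' Random-forest association between suitability and structure variables
#'
#' Fits a regression forest of the response on the site predictors and
#' scores the association as the correlation between out-of-bag predictions
#' and the observed response — an honest (internally cross-validated)
#' analogue of a multivariate r.  Categorical predictors are passed as
#' factors.  Deterministic given `seed` and `trees`.
#'
#' @param response numeric response per site (e.g. modelled suitability).
#' @param predictors data.frame of per-site structure variables (>= 1
#'   column; >= 10 sites).
#' @param seed integer seed.
#' @param trees number of trees (default 500).
#' @return `association_result` with the fitted forest attached as
#'   `forest` and OOB predictions as `oob`.
#' @export
rf_association <- function(response, predictors, seed = NULL, trees = 500) {
  stopifnot(is.data.frame(predictors), ncol(predictors) >= 1)
  ok <- complete.cases(predictors) & is.finite(response)
  response <- response[ok]
  predictors <- predictors[ok, , drop = FALSE]
  if (length(response) < 10) stop("need at least 10 sites")
  if (ncol(predictors) > length(response))
    warning("degraded fit: more predictors than sites")
  for (nm in names(predictors))
    if (is.character(predictors[[nm]]) || is.logical(predictors[[nm]]))
      predictors[[nm]] <- factor(predictors[[nm]])
  with_seed(seed, {
    rf <- randomForest::randomForest(x = predictors, y = response,
                                     ntree = trees)
    oob <- rf$predicted
    r <- if (sd(oob) == 0) 0 else cor(oob, response)
    n <- length(response)
    tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
    structure(list(r = r, p = 2 * stats::pt(-abs(tt), n - 2), n = n,
                   n_dropped = sum(!ok), method = "rf-oob",
                   tag = "ensemble-regression", forest = rf, oob = oob),
              class = "association_result")
  })
}

#' Conservation-priority overlay mask
#'
#' Boolean raster of cells that combine a low human footprint with high
#' canopy roughness: `HFI < hfi_cut` AND `roughness > rough_cut`.  The
#' default cuts (15 and 12) are the thresholds below/above which most prey
#' populations are maintained.
#'
#' @param footprint,roughness aligned matrices.
#' @param hfi_cut footprint threshold (default 15).
#' @param rough_cut roughness threshold (default 12).
#' @param valid optional validity mask.
#' @return logical matrix with attribute `fraction` (masked share of valid,
#'   non-NA cells).
#' @export
threshold_overlay <- function(footprint, roughness, hfi_cut = 15,
                              rough_cut = 12, valid = NULL) {
  if (!identical(dim(footprint), dim(roughness)))
    stop("inconsistent input: misaligned rasters")
  if (is.null(valid)) valid <- matrix(TRUE, nrow(footprint), ncol(footprint))
  if (!identical(dim(valid), dim(footprint)))
    stop("inconsistent input: misaligned validity mask")
  ok <- valid & is.finite(footprint) & is.finite(roughness)
  mask <- ok & (footprint < hfi_cut) & (roughness > rough_cut)
  attr(mask, "fraction") <- sum(mask) / max(sum(ok), 1)
  mask
}
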