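#' Build the maxent feature schema from a layer stack
#'
#' Continuous layers are rescaled to `[0, 1]` over valid cells and contribute
#' a linear and a quadratic feature each; categorical layers contribute one
#' 0/1 indicator feature per observed class.  Layers that are constant over
#' the valid region carry no information and are dropped with a warning, so
#' no all-constant feature is retained.
#'
#' @param stack a [layer_stack()].
#' @return an object of class `feature_schema` holding the rescaling ranges,
#'   observed classes, and feature names.
#' @export
build_features <- function(stack) {
  vc <- valid_cells(stack)
  if (length(vc) == 0) stop("no data: empty valid mask")
  cont <- list(); cat_ <- list(); nms <- character(0)
  for (nm in names(stack$continuous)) {
    v <- stack$continuous[[nm]][vc]
    lo <- min(v); hi <- max(v)
    if (hi - lo <= 0) {
      warning("dropping constant continuous layer '", nm, "'")
      next
    }
    cont[[nm]] <- c(lo = lo, hi = hi)
    nms <- c(nms, nm, paste0(nm, "^2"))
  }
  for (nm in names(stack$categorical)) {
    cl <- sort(unique(stack$categorical[[nm]][vc]))
    cl <- cl[is.finite(cl)]
    if (length(cl) < 2) {
      warning("dropping single-class categorical layer '", nm, "'")
      next
    }
    cat_[[nm]] <- cl
    nms <- c(nms, paste0(nm, "=", cl))
  }
  if (length(nms) == 0) stop("no usable features")
  structure(list(continuous = cont, categorical = cat_,
                 feature_names = nms, n_features = length(nms)),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("feature_schema:", x$n_features, "features\n ",
      paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the feature matrix for a set of cells
#'
#' Applies the schema's rescaling (clamped to `[0, 1]` for values outside the
#' training range) and class indicators (classes unseen at training map to
#' all-zero indicators) to arbitrary cells of a compatible stack.
#'
#' @param schema a [build_features()] schema.
#' @param stack a [layer_stack()] carrying the schema's layers.
#' @param cells linear cell indices.
#' @return numeric matrix `length(cells)` x `n_features`.
#' @export
feature_matrix <- function(schema, stack, cells) {
  miss <- setdiff(c(names(schema$continuous), names(schema$categorical)),
                  c(names(stack$continuous), names(stack$categorical)))
  if (length(miss))
    stop("inconsistent input: stack lacks layer(s) ",
         paste(miss, collapse = ", "))
  out <- matrix(0, length(cells), schema$n_features,
                dimnames = list(NULL, schema$feature_names))
  j <- 1L
  for (nm in names(schema$continuous)) {
    r <- schema$continuous[[nm]]
    z <- (stack$continuous[[nm]][cells] - r["lo"]) / (r["hi"] - r["lo"])
    z <- pmin(1, pmax(0, z))
    out[, j] <- z; out[, j + 1L] <- z^2
    j <- j + 2L
  }
  for (nm in names(schema$categorical)) {
    v <- stack$categorical[[nm]][cells]
    for (cl in schema$categorical[[nm]]) {
      out[, j] <- as.numeric(v == cl)
      j <- j + 1L
    }
  }
  out
}

# Layer of origin for each feature (used by the jackknife).
feature_variable <- function(schema) {
  v <- character(0)
  for (nm in names(schema$continuous)) v <- c(v, nm, nm)
  for (nm in names(schema$categorical))
    v <- c(v, rep(nm, length(schema$categorical[[nm]])))
  v
}
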