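# Closed-population capture-recapture density estimation from camera traps.
#
# Individual detections (photo-identified animals at georeferenced stations
# over nights) are collapsed into an individuals x occasions encounter
# history; population size is estimated under constant detection (M0, joint
# MLE) or individual heterogeneity (Mh, Burnham-Overton jackknife); the
# effective survey area is the station minimum convex polygon buffered by
# 1/2 MMDM or MMDM (mean maximum distance moved among individuals
# photographed at more than one station), and density is animals per
# 100 km^2.

#' Build an encounter history from detection records
#'
#' Nights are grouped into consecutive occasions of
#' `occasion_length_nights` (the last occasion may be shorter);
#' `X[i, o] = 1` iff individual `i` was detected during occasion `o`.
#'
#' @param detections data.frame with `individual`, `station`, `night`;
#'   optionally `x_km`, `y_km` per detection.
#' @param occasion_length_nights nights per occasion (>= 1).
#' @param total_nights survey length in nights (default: max observed
#'   night).
#' @param stations optional data.frame (`station_id`, `x_km`, `y_km`); when
#'   given, every detection must reference a known station.
#' @return object of class `encounter_history`: binary matrix `X`,
#'   `detections`, `stations`, `occasion_length`.
#' @export
build_encounter_history <- function(detections, occasion_length_nights,
                                    total_nights = NULL, stations = NULL) {
  stopifnot(occasion_length_nights >= 1)
  if (!is.null(stations) &&
      !all(detections$station %in% stations$station_id))
    stop("inconsistent input: detection references unknown station")
  total_nights <- total_nights %||%
    (if (nrow(detections)) max(detections$night) else occasion_length_nights)
  t <- ceiling(total_nights / occasion_length_nights)
  ids <- sort(unique(detections$individual))
  X <- matrix(0L, length(ids), t,
              dimnames = list(as.character(ids), NULL))
  if (nrow(detections)) {
    occ <- pmin(t, ceiling(detections$night / occasion_length_nights))
    for (k in seq_len(nrow(detections)))
      X[as.character(detections$individual[k]), occ[k]] <- 1L
  }
  structure(list(X = X, detections = detections, stations = stations,
                 occasion_length = occasion_length_nights,
                 occasions = t),
            class = "encounter_history")
}

capture_frequencies <- function(X) {
  t <- ncol(X)
  counts <- rowSums(X)
  vapply(seq_len(t), function(k) sum(counts == k), 0)
}

m0_loglik <- function(N, M, n_tot, t) {
  if (N < M) return(-Inf)
  p <- n_tot / (t * N)
  if (p <= 0 || p >= 1) {
    if (p == 1 && N == M) return(lgamma(N + 1) - lgamma(N - M + 1))
    return(-Inf)
  }
  lgamma(N + 1) - lgamma(N - M + 1) + n_tot * log(p) +
    (t * N - n_tot) * log(1 - p)
}

#' M0 (constant detection probability) population estimate
#'
#' Joint maximum-likelihood estimate of `(N, p)` under the null closed-
#' population model — every individual shares the same per-occasion
#' detection probability — with `N` relaxed to the reals and the profile
#' `p = total captures / (t N)`.  The asymptotic SE comes from the observed
#' information at the maximum.
#'
#' @param X binary individuals x occasions matrix (or an
#'   [build_encounter_history()] object).
#' @return object of class `population_estimate`: `estimator`, `N_hat`,
#'   `se`, `p_hat`, `M` (distinct animals), `f` (capture frequencies),
#'   `occasions`, `boundary`.
#' @export
estimate_m0 <- function(X) {
  if (inherits(X, "encounter_history")) X <- X$X
  t <- ncol(X); M <- nrow(X)
  stopifnot(t >= 2, M >= 1)
  n_tot <- sum(X)
  boundary <- n_tot == M * t
  if (boundary) {
    N_hat <- M; p_hat <- 1; se <- 0
  } else {
    # expand the search interval until the maximum is interior (the MLE can
    # be very large when recaptures are scarce)
    upper <- max(10 * M, M + 200)
    repeat {
      opt <- optimize(function(N) m0_loglik(N, M, n_tot, t),
                      interval = c(M, upper), maximum = TRUE, tol = 1e-8)
      if (opt$maximum < 0.99 * upper || upper >= 1e7) break
      upper <- upper * 10
    }
    N_hat <- opt$maximum
    p_hat <- n_tot / (t * N_hat)
    # observed information via finite differences on (N, p)
    ll <- function(N, p) {
      if (N < M || p <= 0 || p >= 1) return(-Inf)
      lgamma(N + 1) - lgamma(N - M + 1) + n_tot * log(p) +
        (t * N - n_tot) * log(1 - p)
    }
    h <- c(1e-3 * max(1, N_hat), 1e-5)
    H <- matrix(NA_real_, 2, 2)
    f0 <- ll(N_hat, p_hat)
    H[1, 1] <- (ll(N_hat + h[1], p_hat) - 2 * f0 + ll(N_hat - h[1], p_hat)) / h[1]^2
    H[2, 2] <- (ll(N_hat, p_hat + h[2]) - 2 * f0 + ll(N_hat, p_hat - h[2])) / h[2]^2
    H[1, 2] <- H[2, 1] <-
      (ll(N_hat + h[1], p_hat + h[2]) - ll(N_hat + h[1], p_hat - h[2]) -
       ll(N_hat - h[1], p_hat + h[2]) + ll(N_hat - h[1], p_hat - h[2])) /
      (4 * h[1] * h[2])
    V <- try(solve(-H), silent = TRUE)
    se <- if (inherits(V, "try-error") || is.na(V[1, 1]) || V[1, 1] < 0)
      NA_real_ else sqrt(V[1, 1])
  }
  structure(list(estimator = "M0", N_hat = N_hat, se = se, p_hat = p_hat,
                 M = M, f = capture_frequencies(X), occasions = t,
                 boundary = boundary),
            class = "population_estimate")
}

# Burnham-Overton jackknife coefficients c_{ik} for orders k = 1..5:
# N_Jk = S + sum_i c_{ik} f_i  (equivalently N_Jk = sum_i a_{ik} f_i with
# a_{ik} = 1 + c_{ik}).
jackknife_coefficients <- function(t, k) {
  c_ <- numeric(t)
  if (k == 1) {
    c_[1] <- (t - 1) / t
  } else if (k == 2) {
    c_[1] <- (2 * t - 3) / t
    c_[2] <- -(t - 2)^2 / (t * (t - 1))
  } else if (k == 3) {
    c_[1] <- (3 * t - 6) / t
    c_[2] <- -(3 * t^2 - 15 * t + 19) / (t * (t - 1))
    c_[3] <- (t - 3)^3 / (t * (t - 1) * (t - 2))
  } else if (k == 4) {
    c_[1] <- (4 * t - 10) / t
    c_[2] <- -(6 * t^2 - 36 * t + 55) / (t * (t - 1))
    c_[3] <- (4 * t^3 - 42 * t^2 + 148 * t - 175) / (t * (t - 1) * (t - 2))
    c_[4] <- -(t - 4)^4 / (t * (t - 1) * (t - 2) * (t - 3))
  } else if (k == 5) {
    c_[1] <- (5 * t - 15) / t
    c_[2] <- -(10 * t^2 - 70 * t + 125) / (t * (t - 1))
    c_[3] <- (10 * t^3 - 120 * t^2 + 485 * t - 660) /
      (t * (t - 1) * (t - 2))
    c_[4] <- -((t - 4)^5 - (t - 5)^5) / (t * (t - 1) * (t - 2) * (t - 3))
    c_[5] <- (t - 5)^5 / (t * (t - 1) * (t - 2) * (t - 3) * (t - 4))
  } else stop("jackknife order must be 1..5")
  c_
}

#' Mh jackknife population estimate (Burnham-Overton)
#'
#' Computes the jackknife estimators `N_Jk`, `k = 1..min(max_order, t-1)`,
#' from the capture frequencies under individual detection heterogeneity,
#' with `var(N_Jk) = sum_i a_ik^2 f_i - N_Jk`.  The reported order is
#' chosen by the standard sequential test on successive differences
#' `N_J(k+1) - N_Jk` (normal test at `alpha`): the first order whose
#' increment is no longer significant, the highest order if all increments
#' are significant, and order 1 if none is.
#'
#' @param X binary matrix or [build_encounter_history()] object.
#' @param max_order highest jackknife order considered (default 5).
#' @param alpha significance level of the sequential test (default 0.05).
#' @return `population_estimate` with fields `orders` (per-order `N_hat`,
#'   `se`) and the selected order's estimate.
#' @export
estimate_mh_jackknife <- function(X, max_order = 5, alpha = 0.05) {
  if (inherits(X, "encounter_history")) X <- X$X
  t <- ncol(X)
  stopifnot(t >= 2)
  f <- capture_frequencies(X)
  S <- sum(f)
  if (S == 0) stop("no data: empty capture-frequency vector")
  kmax <- min(max_order, t - 1)
  A <- sapply(seq_len(kmax), function(k) 1 + jackknife_coefficients(t, k))
  A <- matrix(A, nrow = t)
  N_k <- as.numeric(t(A) %*% f)
  var_k <- as.numeric(t(A^2) %*% f) - N_k
  se_k <- sqrt(pmax(var_k, 0))
  # sequential test on successive differences
  selected <- kmax
  tests <- rep(NA_real_, max(kmax - 1, 0))
  if (kmax >= 2 && S > 1) {
    for (k in seq_len(kmax - 1)) {
      b <- A[, k + 1] - A[, k]
      vd <- (S / (S - 1)) * (sum(b^2 * f) - (sum(b * f))^2 / S)
      z <- if (vd > 0) (N_k[k + 1] - N_k[k]) / sqrt(vd) else 0
      tests[k] <- 2 * pnorm(-abs(z))
      if (tests[k] > alpha) { selected <- k; break }
    }
  } else selected <- kmax
  structure(list(estimator = paste0("Mh-jackknife-", selected),
                 N_hat = N_k[selected], se = se_k[selected],
                 M = S, f = f, occasions = t, order = selected,
                 orders = data.frame(order = seq_len(kmax), N_hat = N_k,
                                     se = se_k),
                 tests = tests),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(x$estimator, ": N =", round(x$N_hat, 1), "(SE",
      round(x$se, 1), "),", x$M, "distinct animals over", x$occasions,
      "occasions\n")
  invisible(x)
}

#' Mean maximum distance moved (MMDM)
#'
#' For each individual photographed at two or more distinct stations, the
#' maximum pairwise Euclidean distance among its stations; MMDM is the mean
#' over those individuals.  Individuals seen at a single station carry no
#' movement information and are excluded; if no individual qualifies the
#' MMDM is undefined and an error is raised (density cannot proceed).
#'
#' @param detections data.frame with `individual`, `station`, `x_km`,
#'   `y_km`.
#' @return MMDM in km, with attribute `n_individuals`.
#' @export
compute_mmdm <- function(detections) {
  if (is.null(detections$x_km) || is.null(detections$y_km))
    stop("station coordinates required")
  per_ind <- split(detections, detections$individual)
  dmax <- vapply(per_ind, function(d) {
    st <- unique(d[, c("station", "x_km", "y_km")])
    if (nrow(st) < 2) return(NA_real_)
    max(dist(st[, c("x_km", "y_km")]))
  }, 0.0)
  dmax <- dmax[!is.na(dmax)]
  if (length(dmax) == 0)
    stop("undefined MMDM: no individual detected at more than one station")
  structure(mean(dmax), n_individuals = length(dmax))
}

#' Effective survey area: buffered minimum convex polygon
#'
#' Area of the station minimum convex polygon dilated by `buffer_km`.  For
#' a convex polygon the dilation is exact in closed form:
#' `A + P b + pi b^2` (polygon area plus perimeter strip plus corner
#' sectors).
#'
#' @param stations data.frame with `x_km`, `y_km` (>= 3 non-collinear).
#' @param buffer_km buffer radius in km (>= 0).
#' @return area in km^2.
#' @export
effective_area <- function(stations, buffer_km) {
  stopifnot(buffer_km >= 0)
  if (nrow(stations) < 3) stop("degenerate geometry: need >= 3 stations")
  h <- chull(stations$x_km, stations$y_km)
  if (length(h) < 3) stop("degenerate geometry: collinear stations")
  x <- stations$x_km[h]; y <- stations$y_km[h]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  area <- abs(sum(x[j] * y - x * y[j])) / 2
  if (area <= 0) stop("degenerate geometry: collinear stations")
  perim <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  area + perim * buffer_km + pi * buffer_km^2
}

#' Density from a population estimate and an effective area
#'
#' `D = 100 N / A` animals per 100 km^2, with the interval
#' `100 (N +/- SE) / A` propagated from the abundance SE.
#'
#' @param est a `population_estimate`.
#' @param area_km2 effective survey area (> 0).
#' @param buffer label for the buffer kind (e.g. `"half-MMDM"`).
#' @return object of class `density_estimate`: `density` (animals /
#'   100 km^2), `lower`, `upper`, `area_km2`, `N_hat`, `buffer`.
#' @export
cmr_density <- function(est, area_km2, buffer = NA_character_) {
  stopifnot(area_km2 > 0)
  N <- if (inherits(est, "population_estimate")) est$N_hat else est
  se <- if (inherits(est, "population_estimate")) est$se else 0
  structure(list(density = 100 * N / area_km2,
                 lower = 100 * (N - se) / area_km2,
                 upper = 100 * (N + se) / area_km2,
                 area_km2 = area_km2, N_hat = N, se = se, buffer = buffer),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("density: %s animals/100 km2 (SE %s-%s) over %.0f km2 [%s]\n",
              format(round_half_away(x$density, 1)),
              format(round_half_away(x$lower, 1)),
              format(round_half_away(x$upper, 1)),
              x$area_km2, x$buffer %||% "?"))
  invisible(x)
}

#' Round half away from zero
#'
#' Reporting convention for density tables (3.25 -> 3.3), unlike R's
#' banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Individual accumulation curve
#'
#' Step series of the cumulative number of distinct individuals against
#' cumulative station-nights, used to judge when a survey has detected all
#' resident animals.
#'
#' @param detections data.frame with `individual`, `night`.
#' @param n_stations number of active stations per night (default: distinct
#'   stations in `detections`).
#' @return data.frame `night`, `station_nights`, `individuals`; attribute
#'   `saturation_night` is the first night after which no new individual
#'   appears.
#' @export
accumulation_curve <- function(detections, n_stations = NULL) {
  if (nrow(detections) == 0)
    return(data.frame(night = integer(0), station_nights = numeric(0),
                      individuals = integer(0)))
  n_stations <- n_stations %||% length(unique(detections$station))
  first <- tapply(detections$night, detections$individual, min)
  nights <- seq_len(max(detections$night))
  cum <- vapply(nights, function(n) sum(first <= n), 0L)
  out <- data.frame(night = nights, station_nights = nights * n_stations,
                    individuals = cum)
  attr(out, "saturation_night") <- max(first)
  out
}
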