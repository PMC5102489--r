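# Habitat-structure proxies from remote sensing: focal-window canopy
# roughness from a DEM, waveform extent from large-footprint LiDAR returns,
# and per-site structure summaries.

#' Focal-window roughness of a DEM
#'
#' Each interior cell receives the sample (n-1) standard deviation of its
#' `window` x `window` neighbourhood — the classic SRTM-derived proxy for
#' canopy roughness.  Border cells (no full window) are `NA`; the result is
#' invariant to adding a constant to the DEM.
#'
#' @param dem numeric matrix (>= `window` in both dimensions).
#' @param window odd window edge length (default 3).
#' @return matrix of the same dimensions.
#' @export
focal_roughness <- function(dem, window = 3) {
  if (length(window) != 1 || window %% 2 != 1 || window < 3)
    stop("invalid argument: window must be an odd square size >= 3")
  if (nrow(dem) < window || ncol(dem) < window)
    stop("DEM smaller than the focal window")
  h <- (window - 1) / 2
  n <- window^2
  s <- s2 <- matrix(0, nrow(dem), ncol(dem))
  for (dr in -h:h) for (dc in -h:h) {
    sh <- shift_matrix(dem, dr, dc)
    s <- s + sh
    s2 <- s2 + sh^2
  }
  v <- (s2 - s^2 / n) / (n - 1)
  out <- sqrt(pmax(v, 0))
  out[c(seq_len(h), nrow(out) - seq_len(h) + 1), ] <- NA
  out[, c(seq_len(h), ncol(out) - seq_len(h) + 1)] <- NA
  out
}

# Shift a matrix by (dr, dc), padding with NA; NA cells poison the window
# sums so partial windows at the border come out NA automatically.
shift_matrix <- function(m, dr, dc) {
  out <- matrix(NA_real_, nrow(m), ncol(m))
  r_src <- seq_len(nrow(m)) + dr
  c_src <- seq_len(ncol(m)) + dc
  ok_r <- r_src >= 1 & r_src <= nrow(m)
  ok_c <- c_src >= 1 & c_src <= ncol(m)
  out[ok_r, ok_c] <- m[r_src[ok_r], c_src[ok_c]]
  out
}

#' Waveform extent of a LiDAR return
#'
#' Signal begin and end are the first and last samples whose intensity
#' exceeds `noise mean + k * noise sd`, both estimated from the waveform
#' tails (the leading and trailing `tail_frac` of samples, assumed to be
#' pure noise); the extent is the elevation difference between them —
#' vegetation height combined with slope-induced spread.  Invariant to
#' uniform intensity scaling.
#'
#' @param elevation_m elevation of each sample (m), any order but regular.
#' @param intensity return intensity per sample (>= 10 samples).
#' @param k noise-threshold multiplier (default 3).
#' @param tail_frac fraction of samples at each tail used to estimate the
#'   noise floor (default 0.1).
#' @return extent in m, with attributes `begin_m` and `end_m`.
#' @export
waveform_extent <- function(elevation_m, intensity, k = 3, tail_frac = 0.1) {
  stopifnot(length(elevation_m) == length(intensity))
  if (length(intensity) < 10) stop("need at least 10 waveform samples")
  ord <- order(elevation_m)
  e <- elevation_m[ord]; y <- intensity[ord]
  nt <- max(2, floor(tail_frac * length(y)))
  noise <- c(head(y, nt), tail(y, nt))
  thr <- mean(noise) + k * sd(noise)
  above <- which(y > thr)
  if (length(above) == 0) stop("no signal above the noise threshold")
  begin <- e[max(above)]  # signal begin = highest elevation crossing
  end <- e[min(above)]
  structure(begin - end, begin_m = begin, end_m = end)
}

#' Summarize habitat structure over a site
#'
#' Aggregates raster layers and waveform footprints over a site polygon:
#' maximum canopy height, mean waveform extent, mean roughness, mean AGB,
#' modal geology class, mean footprint.  Missing layers yield missing
#' fields rather than failure.
#'
#' @param site_poly data.frame or list with `x_km`, `y_km` polygon
#'   vertices.
#' @param rasters named list of matrices (any of `canopy_height`,
#'   `roughness`, `agb`, `geology`, `footprint`, `suitability`).
#' @param cell_km raster cell size (km).
#' @param waveforms optional data.frame of per-footprint waveform extents
#'   with `x_km`, `y_km`, `extent_m`.
#' @param site_id site label.
#' @return one-row data.frame (class `site_structure`).
#' @export
summarize_site <- function(site_poly, rasters, cell_km = 0.5,
                           waveforms = NULL, site_id = NA) {
  ref <- rasters[[1]]
  nr <- nrow(ref); nc <- ncol(ref)
  cx <- (col(ref) - 0.5) * cell_km
  cy <- (row(ref) - 0.5) * cell_km
  inside <- dist_point_poly(as.numeric(cx), as.numeric(cy),
                            site_poly$x_km, site_poly$y_km) == 0
  if (!any(inside)) stop("no data: site does not intersect the raster")
  grab <- function(nm, fun) {
    if (is.null(rasters[[nm]])) return(NA_real_)
    v <- rasters[[nm]][inside]
    v <- v[is.finite(v)]
    if (length(v) == 0) return(NA_real_)
    fun(v)
  }
  modal <- function(v) as.numeric(names(which.max(table(v))))
  wf_mean <- NA_real_
  if (!is.null(waveforms) && nrow(waveforms)) {
    win <- dist_point_poly(waveforms$x_km, waveforms$y_km,
                           site_poly$x_km, site_poly$y_km) == 0
    if (any(win)) wf_mean <- mean(waveforms$extent_m[win])
  }
  out <- data.frame(
    site = site_id,
    n_cells = sum(inside),
    max_canopy_height = grab("canopy_height", max),
    mean_extent = wf_mean,
    mean_roughness = grab("roughness", mean),
    mean_agb = grab("agb", mean),
    modal_geology = grab("geology", modal),
    mean_footprint = grab("footprint", mean),
    mean_suitability = grab("suitability", mean))
  class(out) <- c("site_structure", class(out))
  out
}

#' Square site polygon around a point
#'
#' Convenience constructor for the usual survey-site geometry: an
#' axis-aligned square of side `side_km` centred on (`x_km`, `y_km`).
#'
#' @param x_km,y_km centre coordinates (km).
#' @param side_km side length (km).
#' @return data.frame of 4 vertices.
#' @export
square_site <- function(x_km, y_km, side_km) {
  h <- side_km / 2
  data.frame(x_km = x_km + c(-h, h, h, -h),
             y_km = y_km + c(-h, -h, h, h))
}
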