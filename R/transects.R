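# Line-transect abundance: kilometric and biomass indices.
#
# The kilometric index (KI) is the raw encounter rate — contacts per km
# walked, or individuals per km for gregarious species (group sizes summed).
# The biomass index is KI x species mean adult mass (kg/km), additive over
# species for a community total.  No detection function is fitted: these are
# relative indices, not DISTANCE-style densities.

#' Kilometric abundance index
#'
#' @param contacts data.frame of contact events with `site`, `species`,
#'   `group_size`, `total_km` (as produced by [simulate_transects()] or
#'   read from a survey CSV).
#' @param traits data.frame with `species` and `gregarious` (and optionally
#'   `mass_kg`); every species in `contacts` must appear.
#' @param sites optional data.frame (`site`, `total_km`) declaring surveyed
#'   sites and effort, so sites or species with zero contacts get KI = 0.
#' @return data.frame `site`, `species`, `ki` (per km).
#' @export
kilometric_index <- function(contacts, traits, sites = NULL) {
  unknown <- setdiff(unique(contacts$species), traits$species)
  if (length(unknown))
    stop("missing trait for species: ", paste(unknown, collapse = ", "))
  if (is.null(sites)) {
    sites <- unique(contacts[, c("site", "total_km")])
  }
  if (any(sites$total_km <= 0)) stop("transect length must be > 0")
  grid <- expand.grid(site = sites$site, species = traits$species,
                      stringsAsFactors = FALSE)
  grid$total_km <- sites$total_km[match(grid$site, sites$site)]
  grid$gregarious <- traits$gregarious[match(grid$species, traits$species)]
  key <- function(s, sp) paste(s, sp, sep = "\r")
  cnt <- tapply(rep(1, nrow(contacts)),
                key(contacts$site, contacts$species), sum)
  ind <- tapply(contacts$group_size,
                key(contacts$site, contacts$species), sum)
  k <- key(grid$site, grid$species)
  n <- ifelse(grid$gregarious, ind[k], cnt[k])
  n[is.na(n)] <- 0
  data.frame(site = grid$site, species = grid$species,
             ki = n / grid$total_km)
}

#' Biomass index
#'
#' `B = KI x mean adult mass` per species (kg per km); the community
#' biomass is the sum over species.
#'
#' @param ki data.frame from [kilometric_index()] (columns `site`,
#'   `species`, `ki`).
#' @param traits data.frame with `species` and `mass_kg` (> 0).
#' @return `ki` with an added `biomass` column (kg/km).
#' @export
biomass_index <- function(ki, traits) {
  if (any(ki$ki < 0)) stop("invalid argument: negative KI")
  mass <- traits$mass_kg[match(ki$species, traits$species)]
  if (any(is.na(mass) | mass <= 0))
    stop("missing or non-positive adult mass")
  ki$biomass <- ki$ki * mass
  ki
}

#' Community (summed) index per site
#'
#' @param indexed data.frame with `site` and the column to sum.
#' @param value column name (`"ki"` or `"biomass"`).
#' @param species optional subset of species to include (e.g. one guild).
#' @return data.frame `site`, `total`.
#' @export
community_index <- function(indexed, value = "ki", species = NULL) {
  if (!is.null(species)) indexed <- indexed[indexed$species %in% species, ]
  agg <- tapply(indexed[[value]], indexed$site, sum)
  s <- names(agg)
  if (is.numeric(indexed$site)) s <- as.numeric(s)
  data.frame(site = s, total = as.numeric(agg))
}

#' Survey-effort sufficiency diagnostic
#'
#' For each truncation distance `d`, recomputes every survey's KI using only
#' the first `d` km of transect, and correlates the truncated KI with the
#' full-effort KI across surveys.  The returned curve `r(d)` quantifies how
#' much effort is needed before abundance ranking stabilizes; for
#' homogeneous Poisson encounters the expected correlation is
#' `sqrt(d / L)`.
#'
#' @param contacts data.frame with `site`, `species`, `km_position`,
#'   `group_size`, `total_km` (contact events carry their position along
#'   the transect).
#' @param sites data.frame (`site`, `total_km`), >= 10 surveys.
#' @param truncation_grid truncation distances (km).
#' @param species single species to assess, or `NULL` to pool all contacts.
#' @param gregarious sum group sizes instead of counting contacts.
#' @param threshold correlation defining "sufficient" effort (default 0.9).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame `d`, `r`; attributes `sufficient_d` (smallest `d`
#'   whose correlation reaches `threshold`) and `capped` (surveys shorter
#'   than a requested `d`, which use their full length).
#' @export
effort_sufficiency <- function(contacts, sites, truncation_grid,
                               species = NULL, gregarious = FALSE,
                               threshold = 0.9, method = "pearson") {
  if (nrow(sites) < 10) stop("need at least 10 surveys")
  if (!is.null(species)) contacts <- contacts[contacts$species %in% species, ]
  L <- sites$total_km
  ki_upto <- function(d) {
    eff <- pmin(d, L)
    n <- vapply(seq_len(nrow(sites)), function(i) {
      sel <- contacts$site == sites$site[i] & contacts$km_position <= eff[i]
      if (gregarious) sum(contacts$group_size[sel]) else sum(sel)
    }, 0.0)
    n / eff
  }
  full <- ki_upto(Inf)
  capped <- vapply(truncation_grid, function(d) sum(L < d), 0L)
  r <- vapply(truncation_grid, function(d) {
    kd <- ki_upto(d)
    if (sd(kd) == 0 || sd(full) == 0) return(NA_real_)
    cor(kd, full, method = method)
  }, 0.0)
  out <- data.frame(d = truncation_grid, r = r)
  ok <- which(!is.na(r) & r >= threshold)
  attr(out, "sufficient_d") <- if (length(ok)) truncation_grid[min(ok)] else
    NA_real_
  attr(out, "capped") <- capped
  out
}

#' Read a per-site survey table
#'
#' Reads the deposited site table (CSV export of the study's supplementary
#' site list, or any table with the same layout): one row per survey site
#' with a human-footprint column and one abundance (KI) column per species.
#'
#' @param path CSV path.
#' @param hfi_col name of the human-footprint column (default `"hfi"`).
#' @return data.frame.
#' @export
read_site_table <- function(path, hfi_col = "hfi") {
  if (!file.exists(path)) stop("site table not found: ", path)
  tab <- read.csv(path, check.names = FALSE)
  if (!hfi_col %in% names(tab))
    stop("site table lacks footprint column '", hfi_col, "'")
  tab
}

#' Prey-community vs footprint correlations from a site table
#'
#' Sums the per-species KI columns within each guild (mammals, birds) and
#' correlates the summed abundance with the human-footprint index across
#' sites, the cross-site association structure used to judge prey status.
#'
#' @param site_table data.frame with one row per site.
#' @param mammal_cols,bird_cols names of the per-species KI columns.
#' @param hfi_col human-footprint column name.
#' @param method correlation type (default product-moment).
#' @return data.frame with rows `mammals` and `birds`: `r`, `p`, `n`.
#' @export
site_prey_correlations <- function(site_table,
                                   mammal_cols, bird_cols,
                                   hfi_col = "hfi", method = "pearson") {
  sum_cols <- function(cols) rowSums(site_table[, cols, drop = FALSE])
  res <- lapply(list(mammals = mammal_cols, birds = bird_cols),
                function(cols) {
                  ct <- correlate_sites(sum_cols(cols), site_table[[hfi_col]],
                                        method = method)
                  data.frame(r = ct$r, p = ct$p, n = ct$n)
                })
  out <- do.call(rbind, res)
  out$guild <- rownames(out)
  out
}
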