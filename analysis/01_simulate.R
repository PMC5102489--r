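# Stage 1 — simulate the study system: a landscape with known suitability,
# presence-only sightings with geographic observation bias, two camera-trap
# surveys (low vs high suitability), 30 line-transect surveys, and LiDAR
# waveforms over the transect sites.

source("analysis/00_settings.R")

land <- make_landscape()
stack <- land$stack; truth <- land$truth
write_stack(stack, file.path(OUT, "layers"))
write_asc(truth$suitability, file.path(OUT, "true_suitability.asc"),
          stack$cell_km)

sightings <- generate_sightings(stack, truth, N_SIGHTINGS, bias = TRUE,
                                seed = stage_seed(MASTER_SEED, "sightings"))
write.csv(sightings, file.path(OUT, "sightings.csv"), row.names = FALSE)

for (nm in names(sites <- cmr_sites(stack, truth))) {
  s <- sites[[nm]]
  site_truth <- truth
  site_truth$n_population <- round(6 + 14 * truth$suitability[s$cell])
  sim <- simulate_cmr(site_truth, s$stations, CMR_OCCASIONS,
                      seed = stage_seed(MASTER_SEED, paste0("cmr_", nm)))
  write.csv(sim$detections, file.path(OUT, paste0("detections_", nm, ".csv")),
            row.names = FALSE)
  write.csv(s$stations, file.path(OUT, paste0("stations_", nm, ".csv")),
            row.names = FALSE)
  cat(sprintf("CMR site %-4s: true N = %d, detections = %d, animals seen = %d\n",
              nm, site_truth$n_population, nrow(sim$detections),
              length(unique(sim$detections$individual))))
}

tr <- simulate_transects(stack, truth, N_TRANSECT_SITES, KM_PER_SITE,
                         seed = stage_seed(MASTER_SEED, "transects"))
write.csv(tr$contacts, file.path(OUT, "transect_contacts.csv"),
          row.names = FALSE)
write.csv(tr$sites, file.path(OUT, "transect_sites.csv"), row.names = FALSE)
cat(sprintf("transects: %d sites, %.0f km mean effort, %d contact events\n",
            nrow(tr$sites), mean(tr$sites$total_km), nrow(tr$contacts)))

# one LiDAR footprint per transect site; canopy height declines with the
# human footprint, jittered with the 3.6-m height-estimation noise
set.seed(stage_seed(MASTER_SEED, "waveforms"))
wf_rows <- lapply(seq_len(nrow(tr$sites)), function(i) {
  hfi <- tr$sites$hfi[i]
  h <- max(5, 35 - 0.8 * hfi + rnorm(1, 0, 3.6))
  wf <- simulate_waveform(h, slope_spread_m = runif(1, 2, 8))
  cc <- cell_coords(stack, tr$sites$cell[i])
  data.frame(footprint_id = i, site = tr$sites$site[i],
             x_km = cc$x_km, y_km = cc$y_km, true_height_m = h,
             extent_m = as.numeric(waveform_extent(wf$elevation_m,
                                                   wf$intensity)))
})
waveforms <- do.call(rbind, wf_rows)
write.csv(waveforms, file.path(OUT, "waveform_extents.csv"),
          row.names = FALSE)
cat(sprintf("waveforms: %d footprints, mean extent %.1f m\n",
            nrow(waveforms), mean(waveforms$extent_m)))
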