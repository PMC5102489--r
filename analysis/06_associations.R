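# Stage 6 — cross-site associations: guild abundance and biomass vs the
# human footprint, roughness vs footprint, the random-forest association
# between modelled suitability and habitat-structure variables, and the
# conservation-priority overlay (low footprint AND high roughness).

source("analysis/00_settings.R")

land <- make_landscape()
stack <- land$stack
guilds <- read.csv(file.path(OUT, "guild_indices.csv"))
struct <- read.csv(file.path(OUT, "site_structure.csv"))
rough <- read_asc(file.path(OUT, "roughness.asc"))$mat

pairs <- list(
  mammal_ki_vs_hfi = list(guilds$mammal_ki, guilds$hfi),
  bird_ki_vs_hfi = list(guilds$bird_ki, guilds$hfi),
  mammal_biomass_vs_hfi = list(guilds$mammal_biomass, guilds$hfi),
  bird_biomass_vs_hfi = list(guilds$bird_biomass, guilds$hfi),
  roughness_vs_hfi = list(struct$mean_roughness, struct$mean_footprint),
  bird_ki_vs_roughness = list(guilds$bird_ki, struct$mean_roughness))
assoc <- do.call(rbind, lapply(names(pairs), function(nm) {
  a <- correlate_sites(pairs[[nm]][[1]], pairs[[nm]][[2]])
  data.frame(pair = nm, r = round(a$r, 3), p = signif(a$p, 3), n = a$n,
             method = a$method)
}))

rf1 <- rf_association(struct$mean_suitability,
                      struct[, c("mean_roughness", "modal_geology")],
                      seed = stage_seed(MASTER_SEED, "rf1"))
rf2 <- rf_association(struct$mean_suitability,
                      struct[, c("mean_roughness", "modal_geology",
                                 "mean_extent", "mean_agb")],
                      seed = stage_seed(MASTER_SEED, "rf2"))
assoc <- rbind(assoc,
               data.frame(pair = "suitability_vs_structure_rf_base",
                          r = round(rf1$r, 3), p = signif(rf1$p, 3),
                          n = rf1$n, method = rf1$method),
               data.frame(pair = "suitability_vs_structure_rf_extended",
                          r = round(rf2$r, 3), p = signif(rf2$p, 3),
                          n = rf2$n, method = rf2$method))
write.csv(assoc, file.path(OUT, "associations.csv"), row.names = FALSE)
print(assoc, row.names = FALSE)

ov <- threshold_overlay(stack$continuous$footprint, rough,
                        hfi_cut = 15, rough_cut = 12, stack$valid)
write_asc(ov * 1, file.path(OUT, "priority_mask.asc"), stack$cell_km)
cat(sprintf("priority overlay (HFI < 15 & roughness > 12): %.1f%% of the landscape\n",
            100 * attr(ov, "fraction")))
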