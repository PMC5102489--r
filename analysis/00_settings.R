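# Shared settings for the analysis scripts.  Every script regenerates the
# same synthetic landscape deterministically from MASTER_SEED, so the
# scripts can be run independently (in order, since later ones read tables
# written by earlier ones).

library(oncatools)

MASTER_SEED <- 42
ROWS <- 64
COLS <- 64
N_SIGHTINGS <- 302   # presence records, one per 0.5-km unit
N_TRANSECT_SITES <- 30
KM_PER_SITE <- 97    # mean cumulative transect length per survey site
CMR_OCCASIONS <- 10

OUT <- "results/analysis"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

make_landscape <- function() {
  stack <- generate_layers(stage_seed(MASTER_SEED, "layers"), ROWS, COLS)
  truth <- truth_model(stack, n_population = 12, g0 = 0.35)
  list(stack = stack, truth = truth)
}

# two camera-trap survey sites: one in low-, one in high-suitability terrain
cmr_sites <- function(stack, truth) {
  vc <- valid_cells(stack)
  ord <- vc[order(truth$suitability[vc])]
  picks <- c(low = ord[ceiling(0.1 * length(ord))],
             high = ord[ceiling(0.95 * length(ord))])
  lapply(picks, function(cell) {
    cc <- cell_coords(stack, cell)
    g <- expand.grid(ix = 1:4, iy = 1:4)
    list(cell = cell,
         stations = data.frame(station_id = sprintf("S%02d", 1:16),
                               x_km = cc$x_km + (g$ix - 2.5) * 2.5,
                               y_km = cc$y_km + (g$iy - 2.5) * 2.5))
  })
}
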