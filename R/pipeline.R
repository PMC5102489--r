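# Reproducible end-to-end pipeline over a synthetic landscape: simulate ->
# suitability model -> camera-trap density -> transect indices -> habitat
# structure -> associations, with per-stage seeded RNG substreams, a
# line-oriented log, and a checksum manifest so identical configurations
# reproduce identical outputs.

#' Default pipeline configuration
#'
#' All tunables of the pipeline with their defaults: landscape size,
#' suitability-model settings (regularization multiplier 1, convergence
#' threshold 1e-5, iteration cap 5000, 99 null replicates, 75/25 split),
#' camera-trap settings (occasions, buffers), transect settings, and the
#' overlay cuts (footprint < 15, roughness > 12).
#'
#' @param seed master seed; every stage derives its own substream from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 42) {
  list(
    seed = seed,
    landscape = list(rows = 48, cols = 48, cell_km = 0.5),
    truth = list(n_population = 12, g0 = 0.35, sigma_km = 2, het_sd = 0.75),
    sdm = list(n_sightings = 302, bias = TRUE, reg_multiplier = 1,
               tol = 1e-5, max_iter = 5000, split = 0.75,
               bootstrap_reps = 10, null_reps = 99),
    cmr = list(n_sites = 2, n_stations = 16, spacing_km = 2.5,
               occasions = 10, buffers = c("half", "full")),
    transects = list(n_sites = 30, km_per_site = 97,
                     truncation_grid = seq(10, 90, by = 10)),
    overlay = list(hfi_cut = 15, rough_cut = 12))
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  merge_lists <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  merge_lists(base, config)
}

# Regular camera-trap grid centred on a landscape cell.
station_grid <- function(centre_x, centre_y, n_stations, spacing_km) {
  side <- ceiling(sqrt(n_stations))
  g <- expand.grid(ix = seq_len(side), iy = seq_len(side))[seq_len(n_stations), ]
  data.frame(station_id = sprintf("S%02d", seq_len(n_stations)),
             x_km = centre_x + (g$ix - (side + 1) / 2) * spacing_km,
             y_km = centre_y + (g$iy - (side + 1) / 2) * spacing_km)
}

#' Run the full pipeline
#'
#' Executes every stage on a synthetic landscape and writes all artifacts
#' (ASCII-grid rasters, CSV tables, a metrics JSON, a run log and a
#' checksum manifest) into `out_dir`.  Rerunning with an identical
#' configuration reproduces every deterministic output; any stage failure
#' aborts with the stage name after writing the partial manifest.
#'
#' @param config configuration list (see [default_config()]) or path to a
#'   YAML file with overrides.
#' @param out_dir output directory.
#' @return invisibly, the metrics list.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  cfg <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(stage, ...)
    cat(sprintf("[%s] %s %s\n", format(Sys.time(), "%H:%M:%S"), stage,
                paste0(...)), file = log_path, append = TRUE)
  metrics <- list(config_hash = config_hash(cfg), seed = cfg$seed)
  stage <- "init"
  on_fail <- function(e) {
    write_manifest(out_dir)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    ## ---- simulate ----
    stage <- "simulate"
    logf(stage, "generating landscape and surveys")
    stack <- generate_layers(stage_seed(cfg$seed, "layers"),
                             cfg$landscape$rows, cfg$landscape$cols,
                             cfg$landscape$cell_km)
    truth <- truth_model(stack, n_population = cfg$truth$n_population,
                         g0 = cfg$truth$g0, sigma_km = cfg$truth$sigma_km,
                         het_sd = cfg$truth$het_sd)
    write_stack(stack, file.path(out_dir, "layers"))
    sightings <- generate_sightings(stack, truth, cfg$sdm$n_sightings,
                                    bias = cfg$sdm$bias,
                                    seed = stage_seed(cfg$seed, "sightings"))
    write.csv(sightings, file.path(out_dir, "sightings.csv"),
              row.names = FALSE)

    ## ---- sdm ----
    stage <- "sdm"
    logf(stage, "fitting suitability model")
    model <- fit_sdm(stack, sightings, bias = cfg$sdm$bias,
                     reg_multiplier = cfg$sdm$reg_multiplier,
                     tol = cfg$sdm$tol, max_iter = cfg$sdm$max_iter,
                     split = cfg$sdm$split,
                     bootstrap_reps = cfg$sdm$bootstrap_reps,
                     seed = stage_seed(cfg$seed, "sdm"))
    suit <- project_sdm(model, stack)
    write_asc(suit, file.path(out_dir, "suitability.asc"), stack$cell_km)
    metrics$sdm <- list(auc = model$auc, entropy = model$fit$entropy,
                        converged = model$fit$converged,
                        iterations = model$fit$iterations,
                        truth_spearman = cor(suit[stack$valid],
                                             truth$suitability[stack$valid],
                                             method = "spearman"))
    if (cfg$sdm$null_reps > 0) {
      nm <- null_model_test(stack, length(model$train) + length(model$test),
                            model$auc, seed = stage_seed(cfg$seed, "null"),
                            reps = cfg$sdm$null_reps, bias = cfg$sdm$bias,
                            reg_multiplier = cfg$sdm$reg_multiplier,
                            tol = cfg$sdm$tol, max_iter = cfg$sdm$max_iter,
                            split = cfg$sdm$split)
      write.csv(data.frame(replicate = seq_along(nm$null_auc),
                           auc = nm$null_auc),
                file.path(out_dir, "null_model.csv"), row.names = FALSE)
      metrics$null_model <- list(threshold = nm$threshold,
                                 p_value = nm$p_value,
                                 significant = nm$significant)
    }

    ## ---- cmr ----
    stage <- "cmr"
    logf(stage, "simulating and estimating camera-trap density")
    # one site in high-suitability, one in low-suitability terrain
    vc <- valid_cells(stack)
    s_ord <- vc[order(truth$suitability[vc])]
    picks <- c(low = s_ord[ceiling(0.1 * length(s_ord))],
               high = s_ord[ceiling(0.95 * length(s_ord))])
    dens_rows <- list()
    for (site_nm in names(picks)) {
      cc <- cell_coords(stack, picks[[site_nm]])
      st <- station_grid(cc$x_km, cc$y_km, cfg$cmr$n_stations,
                         cfg$cmr$spacing_km)
      site_truth <- truth
      site_truth$n_population <- max(
        4L, round(cfg$truth$n_population *
                    (0.5 + truth$suitability[picks[[site_nm]]])))
      sim <- simulate_cmr(site_truth, st, cfg$cmr$occasions,
                          seed = stage_seed(cfg$seed, paste0("cmr_", site_nm)))
      eh <- build_encounter_history(sim$detections, 1,
                                    total_nights = cfg$cmr$occasions,
                                    stations = st)
      est <- estimate_mh_jackknife(eh)
      mmdm <- tryCatch(compute_mmdm(sim$detections), error = function(e) NA)
      for (buf in cfg$cmr$buffers) {
        b <- if (buf == "half") mmdm / 2 else mmdm
        if (is.na(b)) next
        area <- effective_area(st, b)
        d <- cmr_density(est, area, buffer = paste0(buf, "-MMDM"))
        dens_rows[[length(dens_rows) + 1]] <- data.frame(
          site = site_nm, n_identified = est$M,
          N_hat = est$N_hat, se = est$se, estimator = est$estimator,
          mmdm_km = as.numeric(mmdm), buffer = d$buffer,
          area_km2 = d$area_km2,
          density = round_half_away(d$density, 1),
          density_lo = round_half_away(d$lower, 1),
          density_hi = round_half_away(d$upper, 1),
          true_N = site_truth$n_population)
      }
    }
    density_table <- do.call(rbind, dens_rows)
    write.csv(density_table, file.path(out_dir, "density_table.csv"),
              row.names = FALSE)
    metrics$cmr <- list(sites = nrow(density_table))

    ## ---- transects ----
    stage <- "transects"
    logf(stage, "simulating transects, computing indices")
    tr <- simulate_transects(stack, truth, cfg$transects$n_sites,
                             cfg$transects$km_per_site,
                             seed = stage_seed(cfg$seed, "transects"))
    traits <- truth$species
    ki <- kilometric_index(tr$contacts, traits, tr$sites)
    ki <- biomass_index(ki, traits)
    write.csv(ki, file.path(out_dir, "transect_indices.csv"),
              row.names = FALSE)
    eff <- effort_sufficiency(tr$contacts, tr$sites,
                              cfg$transects$truncation_grid)
    write.csv(eff, file.path(out_dir, "effort_curve.csv"), row.names = FALSE)
    metrics$transects <- list(
      sufficient_km = attr(eff, "sufficient_d"))

    ## ---- structure ----
    stage <- "structure"
    logf(stage, "deriving habitat-structure variables")
    rough <- focal_roughness(stack$continuous$dem)
    write_asc(rough, file.path(out_dir, "roughness.asc"), stack$cell_km)
    site_rows <- lapply(seq_len(nrow(tr$sites)), function(i) {
      cc <- cell_coords(stack, tr$sites$cell[i])
      poly <- square_site(cc$x_km, cc$y_km, 6 * stack$cell_km)
      summarize_site(poly, list(roughness = rough,
                                agb = stack$continuous$agb,
                                geology = stack$categorical$geology,
                                footprint = stack$continuous$footprint,
                                suitability = suit),
                     stack$cell_km, site_id = tr$sites$site[i])
    })
    site_structure <- do.call(rbind, site_rows)
    write.csv(site_structure, file.path(out_dir, "site_structure.csv"),
              row.names = FALSE)

    ## ---- associate ----
    stage <- "associate"
    logf(stage, "cross-site associations")
    mam <- community_index(ki, "ki",
                           traits$species[traits$guild == "mammal"])
    brd <- community_index(ki, "ki",
                           traits$species[traits$guild == "bird"])
    merged <- data.frame(site = tr$sites$site, hfi = tr$sites$hfi,
                         suitability = tr$sites$suitability,
                         mammal_ki = mam$total[match(tr$sites$site, mam$site)],
                         bird_ki = brd$total[match(tr$sites$site, brd$site)])
    assoc <- rbind(
      assoc_row("mammal_ki~hfi",
                correlate_sites(merged$mammal_ki, merged$hfi)),
      assoc_row("bird_ki~hfi", correlate_sites(merged$bird_ki, merged$hfi)),
      assoc_row("roughness~hfi",
                correlate_sites(site_structure$mean_roughness,
                                site_structure$mean_footprint)))
    rf <- rf_association(site_structure$mean_suitability,
                         site_structure[, c("mean_roughness", "mean_agb",
                                            "modal_geology")],
                         seed = stage_seed(cfg$seed, "rf"))
    assoc <- rbind(assoc, assoc_row("suitability~structure(rf)", rf))
    write.csv(assoc, file.path(out_dir, "associations.csv"),
              row.names = FALSE)
    overlay <- threshold_overlay(stack$continuous$footprint, rough,
                                 cfg$overlay$hfi_cut, cfg$overlay$rough_cut,
                                 stack$valid)
    write_asc(overlay * 1, file.path(out_dir, "priority_mask.asc"),
              stack$cell_km)
    metrics$associations <- setNames(as.list(assoc$r), assoc$pair)
    metrics$priority_fraction <- attr(overlay, "fraction")

    ## ---- report ----
    stage <- "report"
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(out_dir)
    logf(stage, "done")
  }, error = on_fail)
  invisible(metrics)
}

assoc_row <- function(pair, a)
  data.frame(pair = pair, r = a$r, p = a$p, n = a$n, method = a$method)

config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)))
}

write_manifest <- function(out_dir) {
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   c("manifest.csv", "log.txt"))
  if (length(files) == 0) return(invisible(NULL))
  md5 <- tools::md5sum(file.path(out_dir, files))
  write.csv(data.frame(file = files, md5 = unname(md5)),
            file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(md5)
}
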