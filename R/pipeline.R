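#' Default run configuration
#'
#' A complete configuration for an end-to-end run on a synthetic landscape,
#' with the standard analysis defaults: kernel `p = 0.5` and edge cutoff
#' `prob_min = 0.0001`, BRT learning rate 0.001 / tree complexity 5 / bag
#' fraction 0.75, and the 300 m - 10 km distance grid.
#'
#' @return A nested `run_config` list.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    output_dir = "habnetsens_out",
    inputs = list(suitability = NULL, mask = NULL, observations = NULL),
    landscape = list(grid_width = 200L, grid_height = 200L, cell_size = 100,
                     suitability_correlation_length = 400,
                     n_water_sites = 800L, water_buffer = 120,
                     truth_threshold = 0.5),
    occupancy = list(true_max_distance = 4000, beta_hsi = 3,
                     beta_logarea = 0.25, beta_connectivity = 2.5,
                     intercept = -6, n_settle_iterations = 5L),
    sampling = list(mean_visits_per_patch = 5, detection_prob_per_visit = 0.7,
                    n_target_group_species = 12L),
    patches = list(threshold = NULL, connectivity = 8L,
                   n_background = 2000L),
    network = list(p = 0.5, prob_min = 1e-4),
    occurrence = list(snap_distance = 0, saturation_fraction = 0.9,
                      intensity_threshold = 4L),
    brt = list(learning_rate = 0.001, tree_complexity = 5L,
               bag_fraction = 0.75, n_folds = 10L, step_size = 50L,
               max_trees = 10000L, patience = 5L),
    sweep = list(species = "focal",
                 fixed_distances = c(300, 1000, 2000, 4000, 6000, 8000,
                                     10000),
                 species_specific = NULL, dedupe = TRUE,
                 n_replicates = 100L)
  ), class = "run_config")
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]])
    } else {
      defaults[k] <- list(user[[k]])   # preserves explicit NULLs
    }
  }
  defaults
}

#' Validate a run configuration
#'
#' Accepts a YAML file path or a (possibly partial) configuration list,
#' fills in defaults from [default_run_config()], and checks types, ranges
#' and referenced input files, collecting every violation into one error
#' message that names the offending keys.
#'
#' @param config YAML file path or list.
#' @return A validated `run_config` with defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_input("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_input("config must be a list or a YAML path")
  cfg <- merge_config(default_run_config(), config)
  bad <- character(0)
  chk <- function(ok, key, msg) {
    if (!isTRUE(ok)) bad <<- c(bad, sprintf("%s: %s", key, msg))
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$seed), "seed", "must be a single number")
  chk(num1(cfg$network$p) && cfg$network$p > 0 && cfg$network$p < 1,
      "network.p", "must be in (0, 1)")
  chk(num1(cfg$network$prob_min) && cfg$network$prob_min > 0 &&
        cfg$network$prob_min < 1, "network.prob_min", "must be in (0, 1)")
  chk(num1(cfg$brt$learning_rate) && cfg$brt$learning_rate > 0 &&
        cfg$brt$learning_rate <= 1, "brt.learning_rate",
      "must be in (0, 1]")
  chk(num1(cfg$brt$bag_fraction) && cfg$brt$bag_fraction > 0 &&
        cfg$brt$bag_fraction <= 1, "brt.bag_fraction", "must be in (0, 1]")
  chk(num1(cfg$occupancy$true_max_distance) &&
        cfg$occupancy$true_max_distance > 0,
      "occupancy.true_max_distance", "must be > 0")
  chk(is.numeric(cfg$sweep$fixed_distances) &&
        all(cfg$sweep$fixed_distances > 0),
      "sweep.fixed_distances", "must all be > 0")
  chk(is.character(cfg$sweep$species) && length(cfg$sweep$species) >= 1L &&
        !anyDuplicated(cfg$sweep$species),
      "sweep.species", "must be unique species names")
  if (!is.null(cfg$sweep$species_specific))
    chk(all(unlist(cfg$sweep$species_specific) > 0),
        "sweep.species_specific", "distances must be > 0")
  chk(num1(cfg$landscape$cell_size) && cfg$landscape$cell_size > 0,
      "landscape.cell_size", "must be > 0")
  chk(cfg$patches$connectivity %in% c(4L, 8L), "patches.connectivity",
      "must be 4 or 8")
  for (k in c("suitability", "mask", "observations")) {
    pth <- cfg$inputs[[k]]
    if (!is.null(pth))
      chk(file.exists(pth), paste0("inputs.", k),
          sprintf("file '%s' does not exist", pth))
  }
  if (length(bad))
    stop_input("invalid configuration:\n  %s", paste(bad, collapse = "\n  "))
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration as YAML
#'
#' @param config a `run_config`.
#' @param path output file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

pipe_log <- function(quiet, ...) if (!quiet) message(sprintf(...))

require_file <- function(path, stage, needed_from) {
  if (!file.exists(path))
    stop_input("stage '%s' requires '%s'; run '%s' first (or point inputs to existing files)",
               stage, basename(path), needed_from)
  path
}

load_patch_set <- function(out) {
  pd <- utils::read.csv(file.path(out, "patches.csv"))
  cells <- utils::read.csv(file.path(out, "patch_cells.csv"))
  meta <- jsonlite::read_json(file.path(out, "patch_meta.json"),
                              simplifyVector = TRUE)
  cl <- split(cells$cell, cells$patch_id)
  cl <- cl[as.character(pd$patch_id)]
  names(cl) <- NULL
  structure(list(patches = pd, cells = lapply(cl, as.integer),
                 cell_size = meta$cell_size,
                 dim = as.integer(meta$dim), xll = meta$xll, yll = meta$yll,
                 provenance = list(connectivity = meta$connectivity,
                                   threshold = meta$threshold)),
            class = "patch_set")
}

save_patch_set <- function(patches, out) {
  write_patches_csv(patches, file.path(out, "patches.csv"))
  utils::write.csv(
    data.frame(patch_id = rep(patches$patches$patch_id,
                              lengths(patches$cells)),
               cell = unlist(patches$cells, use.names = FALSE)),
    file.path(out, "patch_cells.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(cell_size = patches$cell_size, dim = patches$dim,
         xll = patches$xll, yll = patches$yll,
         connectivity = patches$provenance$connectivity,
         threshold = patches$provenance$threshold),
    file.path(out, "patch_meta.json"), auto_unbox = TRUE, digits = NA)
  write_patches_geojson(patches, file.path(out, "patches.geojson"))
}

#' Run the pipeline
#'
#' Executes the requested stages in canonical order — `simulate`,
#' `delineate`, `network`, `metrics`, `occurrence`, `fit`, `sweep`,
#' `report` — passing state between stages through versioned files under the
#' configured output directory, and writing a manifest (config echo and MD5,
#' master seed, per-stage timing and status) that makes the run
#' reconstructible.
#'
#' @param config a `run_config` (or anything [validate_config()] accepts).
#' @param stages character vector of stage names.
#' @param quiet suppress progress messages?
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config, stages = c("simulate", "delineate",
                                            "network", "metrics",
                                            "occurrence", "fit", "sweep",
                                            "report"),
                         quiet = FALSE) {
  cfg <- validate_config(config)
  all_stages <- c("simulate", "delineate", "network", "metrics",
                  "occurrence", "fit", "sweep", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out, "config.yaml")
  write_run_config(cfg, cfg_path)
  manifest <- list(config = unclass(cfg),
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = cfg$seed, stages = list())
  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    pipe_log(quiet, "[%s] starting (seed %d)", st, cfg$seed)
    switch(st,
           simulate = stage_simulate(cfg, out),
           delineate = stage_delineate(cfg, out),
           network = stage_network(cfg, out),
           metrics = stage_metrics(cfg, out),
           occurrence = stage_occurrence(cfg, out),
           fit = stage_fit(cfg, out),
           sweep = stage_sweep(cfg, out),
           report = stage_report(cfg, out))
    el <- proc.time()[["elapsed"]] - t0
    pipe_log(quiet, "[%s] done in %.1f s", st, el)
    manifest$stages[[st]] <- list(elapsed_s = round(el, 3), status = "ok")
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

stage_simulate <- function(cfg, out) {
  L <- cfg$landscape
  lc <- landscape_config(L$grid_width, L$grid_height, L$cell_size,
                         L$suitability_correlation_length, L$n_water_sites,
                         L$water_buffer, seed = cfg$seed)
  suit <- generate_suitability(lc)
  mask <- generate_mask(lc)
  patches <- delineate_patches(binarize(suit, L$truth_threshold), mask, suit,
                               connectivity = cfg$patches$connectivity)
  if (n_patches(patches) < 2L)
    stop_input("synthetic landscape produced fewer than 2 patches")
  O <- cfg$occupancy
  params <- dispersal_params(
    d0 = d0_for_max_distance(O$true_max_distance, cfg$network$p,
                             cfg$network$prob_min),
    p = cfg$network$p, prob_min = cfg$network$prob_min)
  costs <- interpatch_costs(patches, cost_cap = cost_threshold(params))
  net <- build_network(patches, costs, params)
  obs <- list(); occs <- list()
  for (i in seq_along(cfg$sweep$species)) {
    sp <- cfg$sweep$species[i]
    oc <- occupancy_truth_config(true_d0 = params$d0, beta_hsi = O$beta_hsi,
                                 beta_logarea = O$beta_logarea,
                                 beta_connectivity = O$beta_connectivity,
                                 intercept = O$intercept,
                                 n_settle_iterations = O$n_settle_iterations,
                                 seed = derive_seed(cfg$seed, i))
    occ <- generate_true_occupancy(patches, net, oc)
    sc <- sampling_config(cfg$sampling$mean_visits_per_patch,
                          cfg$sampling$detection_prob_per_visit,
                          cfg$sampling$n_target_group_species,
                          seed = derive_seed(cfg$seed, 1000L + i))
    obs[[i]] <- generate_observations(patches, occ, sc, focal_species = sp)
    occ$species <- sp
    occs[[i]] <- occ
  }
  observations <- do.call(rbind, obs)
  write_truth_bundle(out, suit, mask, patches, do.call(rbind, occs),
                     observations,
                     configs = list(landscape = L, occupancy = O,
                                    sampling = cfg$sampling,
                                    seed = cfg$seed))
  invisible(out)
}

sim_or_input <- function(cfg, out, key, simfile) {
  cfg$inputs[[key]] %||% file.path(out, simfile)
}

stage_delineate <- function(cfg, out) {
  spath <- sim_or_input(cfg, out, "suitability", "suitability.asc")
  mpath <- sim_or_input(cfg, out, "mask", "mask.asc")
  opath <- sim_or_input(cfg, out, "observations", "observations.csv")
  require_file(spath, "delineate", "simulate")
  require_file(mpath, "delineate", "simulate")
  suit <- read_asc(spath)
  mask <- read_asc(mpath)
  mask <- hn_raster(!is.na(mask$values) & mask$values != 0, mask$cell_size,
                    mask$xll, mask$yll)
  thr <- cfg$patches$threshold
  if (is.null(thr)) {
    require_file(opath, "delineate", "simulate")
    obs <- utils::read.csv(opath)
    pres <- suit$values[stats::na.omit(cell_at_xy(suit, obs$x, obs$y))]
    bg_cells <- with_seed(derive_seed(cfg$seed, 99L),
                          sample.int(length(suit$values),
                                     min(cfg$patches$n_background,
                                         length(suit$values))))
    thr <- roc_balance_threshold(pres, suit$values[bg_cells])
  }
  patches <- delineate_patches(binarize(suit, thr), mask, suit,
                               connectivity = cfg$patches$connectivity)
  patches$provenance$threshold <- thr
  save_patch_set(patches, out)
  invisible(out)
}

sweep_from_cfg <- function(cfg) {
  ss <- cfg$sweep$species_specific
  if (!is.null(ss)) ss <- unlist(ss)
  sweep_design(cfg$sweep$species, species_specific = ss,
               fixed_distances = cfg$sweep$fixed_distances,
               dedupe = isTRUE(cfg$sweep$dedupe))
}

networks_for_tasks <- function(cfg, patches) {
  tasks <- enumerate_networks(sweep_from_cfg(cfg))
  dists <- sort(unique(tasks$distance))
  thr <- vapply(dists, function(D) cost_threshold(dispersal_params(
    d0 = d0_for_max_distance(D, cfg$network$p, cfg$network$prob_min),
    p = cfg$network$p, prob_min = cfg$network$prob_min)), numeric(1))
  costs <- interpatch_costs(patches, cost_cap = max(thr))
  nets <- lapply(dists, function(D) build_network(
    patches, costs,
    dispersal_params(d0 = d0_for_max_distance(D, cfg$network$p,
                                              cfg$network$prob_min),
                     p = cfg$network$p, prob_min = cfg$network$prob_min)))
  list(tasks = tasks, distances = dists, networks = nets, costs = costs)
}

stage_network <- function(cfg, out) {
  require_file(file.path(out, "patches.csv"), "network", "delineate")
  patches <- load_patch_set(out)
  nw <- networks_for_tasks(cfg, patches)
  utils::write.csv(nw$costs, file.path(out, "costs.csv"), row.names = FALSE)
  dir.create(file.path(out, "networks"), showWarnings = FALSE)
  for (i in seq_along(nw$distances))
    write_network(nw$networks[[i]],
                  file.path(out, "networks",
                            sprintf("network_d%06d", nw$distances[i])))
  invisible(out)
}

stage_metrics <- function(cfg, out) {
  require_file(file.path(out, "patches.csv"), "metrics", "delineate")
  patches <- load_patch_set(out)
  nw <- networks_for_tasks(cfg, patches)
  dir.create(file.path(out, "metrics"), showWarnings = FALSE)
  for (i in seq_along(nw$distances)) {
    net <- nw$networks[[i]]
    write_metrics(patch_predictors(net), component_census(net),
                  file.path(out, "metrics",
                            sprintf("metrics_d%06d", nw$distances[i])))
  }
  invisible(out)
}

stage_occurrence <- function(cfg, out) {
  require_file(file.path(out, "patches.csv"), "occurrence", "delineate")
  opath <- sim_or_input(cfg, out, "observations", "observations.csv")
  require_file(opath, "occurrence", "simulate")
  patches <- load_patch_set(out)
  obs <- utils::read.csv(opath)
  dir.create(file.path(out, "occurrence"), showWarnings = FALSE)
  for (sp in cfg$sweep$species) {
    tab <- sampling_intensity(obs, patches,
                              snap_distance = cfg$occurrence$snap_distance,
                              focal_species = sp)
    curve <- detection_curve(tab)
    thr <- select_intensity_threshold(
      curve, cfg$occurrence$saturation_fraction,
      manual = cfg$occurrence$intensity_threshold)
    occ <- assign_occurrence_state(tab, thr)
    utils::write.csv(occ, file.path(out, "occurrence",
                                    sprintf("occurrence_%s.csv", sp)),
                     row.names = FALSE)
    utils::write.csv(curve, file.path(out, "occurrence",
                                      sprintf("detection_curve_%s.csv", sp)),
                     row.names = FALSE)
  }
  invisible(out)
}

brt_from_cfg <- function(cfg, seed) {
  b <- cfg$brt
  brt_config(b$learning_rate, b$tree_complexity, b$bag_fraction, b$n_folds,
             b$step_size, b$max_trees, b$patience, seed = seed)
}

stage_fit <- function(cfg, out) {
  require_file(file.path(out, "patches.csv"), "fit", "delineate")
  sp <- cfg$sweep$species[1L]
  occ_path <- require_file(
    file.path(out, "occurrence", sprintf("occurrence_%s.csv", sp)),
    "fit", "occurrence")
  patches <- load_patch_set(out)
  occ <- utils::read.csv(occ_path)
  ss <- cfg$sweep$species_specific[[sp]]
  D <- if (is.null(ss)) cfg$sweep$fixed_distances[1L] else ss
  params <- dispersal_params(
    d0 = d0_for_max_distance(D, cfg$network$p, cfg$network$prob_min),
    p = cfg$network$p, prob_min = cfg$network$prob_min)
  costs <- interpatch_costs(patches, cost_cap = cost_threshold(params))
  net <- build_network(patches, costs, params)
  pred <- patch_predictors(net)
  state <- occ$state[match(pred$patch_id, occ$patch_id)]
  lab <- !is.na(state)
  fit <- fit_brt_step(pred[lab, ], state[lab],
                      brt_from_cfg(cfg, derive_seed(cfg$seed, 5000L)))
  reps <- run_brt_replicates(pred[lab, ], state[lab],
                             brt_from_cfg(cfg, derive_seed(cfg$seed, 5000L)),
                             n_replicates = 1L)
  write_brt_results(reps, fit, file.path(out, sprintf("fit_%s_d%g", sp, D)))
  invisible(out)
}

stage_sweep <- function(cfg, out) {
  require_file(file.path(out, "patches.csv"), "sweep", "delineate")
  opath <- sim_or_input(cfg, out, "observations", "observations.csv")
  require_file(opath, "sweep", "simulate")
  patches <- load_patch_set(out)
  obs <- utils::read.csv(opath)
  res <- run_sweep(sweep_from_cfg(cfg), patches, obs,
                   brt_config = brt_from_cfg(cfg, cfg$seed),
                   n_replicates = cfg$sweep$n_replicates,
                   p = cfg$network$p, prob_min = cfg$network$prob_min,
                   snap_distance = cfg$occurrence$snap_distance,
                   saturation_fraction = cfg$occurrence$saturation_fraction,
                   intensity_threshold = cfg$occurrence$intensity_threshold,
                   seed = cfg$seed)
  utils::write.csv(res$results, file.path(out, "sensitivity_results.csv"),
                   row.names = FALSE)
  utils::write.csv(res$replicates, file.path(out, "sweep_replicates.csv"),
                   row.names = FALSE)
  utils::write.csv(collate_importance_curves(res),
                   file.path(out, "importance_long.csv"), row.names = FALSE)
  regs <- list()
  for (sp in unique(res$results$species)) {
    if (length(unique(res$results$distance[res$results$species == sp])) >= 3L)
      regs[[sp]] <- regress_auc_on_distance(res, sp)
  }
  if (length(regs))
    utils::write.csv(do.call(rbind, regs),
                     file.path(out, "auc_distance_regression.csv"),
                     row.names = FALSE)
  if (length(res$log))
    jsonlite::write_json(res$log, file.path(out, "sweep_log.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(out)
}

stage_report <- function(cfg, out) {
  res_path <- require_file(file.path(out, "sensitivity_results.csv"),
                           "report", "sweep")
  res <- utils::read.csv(res_path)
  dir.create(file.path(out, "report"), showWarnings = FALSE)
  # plot-ready long tables mirroring the sweep's headline figures
  utils::write.csv(res[, c("species", "distance", "n_edges", "n_components")],
                   file.path(out, "report", "components_vs_distance.csv"),
                   row.names = FALSE)
  utils::write.csv(res[, c("species", "distance", "mean_auc_cv",
                           "sd_auc_cv", "mean_n_trees")],
                   file.path(out, "report", "auc_vs_distance.csv"),
                   row.names = FALSE)
  ok <- tryCatch({
    grDevices::png(file.path(out, "report", "sensitivity.png"),
                   width = 1500, height = 500, res = 120, type = "cairo")
    graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
    for (spec in list(
      list(y = "n_components", lab = "Number of components", log = "y"),
      list(y = "mean_auc_cv", lab = "Mean AUC-cv", log = ""),
      list(y = "mean_n_trees", lab = "Mean number of trees", log = ""))) {
      graphics::plot(NA, xlim = range(res$distance),
                     ylim = range(res[[spec$y]]), log = spec$log,
                     xlab = "Maximum dispersal distance (m)",
                     ylab = spec$lab)
      for (sp in unique(res$species)) {
        r <- res[res$species == sp, ]
        graphics::lines(r$distance, r[[spec$y]], type = "b",
                        col = which(unique(res$species) == sp))
      }
    }
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    warning("figure rendering unavailable: ", conditionMessage(e))
    FALSE
  })
  invisible(out)
}
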