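#' Design of a dispersal-distance sweep
#'
#' Each species is modelled at a common grid of maximum dispersal distances
#' plus, optionally, a species-specific distance from the literature.  When
#' `dedupe` is on (default), a species-specific distance that coincides with
#' a fixed distance yields no extra network.
#'
#' @param species character vector of species names (unique).
#' @param species_specific named numeric vector of species-specific maximum
#'   dispersal distances (m); names must be a subset of `species`.
#' @param fixed_distances increasing vector of fixed maximum dispersal
#'   distances (m); default 300 m to 10 km.
#' @param dedupe drop species-specific distances equal to a fixed one?
#' @return A `sweep_design` list.
#' @export
sweep_design <- function(species, species_specific = NULL,
                         fixed_distances = c(300, 1000, 2000, 4000, 6000,
                                             8000, 10000),
                         dedupe = TRUE) {
  if (anyDuplicated(species)) stop_input("duplicate species names")
  if (any(fixed_distances <= 0) || is.unsorted(fixed_distances,
                                               strictly = TRUE))
    stop_input("fixed_distances must be positive and strictly increasing")
  if (!is.null(species_specific)) {
    if (is.null(names(species_specific)) ||
        !all(names(species_specific) %in% species))
      stop_input("species_specific must be named by species")
    if (any(species_specific <= 0))
      stop_input("species-specific distances must be > 0")
  }
  structure(list(species = species, species_specific = species_specific,
                 fixed_distances = fixed_distances, dedupe = dedupe),
            class = "sweep_design")
}

#' Enumerate the (species, distance) model tasks of a sweep
#'
#' Cartesian product of species and the union of fixed and species-specific
#' distances, deduplicated per species when the species-specific value
#' coincides with a fixed one.
#'
#' @param design a [sweep_design()].
#' @return Data frame `species`, `distance`, `is_specific`, one row per
#'   network to build.
#' @export
enumerate_networks <- function(design) {
  stopifnot(inherits(design, "sweep_design"))
  rows <- lapply(design$species, function(sp) {
    d <- design$fixed_distances
    spec <- unname(design$species_specific[sp])
    is_spec <- rep(FALSE, length(d))
    if (length(spec) && !is.na(spec)) {
      if (spec %in% d) {
        if (design$dedupe) {
          is_spec[d == spec] <- TRUE
        } else {
          d <- c(d, spec); is_spec <- c(is_spec, TRUE)
        }
      } else {
        d <- c(d, spec); is_spec <- c(is_spec, TRUE)
      }
    }
    o <- order(d)
    data.frame(species = sp, distance = d[o], is_specific = is_spec[o])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full dispersal-distance sensitivity sweep
#'
#' For each (species, distance) task: derive the kernel (`d0` approximating
#' the distance), build the network by filtering a single cost table computed
#' once up to the largest threshold, compute the per-patch predictors and the
#' component census, join the species' occurrence-state (computed once per
#' species — it depends on the observations, not on the network), and run
#' replicate BRT fits.  Task seeds are derived from the master seed, so
#' results are independent of execution order.  Task-level failures are
#' recorded in the log and skipped.
#'
#' @param design a [sweep_design()]; species names must match the `species`
#'   column of `observations`.
#' @param patches a `patch_set`.
#' @param observations observation records (`x`, `y`, `date`, `species`).
#' @param brt_config a [brt_config()].
#' @param n_replicates BRT replicates per task.
#' @param p,prob_min kernel parameters.
#' @param costs optional precomputed [interpatch_costs()] table.
#' @param snap_distance record-to-patch snapping distance (m).
#' @param saturation_fraction passed to [select_intensity_threshold()].
#' @param intensity_threshold optional manual visit-count threshold (single
#'   value or named per species).
#' @param include_self passed to [habitat_availability()].
#' @param seed master seed.
#' @return A `sensitivity_result`: `results` (one row per task with network
#'   structure, AUC summaries and mean influences), `replicates`
#'   (replicate-level rows), `thresholds` (per-species intensity threshold),
#'   `log`, and the design/config echo.
#' @export
run_sweep <- function(design, patches, observations,
                      brt_config = brt_config(), n_replicates = 100,
                      p = 0.5, prob_min = 1e-4, costs = NULL,
                      snap_distance = 0, saturation_fraction = 0.9,
                      intensity_threshold = NULL, include_self = TRUE,
                      seed = 1L) {
  tasks <- enumerate_networks(design)
  thr_all <- vapply(tasks$distance, function(D)
    cost_threshold(dispersal_params(d0 = d0_for_max_distance(D, p, prob_min),
                                    p = p, prob_min = prob_min)), numeric(1))
  cap <- max(thr_all)
  if (is.null(costs)) {
    costs <- interpatch_costs(patches, cost_cap = cap)
  } else if ((attr(costs, "cost_cap") %||% Inf) < cap) {
    stop_input("supplied cost table cap %g is below the largest threshold %g",
               attr(costs, "cost_cap"), cap)
  }
  log <- list()
  occ_by_species <- list()
  thr_by_species <- list()
  for (sp in design$species) {
    res <- tryCatch({
      tab <- sampling_intensity(observations, patches,
                                snap_distance = snap_distance,
                                focal_species = sp)
      manual <- if (is.null(intensity_threshold)) NULL
                else if (!is.null(names(intensity_threshold)))
                  intensity_threshold[[sp]]
                else intensity_threshold
      vthr <- select_intensity_threshold(detection_curve(tab),
                                         saturation_fraction, manual = manual)
      list(occ = assign_occurrence_state(tab, vthr), thr = vthr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log[[length(log) + 1L]] <- list(species = sp, stage = "occurrence",
                                      error = conditionMessage(res))
    } else {
      occ_by_species[[sp]] <- res$occ
      thr_by_species[[sp]] <- as.integer(res$thr)
    }
  }
  results <- list(); replicates <- list()
  for (ti in seq_len(nrow(tasks))) {
    sp <- tasks$species[ti]; D <- tasks$distance[ti]
    if (is.null(occ_by_species[[sp]])) next
    out <- tryCatch({
      params <- dispersal_params(d0 = d0_for_max_distance(D, p, prob_min),
                                 p = p, prob_min = prob_min)
      net <- build_network(patches, costs, params)
      census <- component_census(net)
      pred <- patch_predictors(net, include_self = include_self)
      occ <- occ_by_species[[sp]]
      state <- occ$state[match(pred$patch_id, occ$patch_id)]
      lab <- !is.na(state)
      cfg <- brt_config
      cfg$seed <- derive_seed(seed, ti)
      reps <- run_brt_replicates(pred[lab, ], state[lab], cfg, n_replicates)
      infl <- reps$summary$mean_influence
      rrow <- cbind(
        data.frame(species = sp, distance = D,
                   is_specific = tasks$is_specific[ti],
                   n_patches = n_patches(patches),
                   n_edges = nrow(net$edges),
                   n_components = census$n_components,
                   n_labelled = sum(lab), n_presence = sum(state[lab] == 1L),
                   mean_auc_cv = reps$summary$mean_auc_cv,
                   sd_auc_cv = reps$summary$sd_auc_cv,
                   mean_auc_train = reps$summary$mean_auc_train,
                   mean_n_trees = reps$summary$mean_n_trees),
        as.data.frame(as.list(stats::setNames(infl,
                                              paste0("imp_", names(infl))))))
      list(row = rrow,
           reps = cbind(data.frame(species = sp, distance = D),
                        reps$replicates))
    }, error = function(e) e)
    if (inherits(out, "error")) {
      log[[length(log) + 1L]] <- list(species = sp, distance = D,
                                      stage = "model",
                                      error = conditionMessage(out))
    } else {
      results[[length(results) + 1L]] <- out$row
      replicates[[length(replicates) + 1L]] <- out$reps
    }
  }
  structure(list(results = do.call(rbind, results),
                 replicates = do.call(rbind, replicates),
                 thresholds = thr_by_species, log = log, design = design,
                 brt_config = brt_config, seed = seed),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> %d tasks, %d species\n",
              if (is.null(x$results)) 0L else nrow(x$results),
              length(unique(x$results$species))))
  if (length(x$log)) cat(sprintf("  %d task(s) failed (see $log)\n",
                                 length(x$log)))
  invisible(x)
}

#' Regress AUC-cv on maximum dispersal distance
#'
#' Ordinary least squares of the replicate-level AUC-cv values on the
#' maximum dispersal distance for one species, summarizing the sweep's
#' headline relation (slope, its standard error and p-value, and the model
#' R-squared).
#'
#' @param result a [run_sweep()] result.
#' @param species species name.
#' @return Data frame `species`, `slope`, `std_error`, `p_value`,
#'   `r_squared`.
#' @export
regress_auc_on_distance <- function(result, species) {
  stopifnot(inherits(result, "sensitivity_result"))
  rows <- result$replicates[result$replicates$species == species, ]
  if (length(unique(rows$distance)) < 3L)
    stop_input("need replicate AUC-cv values at >= 3 distinct distances")
  fit <- stats::lm(auc_cv ~ distance, data = rows)
  s <- summary(fit)
  data.frame(species = species,
             slope = unname(stats::coef(fit)["distance"]),
             std_error = s$coefficients["distance", "Std. Error"],
             p_value = s$coefficients["distance", "Pr(>|t|)"],
             r_squared = s$r.squared)
}

#' Long-format predictor-importance curves
#'
#' Mean relative influence of every predictor against maximum dispersal
#' distance, per species — the table behind importance-versus-distance
#' figures.
#'
#' @param result a [run_sweep()] result.
#' @return Data frame `species`, `distance`, `predictor`, `mean_influence`.
#' @export
collate_importance_curves <- function(result) {
  stopifnot(inherits(result, "sensitivity_result"))
  res <- result$results
  imp_cols <- grep("^imp_", names(res), value = TRUE)
  out <- do.call(rbind, lapply(imp_cols, function(cl) {
    data.frame(species = res$species, distance = res$distance,
               predictor = sub("^imp_", "", cl), mean_influence = res[[cl]])
  }))
  out <- out[order(out$species, out$distance, out$predictor), ]
  rownames(out) <- NULL
  out
}
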