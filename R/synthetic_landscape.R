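#' Configuration for a synthetic landscape
#'
#' Defines a patchy habitat-suitability surface (a Gaussian-smoothed random
#' field rescaled to \[0, 1\]) and a sparse aquatic mask (random water sites
#' buffered by a fixed radius), emulating the kind of study-area rasters a
#' habitat-suitability model and a water-body inventory would provide.
#'
#' @param grid_width,grid_height grid dimensions in cells (>= 16).
#' @param cell_size cell side length in meters (> 0).
#' @param suitability_correlation_length smoothing length of the suitability
#'   field in meters; 0 yields an i.i.d. noise field.
#' @param n_water_sites number of water sites to scatter.
#' @param water_buffer buffer radius around each site in meters.
#' @param seed integer seed; fully determines all generated outputs.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(grid_width = 200, grid_height = 200,
                             cell_size = 100,
                             suitability_correlation_length = 400,
                             n_water_sites = 800, water_buffer = 120,
                             seed = 1L) {
  if (grid_width < 16 || grid_height < 16)
    stop_input("grid dimensions must be >= 16 cells (got %d x %d)",
               grid_width, grid_height)
  if (cell_size <= 0) stop_input("cell_size must be > 0")
  if (suitability_correlation_length < 0)
    stop_input("suitability_correlation_length must be >= 0")
  if (n_water_sites < 0) stop_input("n_water_sites must be >= 0")
  if (water_buffer < 0) stop_input("water_buffer must be >= 0")
  structure(list(grid_width = as.integer(grid_width),
                 grid_height = as.integer(grid_height),
                 cell_size = cell_size,
                 suitability_correlation_length = suitability_correlation_length,
                 n_water_sites = as.integer(n_water_sites),
                 water_buffer = water_buffer,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

#' Configuration of the occupancy-generating model
#'
#' True occupancy is produced by an iterative settlement process on the true
#' habitat network: initial occupancy follows a logistic model in patch
#' quality (HSI) and log area; each settlement iteration adds a connectivity
#' term `beta_connectivity * S_i`, with `S_i` the summed dispersal probability
#' from currently occupied neighbours, and resamples.  This encodes the
#' premise that patch occupancy depends on habitat quality and size but also
#' on connectivity to surrounding patches.
#'
#' @param true_d0 median-dispersal parameter (m) of the generating kernel
#'   (> 0); the truth network must be built with this `d0`.
#' @param beta_hsi,beta_logarea,beta_connectivity,intercept logistic
#'   coefficients of the settlement model.
#' @param n_settle_iterations number of settlement iterations (>= 1).
#' @param seed integer seed.
#' @return An `occupancy_truth_config` list.
#' @export
occupancy_truth_config <- function(true_d0 = 301, beta_hsi = 3,
                                   beta_logarea = 0.25,
                                   beta_connectivity = 2.5, intercept = -6,
                                   n_settle_iterations = 5, seed = 1L) {
  if (true_d0 <= 0) stop_input("true_d0 must be > 0")
  if (n_settle_iterations < 1) stop_input("n_settle_iterations must be >= 1")
  structure(list(true_d0 = true_d0, beta_hsi = beta_hsi,
                 beta_logarea = beta_logarea,
                 beta_connectivity = beta_connectivity,
                 intercept = intercept,
                 n_settle_iterations = as.integer(n_settle_iterations),
                 seed = as.integer(seed)),
            class = "occupancy_truth_config")
}

#' Configuration of visit-based opportunistic sampling
#'
#' Emulates a non-systematically sampled multi-species record database:
#' per-patch visit counts follow an overdispersed (negative-binomial) law,
#' every visit emits one or more records of target-group species, and the
#' focal species is detected at occupied patches with a fixed per-visit
#' probability.
#'
#' @param mean_visits_per_patch mean of the skewed visit distribution.
#' @param detection_prob_per_visit focal detection probability per visit,
#'   in \[0, 1\] (0 yields no focal records at all).
#' @param n_target_group_species number of non-focal target-group species.
#' @param seed integer seed.
#' @return A `sampling_config` list.
#' @export
sampling_config <- function(mean_visits_per_patch = 5,
                            detection_prob_per_visit = 0.7,
                            n_target_group_species = 12, seed = 1L) {
  if (detection_prob_per_visit < 0 || detection_prob_per_visit > 1)
    stop_input("detection_prob_per_visit must be in [0, 1]")
  if (mean_visits_per_patch < 0) stop_input("mean_visits_per_patch must be >= 0")
  if (n_target_group_species < 1) stop_input("n_target_group_species must be >= 1")
  structure(list(mean_visits_per_patch = mean_visits_per_patch,
                 detection_prob_per_visit = detection_prob_per_visit,
                 n_target_group_species = as.integer(n_target_group_species),
                 seed = as.integer(seed)),
            class = "sampling_config")
}

# Periodic Gaussian smoothing of a matrix via the 2-D FFT.
gaussian_smooth_periodic <- function(mat, sigma_cells) {
  n <- nrow(mat); m <- ncol(mat)
  dr <- 0:(n - 1); dr <- pmin(dr, n - dr)
  dc <- 0:(m - 1); dc <- pmin(dc, m - dc)
  K <- outer(exp(-0.5 * (dr / sigma_cells)^2),
             exp(-0.5 * (dc / sigma_cells)^2))
  K <- K / sum(K)
  Re(stats::fft(stats::fft(mat) * stats::fft(K), inverse = TRUE)) / (n * m)
}

#' Generate a synthetic habitat-suitability raster
#'
#' White noise smoothed with a Gaussian kernel of standard deviation
#' `suitability_correlation_length` (periodic boundary), rescaled to
#' \[0, 1\].  With correlation length 0 the field is i.i.d. uniform noise.
#'
#' @param config a [landscape_config()].
#' @return An [hn_raster()] with values in \[0, 1\].
#' @export
generate_suitability <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  with_seed(config$seed, {
    m <- matrix(stats::rnorm(config$grid_height * config$grid_width),
                nrow = config$grid_height, ncol = config$grid_width)
    sigma <- config$suitability_correlation_length / config$cell_size
    if (sigma > 0) m <- gaussian_smooth_periodic(m, sigma)
    m <- (m - min(m)) / (max(m) - min(m))
    hn_raster(m, cell_size = config$cell_size)
  })
}

#' Generate a synthetic aquatic mask raster
#'
#' Scatters `n_water_sites` uniform random points over the extent and marks as
#' water every cell whose centre lies within `water_buffer` of a site, plus
#' the cell containing each site.
#'
#' @param config a [landscape_config()].
#' @return A logical [hn_raster()].
#' @export
generate_mask <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$grid_height; nc <- config$grid_width; cs <- config$cell_size
  mask <- matrix(FALSE, nr, nc)
  r <- hn_raster(mask, cell_size = cs)
  if (config$n_water_sites == 0L) return(r)
  with_seed(config$seed + 1L, {
    sx <- stats::runif(config$n_water_sites, 0, nc * cs)
    sy <- stats::runif(config$n_water_sites, 0, nr * cs)
  })
  buf <- config$water_buffer
  for (k in seq_along(sx)) {
    # cells whose centre may be within the buffer (bounding window)
    c0 <- max(1L, floor((sx[k] - buf) / cs - 0.5) + 1L)
    c1 <- min(nc, ceiling((sx[k] + buf) / cs + 0.5))
    rb0 <- max(1L, floor((sy[k] - buf) / cs - 0.5) + 1L)
    rb1 <- min(nr, ceiling((sy[k] + buf) / cs + 0.5))
    cols <- c0:c1
    rows_from_bottom <- rb0:rb1
    cx <- (cols - 0.5) * cs
    cy <- (rows_from_bottom - 0.5) * cs
    d2 <- outer((cy - sy[k])^2, (cx - sx[k])^2, `+`)
    hit <- d2 <= buf^2
    rows <- nr - rows_from_bottom + 1L
    mask[rows, cols] <- mask[rows, cols] | hit
    cell <- cell_at_xy(r, sx[k], sy[k])
    if (!is.na(cell)) mask[cell] <- TRUE
  }
  out <- hn_raster(mask, cell_size = cs)
  attr(out, "sites") <- cbind(x = sx, y = sy)
  out
}

#' Simulate true occupancy on a habitat network
#'
#' Iterative settlement: occupancy is initialised as Bernoulli with logistic
#' probability `intercept + beta_hsi * HSI + beta_logarea * log(area)`; each of
#' `n_settle_iterations` iterations recomputes the probability adding
#' `beta_connectivity * S_i`, where `S_i` sums the dispersal probabilities of
#' edges to currently occupied neighbours, and resamples all patches.
#'
#' @param patches a [patch_set][delineate_patches()].
#' @param network_truth a [habitat_network()] built on `patches` with the
#'   generating kernel's `true_d0`.
#' @param config an [occupancy_truth_config()].
#' @return Data frame with columns `patch_id`, `occupied` (logical), and
#'   `prob` (settlement probability at the final iteration).
#' @export
generate_true_occupancy <- function(patches, network_truth, config) {
  stopifnot(inherits(config, "occupancy_truth_config"))
  pd <- patches$patches
  if (!setequal(network_truth$nodes$patch_id, pd$patch_id))
    stop_input("network and patch set refer to different patches")
  n <- nrow(pd)
  eta0 <- config$intercept + config$beta_hsi * pd$hsi +
    config$beta_logarea * log(pd$area_m2)
  e <- network_truth$edges
  ia <- match(e$from, pd$patch_id)
  ib <- match(e$to, pd$patch_id)
  conn_sum <- function(occ) {
    s <- numeric(n)
    if (nrow(e)) {
      inc <- c(ia, ib)
      nb <- c(ib, ia)
      w <- rep(e$probability, 2L) * occ[nb]
      add <- tapply(w, inc, sum)
      s[as.integer(names(add))] <- add
    }
    s
  }
  with_seed(config$seed, {
    prob <- stats::plogis(eta0)
    occ <- stats::runif(n) < prob
    for (it in seq_len(config$n_settle_iterations)) {
      prob <- stats::plogis(eta0 + config$beta_connectivity * conn_sum(occ))
      occ <- stats::runif(n) < prob
    }
    data.frame(patch_id = pd$patch_id, occupied = occ, prob = prob)
  })
}

#' Simulate visit-based observation records
#'
#' Each patch receives an overdispersed random number of visits (negative
#' binomial, dispersion 0.8; many patches get none).  Every visit emits one or
#' more records of randomly chosen target-group species; at occupied patches
#' each visit additionally yields a focal-species record with probability
#' `detection_prob_per_visit`.  Record coordinates fall uniformly inside a
#' random member cell of the patch; dates are synthetic per-patch visit labels
#' (one visit = one unique patch-date pair).  Focal records never occur at
#' unoccupied patches.
#'
#' @param patches a [patch_set][delineate_patches()].
#' @param occupancy data frame from [generate_true_occupancy()] (or any frame
#'   with `patch_id` and logical `occupied`).
#' @param config a [sampling_config()].
#' @param focal_species species name used for focal records.
#' @return Data frame of records: `x`, `y`, `date`, `species`, plus a
#'   `patch_id` bookkeeping column with the generating patch.
#' @export
generate_observations <- function(patches, occupancy, config,
                                  focal_species = "focal") {
  stopifnot(inherits(config, "sampling_config"))
  pd <- patches$patches
  occ <- occupancy$occupied[match(pd$patch_id, occupancy$patch_id)]
  if (anyNA(occ)) stop_input("occupancy must be defined for all patches")
  nr <- patches$dim[1L]; cs <- patches$cell_size
  pool <- sprintf("sp%02d", seq_len(config$n_target_group_species))
  with_seed(config$seed, {
    visits <- stats::rnbinom(nrow(pd), size = 0.8,
                             mu = config$mean_visits_per_patch)
    out <- vector("list", nrow(pd))
    for (i in seq_len(nrow(pd))) {
      v <- visits[i]
      if (v == 0L) next
      cells <- patches$cells[[i]]
      recs <- list()
      for (k in seq_len(v)) {
        date <- sprintf("day%04d", k)
        n_bg <- 1L + stats::rpois(1L, 0.5)
        sp <- sample(pool, n_bg, replace = TRUE)
        if (occ[i] && stats::runif(1) < config$detection_prob_per_visit)
          sp <- c(sp, focal_species)
        cell <- cells[sample.int(length(cells), length(sp), replace = TRUE)]
        ccol <- (cell - 1L) %/% nr + 1L
        crow <- (cell - 1L) %% nr + 1L
        cx <- patches$xll + (ccol - 0.5) * cs
        cy <- patches$yll + (nr - crow + 0.5) * cs
        recs[[k]] <- data.frame(
          x = cx + stats::runif(length(sp), -cs / 2, cs / 2),
          y = cy + stats::runif(length(sp), -cs / 2, cs / 2),
          date = date, species = sp, patch_id = pd$patch_id[i])
      }
      out[[i]] <- do.call(rbind, recs)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out))
      return(data.frame(x = numeric(), y = numeric(), date = character(),
                        species = character(), patch_id = integer()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Write a full synthetic-truth bundle to disk
#'
#' Emits the suitability and mask rasters (Esri ASCII grid), the observation
#' records (CSV), the truth patches (GeoJSON), and a JSON truth file with the
#' occupancy flags and a config echo, for use by test harnesses and external
#' tools.
#'
#' @param dir output directory (created if missing).
#' @param suitability,mask [hn_raster()] layers.
#' @param patches a patch set.
#' @param occupancy data frame from [generate_true_occupancy()].
#' @param observations data frame from [generate_observations()].
#' @param configs named list of configs to echo into the truth file.
#' @return `dir`, invisibly.
#' @export
write_truth_bundle <- function(dir, suitability, mask, patches, occupancy,
                               observations, configs = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_asc(suitability, file.path(dir, "suitability.asc"))
  write_asc(hn_raster(mask$values * 1, mask$cell_size, mask$xll, mask$yll),
            file.path(dir, "mask.asc"))
  utils::write.csv(observations, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  write_patches_geojson(patches, file.path(dir, "patches_truth.geojson"))
  jsonlite::write_json(
    list(occupancy = occupancy, configs = configs),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
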