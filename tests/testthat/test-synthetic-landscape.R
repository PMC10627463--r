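test_that("landscape generation is deterministic given the seed", {
  lc <- landscape_config(grid_width = 40, grid_height = 40, cell_size = 100,
                         n_water_sites = 30, seed = 5)
  expect_identical(generate_suitability(lc)$values,
                   generate_suitability(lc)$values)
  expect_identical(generate_mask(lc)$values, generate_mask(lc)$values)
})

test_that("suitability is in [0,1]; zero correlation length gives white noise", {
  lc <- landscape_config(grid_width = 64, grid_height = 64, seed = 2)
  s <- generate_suitability(lc)
  expect_true(min(s$values) >= 0 && max(s$values) <= 1)

  lc0 <- landscape_config(grid_width = 256, grid_height = 256,
                          suitability_correlation_length = 0, seed = 3)
  f <- generate_suitability(lc0)$values
  r_col <- cor(as.vector(f[, -1]), as.vector(f[, -ncol(f)]))
  r_row <- cor(as.vector(f[-1, ]), as.vector(f[-nrow(f), ]))
  expect_lt(abs(r_col), 0.05)
  expect_lt(abs(r_row), 0.05)

  expect_error(landscape_config(grid_width = 8), "grid dimensions")
})

test_that("mask is the rasterized union of buffered water sites", {
  lc0 <- landscape_config(grid_width = 32, grid_height = 32,
                          n_water_sites = 0, seed = 1)
  expect_false(any(generate_mask(lc0)$values))

  lcp <- landscape_config(grid_width = 32, grid_height = 32,
                          n_water_sites = 5, water_buffer = 0, seed = 1)
  expect_lte(sum(generate_mask(lcp)$values), 5)

  lc <- landscape_config(grid_width = 64, grid_height = 64, cell_size = 100,
                         n_water_sites = 3, water_buffer = 200, seed = 9)
  mask <- generate_mask(lc)
  sites <- attr(mask, "sites")
  # brute-force disc rasterization over every cell
  ref <- matrix(FALSE, 64, 64)
  r <- hn_raster(ref, 100)
  for (cell in seq_len(64 * 64)) {
    xy <- cell_xy(r, cell)
    d <- sqrt((sites[, "x"] - xy[1])^2 + (sites[, "y"] - xy[2])^2)
    if (any(d <= 200)) ref[cell] <- TRUE
  }
  for (k in seq_len(nrow(sites)))
    ref[cell_at_xy(r, sites[k, "x"], sites[k, "y"])] <- TRUE
  expect_identical(mask$values, ref)
})

test_that("occupancy follows the settlement model", {
  patches <- spaced_patchset(n_side = 30, seed = 4)   # 900 isolated patches
  costs <- interpatch_costs(patches, cost_cap = 1)    # no pairs within 1 m
  net0 <- build_network(patches, costs, dispersal_params(d0 = 0.05))
  stopifnot(nrow(net0$edges) == 0)

  # saturated logistic: everything occupied
  sat <- occupancy_truth_config(intercept = 50, beta_hsi = 0,
                                beta_logarea = 0, beta_connectivity = 0,
                                seed = 1)
  expect_true(all(generate_true_occupancy(patches, net0, sat)$occupied))

  # beta_connectivity = 0: empirical rate matches mean logistic(eta)
  oc <- occupancy_truth_config(intercept = -9, beta_hsi = 2,
                               beta_logarea = 0.8, beta_connectivity = 0,
                               seed = 7)
  occ <- generate_true_occupancy(patches, net0, oc)
  p <- plogis(oc$intercept + oc$beta_hsi * patches$patches$hsi +
                oc$beta_logarea * log(patches$patches$area_m2))
  se <- sqrt(sum(p * (1 - p))) / length(p)
  expect_lt(abs(mean(occ$occupied) - mean(p)), 3 * se + 1e-12)

  # determinism and patch-mismatch error
  expect_identical(generate_true_occupancy(patches, net0, oc)$occupied,
                   occ$occupied)
  bad_net <- toy_network(3)
  expect_error(generate_true_occupancy(patches, bad_net, oc), "different")
})

test_that("strong connectivity raises occupancy of well-connected patches", {
  world <- small_world(seed = 21, cap_d = 4000)
  net <- network_at(world, 4000)
  deg <- patch_degree(net)
  mean_deg <- c(occ = 0, emp = 0)
  occ_all <- unocc_all <- numeric(0)
  for (s in 1:20) {
    oc <- occupancy_truth_config(beta_connectivity = 2.5, seed = s)
    occ <- generate_true_occupancy(world$patches, net, oc)
    occ_all <- c(occ_all, deg[occ$occupied])
    unocc_all <- c(unocc_all, deg[!occ$occupied])
  }
  expect_gte(mean(occ_all), mean(unocc_all))
})

test_that("observation records respect occupancy and patch geometry", {
  patches <- spaced_patchset(n_side = 15, seed = 2)
  n <- n_patches(patches)
  occ <- data.frame(patch_id = patches$patches$patch_id,
                    occupied = rep(c(TRUE, FALSE), length.out = n))

  # perfect detection: every occupied patch with >= 1 visit has a focal record
  obs1 <- generate_observations(patches, occ,
                                sampling_config(detection_prob_per_visit = 1,
                                                seed = 3))
  visited <- unique(obs1$patch_id)
  focal_at <- unique(obs1$patch_id[obs1$species == "focal"])
  occupied_visited <- intersect(visited,
                                occ$patch_id[occ$occupied])
  expect_setequal(focal_at, occupied_visited)

  # zero detection: no focal records anywhere
  obs0 <- generate_observations(patches, occ,
                                sampling_config(detection_prob_per_visit = 0,
                                                seed = 3))
  expect_identical(sum(obs0$species == "focal"), 0L)

  # no false presences, coordinates inside the generating patch
  expect_true(all(obs1$patch_id[obs1$species == "focal"] %in%
                    occ$patch_id[occ$occupied]))
  r <- hn_raster(matrix(0, patches$dim[1], patches$dim[2]),
                 patches$cell_size, patches$xll, patches$yll)
  cells <- cell_at_xy(r, obs1$x, obs1$y)
  owner <- integer(prod(patches$dim))
  for (i in seq_along(patches$cells))
    owner[patches$cells[[i]]] <- patches$patches$patch_id[i]
  expect_identical(owner[cells], obs1$patch_id)

  # determinism
  expect_identical(obs1, generate_observations(
    patches, occ, sampling_config(detection_prob_per_visit = 1, seed = 3)))
})

test_that("per-visit detection follows the binomial closed form", {
  patches <- spaced_patchset(n_side = 40, seed = 6)  # 1600 patches
  occ <- data.frame(patch_id = patches$patches$patch_id, occupied = TRUE)
  p <- 0.5
  obs <- generate_observations(
    patches, occ, sampling_config(mean_visits_per_patch = 3,
                                  detection_prob_per_visit = p, seed = 8))
  tab <- sampling_intensity(obs, patches)
  for (v in 1:3) {
    stratum <- tab[tab$visits == v, ]
    if (nrow(stratum) < 150) next
    q <- 1 - (1 - p)^v
    frac <- mean(stratum$focal_detections >= 1)
    se <- sqrt(q * (1 - q) / nrow(stratum))
    expect_lt(abs(frac - q), 3 * se)
  }
})

test_that("truth bundle writes a complete plain-text artefact set", {
  world <- small_world(seed = 3, cap_d = 2000, n_water_sites = 60,
                       grid = 40)
  net <- network_at(world, 2000)
  occ <- generate_true_occupancy(world$patches, net,
                                 occupancy_truth_config(seed = 1))
  obs <- generate_observations(world$patches, occ, sampling_config(seed = 1))
  dir <- withr::local_tempdir()
  write_truth_bundle(dir, world$suit, world$mask, world$patches, occ, obs,
                     configs = list(seed = 1))
  expect_true(all(file.exists(file.path(
    dir, c("suitability.asc", "mask.asc", "observations.csv",
           "patches_truth.geojson", "truth.json")))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$occupancy), n_patches(world$patches))
})
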