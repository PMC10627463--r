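# Fixture builders shared across test files.  Everything is generated in code
# at test time; no stored data.

# Patch set of isolated single-cell patches on a regular lattice (every third
# row/column suitable), with random suitability values for HSI variety.
spaced_patchset <- function(n_side = 20, cell_size = 100, seed = 1) {
  dimn <- 3 * n_side
  set.seed(seed)
  suit <- hn_raster(matrix(runif(dimn^2, 0.5, 1), dimn, dimn), cell_size)
  sel <- matrix(FALSE, dimn, dimn)
  sel[seq(2, dimn, by = 3), seq(2, dimn, by = 3)] <- TRUE
  bin <- hn_raster(sel, cell_size)
  mask <- hn_raster(matrix(TRUE, dimn, dimn), cell_size)
  delineate_patches(bin, mask, suit)
}

# Raster triple built from an explicit logical matrix (mask all-TRUE).
rasters_from_matrix <- function(sel, suit_values = NULL, cell_size = 100) {
  if (is.null(suit_values))
    suit_values <- matrix(0.75, nrow(sel), ncol(sel))
  list(suit = hn_raster(suit_values, cell_size),
       bin = hn_raster(sel, cell_size),
       mask = hn_raster(matrix(TRUE, nrow(sel), ncol(sel)), cell_size))
}

# Hand-built habitat network from an edge list on patch ids 1..n.
toy_network <- function(n, edges = NULL, areas = rep(1, n),
                        hsi = rep(0.5, n), d0 = 1000) {
  params <- dispersal_params(d0 = d0)
  nodes <- data.frame(patch_id = seq_len(n), area_m2 = areas, hsi = hsi)
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = integer(), to = integer(), cost = numeric(),
                        probability = numeric())
  } else {
    if (is.null(edges$probability))
      edges$probability <- rep(0.5, nrow(edges))
    if (is.null(edges$cost))
      edges$cost <- -log(edges$probability) / log(2) * d0
  }
  habitat_network(nodes, edges, params,
                  max_dispersal_distance = cost_threshold(params))
}

# Random connected-ish network on <= 8 nodes for oracle comparisons.
random_toy_network <- function(seed, n_max = 8) {
  set.seed(seed)
  n <- sample(4:n_max, 1)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < 0.45
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2])
  edges$probability <- runif(nrow(edges), 0.1, 0.9)
  toy_network(n, edges, areas = runif(n, 1, 10), hsi = runif(n))
}

# Small synthetic world: landscape, patches, cost table capped at `cap_d`.
small_world <- function(seed = 1, cap_d = 10000, n_water_sites = 300,
                        grid = 100, cell_size = 100) {
  lc <- landscape_config(grid_width = grid, grid_height = grid,
                         cell_size = cell_size,
                         suitability_correlation_length = 400,
                         n_water_sites = n_water_sites, water_buffer = 120,
                         seed = seed)
  suit <- generate_suitability(lc)
  mask <- generate_mask(lc)
  patches <- delineate_patches(binarize(suit, 0.5), mask, suit)
  cap <- cost_threshold(dispersal_params(d0 = d0_for_max_distance(cap_d)))
  list(config = lc, suit = suit, mask = mask, patches = patches,
       costs = interpatch_costs(patches, cost_cap = cap))
}

network_at <- function(world, distance) {
  build_network(world$patches, world$costs,
                dispersal_params(d0 = d0_for_max_distance(distance)))
}
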