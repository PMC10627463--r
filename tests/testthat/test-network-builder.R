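test_that("kernel cost threshold and d0 conversion reproduce known values", {
  # d0 = 113 gives a threshold within rounding of the 1500 m distance
  expect_equal(cost_threshold(dispersal_params(d0 = 113)), 1501.5,
               tolerance = 0.0001)
  # prob_min = p recovers d0; squaring the probability doubles the cost
  expect_equal(cost_threshold(dispersal_params(d0 = 100, prob_min = 0.5)),
               100)
  expect_equal(cost_threshold(dispersal_params(d0 = 100, prob_min = 0.25)),
               200)
  expect_error(dispersal_params(d0 = 100, p = 1), "p must be")

  expect_identical(d0_for_max_distance(4411), 332L)
  expect_identical(d0_for_max_distance(2658), 200L)
  expect_error(d0_for_max_distance(-5), "max_distance")
  expect_error(d0_for_max_distance(100, prob_min = 0), "degenerate")

  # round-trip identity: threshold of integer d0 maps back to d0
  for (k in c(1, 7, 50, 113, 332, 1000))
    expect_identical(
      d0_for_max_distance(cost_threshold(dispersal_params(d0 = k))),
      as.integer(k))
})

test_that("edge probability follows the negative-exponential kernel", {
  p <- dispersal_params(d0 = 500)
  expect_equal(edge_probability(0, p), 1)
  expect_equal(edge_probability(500, p), 0.5)
  expect_equal(edge_probability(1000, p), 0.25)
  expect_error(edge_probability(-1, p), "cost")
})

test_that("euclidean interpatch costs equal minimum member-cell distances", {
  # diagonal single-cell patches under 4-connectivity: sqrt(2) cells apart
  sel <- matrix(FALSE, 3, 3)
  sel[1, 1] <- TRUE; sel[2, 2] <- TRUE
  rs <- rasters_from_matrix(sel)
  ps4 <- delineate_patches(rs$bin, rs$mask, rs$suit, 4)
  expect_equal(interpatch_costs(ps4)$cost, sqrt(2) * 100)

  sel <- matrix(FALSE, 3, 8)
  sel[2, 1] <- TRUE; sel[2, 7] <- TRUE
  rs <- rasters_from_matrix(sel)
  ps <- delineate_patches(rs$bin, rs$mask, rs$suit)
  costs <- interpatch_costs(ps)
  expect_equal(nrow(costs), 1)
  expect_equal(costs$cost, 6 * 100)  # 6 cells apart on a row

  # random landscape: every pair equals the brute-force min over cell centres
  world <- small_world(seed = 5, cap_d = 10000, n_water_sites = 40,
                       grid = 40)
  ps <- world$patches
  r <- hn_raster(matrix(0, ps$dim[1], ps$dim[2]), ps$cell_size)
  got <- world$costs
  for (k in sample(nrow(got), min(25, nrow(got)))) {
    A <- cell_xy(r, ps$cells[[got$from[k]]])
    B <- cell_xy(r, ps$cells[[got$to[k]]])
    ref <- sqrt(min(outer(A[, 1], B[, 1], `-`)^2 +
                      outer(A[, 2], B[, 2], `-`)^2))
    expect_equal(got$cost[k], ref)
  }
})

test_that("grid-mode costs dominate euclidean costs on a uniform surface", {
  world <- small_world(seed = 6, cap_d = 4000, n_water_sites = 25, grid = 30)
  eu <- interpatch_costs(world$patches, cost_cap = 5000)
  gr <- interpatch_costs(world$patches, cost_cap = 1e9, mode = "grid")
  key <- function(d) paste(d$from, d$to)
  common <- intersect(key(eu), key(gr))
  expect_gt(length(common), 0)
  e <- eu$cost[match(common, key(eu))]
  g <- gr$cost[match(common, key(gr))]
  expect_true(all(g >= e - 1e-9))
  # octile-metric bound for straight-line-reachable pairs
  expect_true(all(g <= e * (sqrt(2) + 0.02)))

  # grid mode with a barrier of untraversable cells forces a detour
  sel <- matrix(FALSE, 5, 5)
  sel[3, 1] <- TRUE; sel[3, 5] <- TRUE
  rs <- rasters_from_matrix(sel)
  ps <- delineate_patches(rs$bin, rs$mask, rs$suit)
  res <- matrix(1, 5, 5); res[1:4, 3] <- NA
  gr2 <- interpatch_costs(ps, hn_raster(res, 100), cost_cap = 1e9,
                          mode = "grid")
  direct <- interpatch_costs(ps, cost_cap = 1e9)
  expect_gt(gr2$cost, direct$cost * 1.2)
})

test_that("edges form strictly below the kernel threshold", {
  # hand-built cost table: AB 100, AC 250, BC 300, AD 900; threshold ~260
  ps_fake <- list(patches = data.frame(patch_id = 1:4,
                                       area_m2 = rep(100, 4),
                                       hsi = rep(0.5, 4)))
  costs <- structure(data.frame(from = c(1, 1, 2, 1), to = c(2, 3, 3, 4),
                                cost = c(100, 250, 300, 900)),
                     cost_cap = 1000)
  params <- dispersal_params(d0 = 260 / (log(1e-4) / log(0.5)))
  net <- build_network(ps_fake, costs, params)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$from, net$edges$to), c("1 2", "1 3"))
  expect_equal(net$edges$probability, edge_probability(c(100, 250), params))

  # probabilities in [prob_min, 1), decreasing with cost
  expect_true(all(net$edges$probability > params$prob_min &
                    net$edges$probability < 1))

  # tiny d0: no edges; huge threshold: complete graph
  expect_equal(nrow(build_network(ps_fake, costs,
                                  dispersal_params(d0 = 1))$edges), 0)
  big <- dispersal_params(d0 = 75)   # threshold 996.6 m covers all pairs
  expect_equal(nrow(build_network(ps_fake, costs, big)$edges),
               nrow(costs))

  # cost table must cover the threshold
  expect_error(build_network(ps_fake, costs, dispersal_params(d0 = 100)),
               "cost_cap")
})

test_that("edge sets are nested across increasing thresholds", {
  world <- small_world(seed = 9, cap_d = 8000, n_water_sites = 120,
                       grid = 60)
  prev <- character()
  for (D in c(300, 1000, 2000, 4000, 8000)) {
    net <- network_at(world, D)
    key <- paste(net$edges$from, net$edges$to)
    expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("network constructor enforces the edge invariants", {
  expect_error(toy_network(3, data.frame(from = 1, to = 1)), "self-loop")
  expect_error(toy_network(3, data.frame(from = c(1, 2), to = c(2, 1))),
               "duplicate")
  expect_error(toy_network(3, data.frame(from = 1, to = 2,
                                         probability = 1.5)),
               "probabilities")
})

test_that("networks round-trip to GraphML and CSV", {
  net <- toy_network(4, data.frame(from = c(1, 2), to = c(2, 3),
                                   probability = c(0.5, 0.25)))
  stem <- file.path(withr::local_tempdir(), "net")
  write_network(net, stem)
  g <- igraph::read_graph(paste0(stem, ".graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 2)
  ed <- read.csv(paste0(stem, "_edges.csv"))
  expect_equal(sort(ed$probability), c(0.25, 0.5))
})
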