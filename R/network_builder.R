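#' Dispersal-kernel parameters
#'
#' The negative-exponential dispersal kernel is parameterized by `d0`, the
#' cost distance still reached by a proportion `p` of dispersing individuals
#' (with `p = 0.5`, `d0` is the median dispersal distance), and `prob_min`,
#' the dispersal probability below which no edge is drawn.  Cost and
#' probability are linked by `cost = log(prob) / log(p) * d0`.
#'
#' @param d0 median-dispersal cost distance in meters (> 0).
#' @param p proportion of individuals reaching `d0`, in (0, 1); default 0.5.
#' @param prob_min edge-formation probability cutoff, in (0, 1);
#'   default 0.0001.
#' @return A `dispersal_params` list.
#' @export
dispersal_params <- function(d0, p = 0.5, prob_min = 1e-4) {
  if (!is.numeric(d0) || d0 <= 0) stop_input("d0 must be > 0")
  if (p <= 0 || p >= 1) stop_input("p must be in (0, 1)")
  if (prob_min <= 0 || prob_min >= 1) stop_input("prob_min must be in (0, 1)")
  structure(list(p = p, d0 = d0, prob_min = prob_min),
            class = "dispersal_params")
}

#' Cost threshold implied by the dispersal kernel
#'
#' The cost distance at which dispersal probability drops to `prob_min`:
#' `log(prob_min) / log(p) * d0`.  Edges are drawn only below this cost, so it
#' plays the role of the species' maximum dispersal distance.
#'
#' @param params a [dispersal_params()].
#' @return Cost threshold in meters-equivalent.
#' @export
cost_threshold <- function(params) {
  stopifnot(inherits(params, "dispersal_params"))
  log(params$prob_min) / log(params$p) * params$d0
}

#' d0 approximating a given maximum dispersal distance
#'
#' Inverts the cost-threshold relation: the integer `d0` whose kernel reaches
#' the `prob_min` cutoff at `max_distance`, i.e.
#' `round(max_distance * log(p) / log(prob_min))`.
#'
#' @param max_distance target maximum dispersal distance in meters (> 0).
#' @param p,prob_min kernel parameters as in [dispersal_params()].
#' @return Integer `d0` in meters.
#' @export
d0_for_max_distance <- function(max_distance, p = 0.5, prob_min = 1e-4) {
  if (!is.numeric(max_distance) || any(max_distance <= 0))
    stop_input("max_distance must be > 0")
  if (p <= 0 || p >= 1 || prob_min <= 0 || prob_min >= 1)
    stop_input("degenerate kernel parameters: need 0 < p < 1 and 0 < prob_min < 1")
  as.integer(round(max_distance * log(p) / log(prob_min)))
}

#' Dispersal probability at a given cost distance
#'
#' `p ^ (cost / d0)`: probability 1 at cost 0, `p` at `d0`, multiplicative in
#' cost.
#'
#' @param cost nonnegative cost distance(s) in meters-equivalent.
#' @param params a [dispersal_params()].
#' @return Dispersal probabilities in (0, 1\].
#' @export
edge_probability <- function(cost, params) {
  stopifnot(inherits(params, "dispersal_params"))
  if (any(cost < 0)) stop_input("cost must be >= 0")
  params$p^(cost / params$d0)
}

#' Pairwise least-cost distances between patches
#'
#' Patch-to-patch distance is boundary-to-boundary: the minimum over member
#' cells of one patch to member cells of the other.  Two modes:
#'
#' * `"euclidean"` (default): exact minimum Euclidean distance between member
#'   cell centres; appropriate for a uniform resistance surface, where least
#'   cumulative costs approximately equal interpatch Euclidean distances.
#' * `"grid"`: least cumulative cost over 8-neighbour moves on a resistance
#'   raster; each step costs the mean of the endpoint resistances times the
#'   centre-to-centre distance (diagonal steps times sqrt(2)).  Cells with
#'   `NA` or nonpositive resistance are untraversable.
#'
#' Pairs with cost above `cost_cap` are omitted, as are unreachable pairs.
#'
#' @param patches a `patch_set`.
#' @param surface optional resistance [hn_raster()] (cost per meter); required
#'   alignment with the patch grid.  `NULL` means uniform resistance 1.
#' @param cost_cap maximum cost to retain (also enables early pruning).
#' @param mode `"euclidean"` or `"grid"`.
#' @return Data frame `from`, `to`, `cost` (one row per unordered pair,
#'   `from < to`), with `cost_cap` and `mode` attributes.
#' @export
interpatch_costs <- function(patches, surface = NULL, cost_cap = Inf,
                             mode = c("euclidean", "grid")) {
  mode <- match.arg(mode)
  n <- n_patches(patches)
  empty <- structure(
    data.frame(from = integer(), to = integer(), cost = numeric()),
    cost_cap = cost_cap, mode = mode)
  if (n < 2L) return(empty)
  if (mode == "euclidean") {
    costs <- euclidean_costs(patches, cost_cap)
  } else {
    costs <- grid_costs(patches, surface, cost_cap)
  }
  structure(costs, cost_cap = cost_cap, mode = mode)
}

# Boundary member cells of each patch (cells with any 8-neighbour outside the
# patch or outside the grid); minimum interpatch distances are attained there.
boundary_cells <- function(patches) {
  nr <- patches$dim[1L]; nc <- patches$dim[2L]
  owner <- integer(nr * nc)
  for (i in seq_along(patches$cells)) owner[patches$cells[[i]]] <- i
  lapply(seq_along(patches$cells), function(i) {
    cc <- patches$cells[[i]]
    row <- (cc - 1L) %% nr + 1L
    col <- (cc - 1L) %/% nr + 1L
    interior <- rep(TRUE, length(cc))
    for (dr in -1L:1L) for (dc in -1L:1L) {
      if (dr == 0L && dc == 0L) next
      r2 <- row + dr; c2 <- col + dc
      inside <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
      nb_owner <- rep(0L, length(cc))
      nb_owner[inside] <- owner[(c2[inside] - 1L) * nr + r2[inside]]
      interior <- interior & inside & nb_owner == i
    }
    cc[!interior]
  })
}

euclidean_costs <- function(patches, cost_cap) {
  n <- n_patches(patches)
  r <- hn_raster(matrix(0, patches$dim[1L], patches$dim[2L]),
                 patches$cell_size, patches$xll, patches$yll)
  bcells <- boundary_cells(patches)
  coords <- lapply(bcells, function(cc) cell_xy(r, cc))
  ctr <- t(vapply(coords, colMeans, numeric(2)))
  rad <- vapply(seq_len(n), function(i) {
    max(sqrt((coords[[i]][, 1L] - ctr[i, 1L])^2 +
             (coords[[i]][, 2L] - ctr[i, 2L])^2))
  }, numeric(1))
  out_from <- integer(0); out_to <- integer(0); out_cost <- numeric(0)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    # bounding-circle prefilter against the cap
    cd <- sqrt((ctr[js, 1L] - ctr[i, 1L])^2 + (ctr[js, 2L] - ctr[i, 2L])^2)
    js <- js[cd - rad[i] - rad[js] <= cost_cap]
    if (!length(js)) next
    A <- coords[[i]]
    for (j in js) {
      B <- coords[[j]]
      d2 <- outer(A[, 1L], B[, 1L], `-`)^2 + outer(A[, 2L], B[, 2L], `-`)^2
      d <- sqrt(min(d2))
      if (d <= cost_cap) {
        out_from <- c(out_from, i); out_to <- c(out_to, j)
        out_cost <- c(out_cost, d)
      }
    }
  }
  data.frame(from = out_from, to = out_to, cost = out_cost)
}

grid_costs <- function(patches, surface, cost_cap) {
  nr <- patches$dim[1L]; nc <- patches$dim[2L]; cs <- patches$cell_size
  if (is.null(surface)) {
    surface <- hn_raster(matrix(1, nr, nc), cs, patches$xll, patches$yll)
  } else {
    stopifnot(is_hn_raster(surface))
    if (!identical(dim(surface$values), c(nr, nc)) ||
        !isTRUE(all.equal(surface$cell_size, cs)))
      stop_input("resistance surface is not aligned with the patch grid")
  }
  res <- surface$values
  trav <- !is.na(res) & res > 0
  idx <- which(trav)
  if (!length(idx)) return(data.frame(from = integer(), to = integer(),
                                      cost = numeric()))
  map <- integer(nr * nc); map[idx] <- seq_along(idx)
  owner <- integer(nr * nc)
  for (i in seq_along(patches$cells)) owner[patches$cells[[i]]] <- i
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  offs <- list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
               c(-1L, 1L, sqrt(2)))
  ea <- integer(0); eb <- integer(0); w <- numeric(0)
  for (off in offs) {
    r2 <- row + off[1L]; c2 <- col + off[2L]
    keep <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    n2 <- (c2[keep] - 1L) * nr + r2[keep]
    hit <- map[n2] > 0L
    a <- idx[keep][hit]; b <- n2[hit]
    step <- (res[a] + res[b]) / 2 * cs * off[3L]
    ea <- c(ea, map[a]); eb <- c(eb, map[b]); w <- c(w, step)
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  g <- igraph::add_edges(g, rbind(ea, eb))
  igraph::E(g)$weight <- w
  npat <- n_patches(patches)
  if (any(vapply(patches$cells, function(cc) any(map[cc] == 0L),
                 logical(1))))
    stop_input("some patch cells lie on untraversable resistance cells")
  out <- list()
  for (i in seq_len(npat - 1L)) {
    # multi-source Dijkstra over the source patch's member cells; crossing
    # other patches costs like any other traversable ground
    Di <- igraph::distances(g, v = map[patches$cells[[i]]],
                            weights = igraph::E(g)$weight)
    dmin <- do.call(pmin, lapply(seq_len(nrow(Di)), function(r) Di[r, ]))
    for (j in (i + 1L):npat) {
      d <- min(dmin[map[patches$cells[[j]]]])
      if (is.finite(d) && d <= cost_cap)
        out[[length(out) + 1L]] <- c(i, j, d)
    }
  }
  if (!length(out)) return(data.frame(from = integer(), to = integer(),
                                      cost = numeric()))
  m <- do.call(rbind, out)
  data.frame(from = as.integer(m[, 1L]), to = as.integer(m[, 2L]),
             cost = m[, 3L])
}

#' Construct a habitat network object
#'
#' Low-level constructor used by [build_network()] and by tests that need
#' hand-built networks.  Validates the network invariants: undirected edges
#' with no self-loops or duplicates, and probabilities in (0, 1\].
#'
#' @param nodes data frame with `patch_id`, `area_m2`, `hsi`.
#' @param edges data frame with `from`, `to` (patch ids), `cost`,
#'   `probability`.
#' @param params the [dispersal_params()] used (echoed).
#' @param max_dispersal_distance the cost threshold in force.
#' @return A `habitat_network` object.
#' @export
habitat_network <- function(nodes, edges, params,
                            max_dispersal_distance = cost_threshold(params)) {
  stopifnot(all(c("patch_id", "area_m2", "hsi") %in% names(nodes)))
  stopifnot(all(c("from", "to", "cost", "probability") %in% names(edges)))
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) stop_input("self-loop edges not allowed")
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) stop_input("duplicate edges not allowed")
    if (any(edges$probability <= 0 | edges$probability > 1))
      stop_input("edge probabilities must be in (0, 1]")
    if (!all(edges$from %in% nodes$patch_id) ||
        !all(edges$to %in% nodes$patch_id))
      stop_input("edge endpoints must be node patch_ids")
  }
  structure(list(nodes = nodes, edges = edges, params = params,
                 max_dispersal_distance = max_dispersal_distance),
            class = "habitat_network")
}

#' Build a habitat network from pairwise costs
#'
#' Draws an undirected edge between every patch pair whose least-cost
#' distance is strictly below the kernel's cost threshold, annotating each
#' edge with its cost and dispersal probability.  The cost table must have
#' been computed at least up to that threshold.
#'
#' @param patches a `patch_set`.
#' @param costs pairwise cost table from [interpatch_costs()].
#' @param params a [dispersal_params()].
#' @return A [habitat_network()] whose `max_dispersal_distance` is
#'   `cost_threshold(params)`.
#' @export
build_network <- function(patches, costs, params) {
  thr <- cost_threshold(params)
  cap <- attr(costs, "cost_cap") %||% Inf
  if (cap < thr)
    stop_input(paste0("cost table computed up to %g but the kernel threshold",
                      " is %g; recompute with a larger cost_cap"), cap, thr)
  keep <- costs$cost < thr
  edges <- data.frame(from = patches$patches$patch_id[costs$from[keep]],
                      to = patches$patches$patch_id[costs$to[keep]],
                      cost = costs$cost[keep])
  edges$probability <- if (nrow(edges)) edge_probability(edges$cost, params)
                       else numeric(0)
  nodes <- patches$patches[, c("patch_id", "area_m2", "hsi")]
  habitat_network(nodes, edges, params, max_dispersal_distance = thr)
}

#' @export
print.habitat_network <- function(x, ...) {
  cat(sprintf(paste0("<habitat_network> %d patches, %d edges ",
                     "(d0 = %g m, p = %g, threshold %.1f m)\n"),
              nrow(x$nodes), nrow(x$edges), x$params$d0, x$params$p,
              x$max_dispersal_distance))
  invisible(x)
}

#' Convert a habitat network to an igraph graph
#'
#' Vertices are patch ids (with `area_m2` and `hsi` attributes); edges carry
#' `cost` and `probability`.
#'
#' @param network a `habitat_network`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "habitat_network"))
  verts <- data.frame(name = as.character(network$nodes$patch_id),
                      area_m2 = network$nodes$area_m2,
                      hsi = network$nodes$hsi)
  ed <- network$edges
  igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$from), to = as.character(ed$to),
               cost = ed$cost, probability = ed$probability),
    directed = FALSE, vertices = verts)
}

#' Write a habitat network to disk
#'
#' Emits GraphML plus two CSVs (`<stem>_nodes.csv`: patch_id, area_m2, hsi;
#' `<stem>_edges.csv`: from, to, cost_m, probability).
#'
#' @param network a `habitat_network`.
#' @param stem output path stem (files `<stem>.graphml`, `<stem>_nodes.csv`,
#'   `<stem>_edges.csv`).
#' @export
write_network <- function(network, stem) {
  g <- as_igraph(network)
  igraph::write_graph(g, paste0(stem, ".graphml"), format = "graphml")
  utils::write.csv(network$nodes, paste0(stem, "_nodes.csv"),
                   row.names = FALSE)
  ed <- network$edges
  names(ed)[names(ed) == "cost"] <- "cost_m"
  utils::write.csv(ed, paste0(stem, "_edges.csv"), row.names = FALSE)
  invisible(stem)
}
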