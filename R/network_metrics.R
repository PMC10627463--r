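#' Per-patch topological predictors
#'
#' The patch-level predictors used in the occurrence-state models: degree,
#' third-order neighborhood, unweighted betweenness centrality, strength
#' (probability-weighted degree), and habitat availability (area-weighted
#' reachability based on the probability-of-connectivity index), together with
#' patch HSI and area.
#'
#' @param network a [habitat_network()].
#' @param include_self should habitat availability include the patch's own
#'   area (the PC index's i = j term)?  Default `TRUE`.
#' @return Data frame with one row per patch: `patch_id`, `degree`, `neigh3`,
#'   `betweenness`, `strength`, `habAv`, `HSI`, `area`.
#' @export
patch_predictors <- function(network, include_self = TRUE) {
  data.frame(
    patch_id = network$nodes$patch_id,
    degree = patch_degree(network),
    neigh3 = third_order_neighborhood(network),
    betweenness = patch_betweenness(network),
    strength = patch_strength(network),
    habAv = habitat_availability(network, include_self = include_self),
    HSI = network$nodes$hsi,
    area = network$nodes$area_m2
  )
}

#' Patch degree
#'
#' Number of edges incident to each patch.
#'
#' @param network a [habitat_network()].
#' @return Numeric vector aligned with `network$nodes`.
#' @export
patch_degree <- function(network) {
  g <- as_igraph(network)
  unname(igraph::degree(g))
}

#' Third-order neighborhood size
#'
#' Number of distinct patches within three edges (unweighted geodesic
#' distance <= 3), excluding the focal patch.
#'
#' @inheritParams patch_degree
#' @return Numeric vector aligned with `network$nodes`.
#' @export
third_order_neighborhood <- function(network) {
  g <- as_igraph(network)
  unname(igraph::ego_size(g, order = 3, mindist = 1))
}

#' Unweighted betweenness centrality
#'
#' Shortest-path betweenness on the unweighted graph, unnormalized, with each
#' unordered pair counted once: the sum over pairs (s, t) of the fraction of
#' shortest s-t paths passing through the focal patch.  Cross-component pairs
#' contribute nothing.
#'
#' @inheritParams patch_degree
#' @return Numeric vector aligned with `network$nodes`.
#' @export
patch_betweenness <- function(network) {
  g <- as_igraph(network)
  unname(igraph::betweenness(g, directed = FALSE, weights = NA))
}

#' Patch strength
#'
#' Sum of the dispersal probabilities on a patch's incident edges (the
#' weighted version of degree).
#'
#' @inheritParams patch_degree
#' @return Numeric vector aligned with `network$nodes`.
#' @export
patch_strength <- function(network) {
  g <- as_igraph(network)
  unname(igraph::strength(g, weights = igraph::E(g)$probability))
}

#' Habitat availability
#'
#' Node-level adaptation of the probability-of-connectivity index: for patch
#' i, `HA_i = [a_i] + sum_j a_j * p*_ij`, where `p*_ij` is the maximum over
#' paths of the product of edge dispersal probabilities (computed exactly as
#' a shortest path on `-log(probability)` weights) and the optional `a_i`
#' term is controlled by `include_self`.  Unreachable patches contribute
#' nothing.
#'
#' @inheritParams patch_predictors
#' @return Numeric vector (m2) aligned with `network$nodes`.
#' @export
habitat_availability <- function(network, include_self = TRUE) {
  if (nrow(network$edges) &&
      any(network$edges$probability <= 0))
    stop_input("edge probabilities must be positive")
  g <- as_igraph(network)
  a <- network$nodes$area_m2
  n <- nrow(network$nodes)
  if (igraph::ecount(g) == 0L) return(if (include_self) a else numeric(n))
  D <- igraph::distances(g, weights = -log(igraph::E(g)$probability))
  P <- exp(-D)
  diag(P) <- 0
  P[!is.finite(P)] <- 0
  ha <- as.numeric(P %*% a)
  if (include_self) ha <- ha + a
  ha
}

#' Component census of a habitat network
#'
#' Connected components of the undirected graph: how many, which patch is in
#' which, and the size of the largest.  Isolated patches are singleton
#' components.
#'
#' @inheritParams patch_degree
#' @return A `component_census` list: `n_components`, `component_id` (integer
#'   vector named by patch id), `sizes`, `giant_component_size`.
#' @export
component_census <- function(network) {
  g <- as_igraph(network)
  cp <- igraph::components(g)
  memb <- cp$membership
  structure(list(n_components = cp$no,
                 component_id = stats::setNames(as.integer(memb),
                                                names(memb)),
                 sizes = as.integer(cp$csize),
                 giant_component_size = if (cp$no) max(cp$csize) else 0L),
            class = "component_census")
}

#' @export
print.component_census <- function(x, ...) {
  cat(sprintf("<component_census> %d components, giant size %d\n",
              x$n_components, x$giant_component_size))
  invisible(x)
}

#' Write predictor table and component census to disk
#'
#' @param predictors data frame from [patch_predictors()].
#' @param census a [component_census()].
#' @param stem output path stem.
#' @export
write_metrics <- function(predictors, census, stem) {
  utils::write.csv(predictors, paste0(stem, "_predictors.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(patch_id = names(census$component_id),
               component_id = census$component_id),
    paste0(stem, "_components.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_components = census$n_components,
         giant_component_size = census$giant_component_size),
    paste0(stem, "_components.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
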