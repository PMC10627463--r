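#' ROC-balance binarization threshold
#'
#' Scans every observed score value as a candidate threshold and returns the
#' one minimizing the absolute difference between sensitivity (fraction of
#' presence scores `>= t`) and specificity (fraction of background scores
#' `< t`), the standard sensitivity-equals-specificity rule for binarizing a
#' continuous suitability map.  Ties are broken toward the smaller threshold.
#'
#' @param scores_presence suitability values at presence locations.
#' @param scores_background suitability values at background locations.
#' @return The selected threshold.
#' @export
roc_balance_threshold <- function(scores_presence, scores_background) {
  if (!length(scores_presence) || !length(scores_background))
    stop_input("both presence and background score sets must be non-empty")
  cand <- sort(unique(c(scores_presence, scores_background)))
  gap <- vapply(cand, function(t) {
    se <- mean(scores_presence >= t)
    sp <- mean(scores_background < t)
    abs(se - sp)
  }, numeric(1))
  cand[which.min(gap)]  # which.min takes the first (smallest) on ties
}

#' Binarize a suitability raster
#'
#' Cells with suitability `>= threshold` become `TRUE`; nodata stays `NA`
#' (treated as unsuitable downstream).
#'
#' @param raster an [hn_raster()] with values in \[0, 1\].
#' @param threshold binarization threshold in \[0, 1\].
#' @return A logical [hn_raster()].
#' @export
binarize <- function(raster, threshold) {
  stopifnot(is_hn_raster(raster))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop_input("threshold must be a single value in [0, 1]")
  hn_raster(raster$values >= threshold, raster$cell_size,
            raster$xll, raster$yll)
}

#' Delineate habitat patches
#'
#' Habitat patches are the connected components (8-connectivity by default;
#' diagonal neighbours merge) of the cells that are both suitable and inside
#' the environmental mask.  Each component becomes one patch with an area
#' (cell count times cell area) and an HSI (mean continuous suitability over
#' exactly its member cells).
#'
#' @param binary logical [hn_raster()] of suitable cells (e.g. from
#'   [binarize()]).
#' @param mask logical [hn_raster()] aligned with `binary`.
#' @param suitability continuous [hn_raster()] used to compute patch HSI;
#'   must be aligned.
#' @param connectivity 8 (default) or 4.
#' @return A `patch_set`: list with a `patches` data frame (`patch_id`,
#'   `n_cells`, `area_m2`, `hsi`, centroid `x`, `y`), the member-cell indices
#'   per patch (`cells`), grid metadata, and provenance.
#' @export
delineate_patches <- function(binary, mask, suitability, connectivity = 8) {
  stopifnot(is_hn_raster(binary), is_hn_raster(mask), is_hn_raster(suitability))
  check_aligned(binary, mask)
  check_aligned(binary, suitability)
  if (!connectivity %in% c(4L, 8L)) stop_input("connectivity must be 4 or 8")
  ok <- binary$values & mask$values
  ok[is.na(ok)] <- FALSE
  nr <- nrow(ok); nc <- ncol(ok)
  idx <- which(ok)
  empty <- structure(
    list(patches = data.frame(patch_id = integer(), n_cells = integer(),
                              area_m2 = numeric(), hsi = numeric(),
                              x = numeric(), y = numeric()),
         cells = list(), cell_size = binary$cell_size, dim = c(nr, nc),
         xll = binary$xll, yll = binary$yll,
         provenance = list(connectivity = connectivity)),
    class = "patch_set")
  if (!length(idx)) return(empty)
  memb <- label_components(ok, idx, connectivity)
  cells <- split(idx, memb)
  # stable ordering: by smallest member cell index
  cells <- cells[order(vapply(cells, min, numeric(1)))]
  names(cells) <- NULL
  cs <- binary$cell_size
  suit <- suitability$values
  pd <- data.frame(
    patch_id = seq_along(cells),
    n_cells = lengths(cells),
    area_m2 = lengths(cells) * cs^2,
    hsi = vapply(cells, function(cc) mean(suit[cc]), numeric(1))
  )
  xy <- lapply(cells, function(cc) colMeans(cell_xy(binary, cc)))
  pd$x <- vapply(xy, `[[`, numeric(1), "x")
  pd$y <- vapply(xy, `[[`, numeric(1), "y")
  structure(list(patches = pd, cells = cells, cell_size = cs, dim = c(nr, nc),
                 xll = binary$xll, yll = binary$yll,
                 provenance = list(connectivity = connectivity)),
            class = "patch_set")
}

# Connected-component labels of the TRUE cells `idx` of logical matrix `ok`.
label_components <- function(ok, idx, connectivity) {
  nr <- nrow(ok); nc <- ncol(ok)
  map <- integer(nr * nc)
  map[idx] <- seq_along(idx)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  ea <- integer(0); eb <- integer(0)
  for (off in offs) {
    r2 <- row + off[1L]; c2 <- col + off[2L]
    keep <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    n2 <- (c2[keep] - 1L) * nr + r2[keep]
    hit <- map[n2] > 0L
    ea <- c(ea, map[idx[keep]][hit])
    eb <- c(eb, map[n2][hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(ea))
    g <- igraph::add_edges(g, rbind(ea, eb))
  igraph::components(g)$membership
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches on a %d x %d grid (cell %g m, %d-connectivity)\n",
              nrow(x$patches), x$dim[1L], x$dim[2L], x$cell_size,
              x$provenance$connectivity))
  if (nrow(x$patches))
    cat(sprintf("  area: %g - %g m2; HSI: %.3f - %.3f\n",
                min(x$patches$area_m2), max(x$patches$area_m2),
                min(x$patches$hsi), max(x$patches$hsi)))
  invisible(x)
}

#' Number of patches in a patch set
#' @param patches a `patch_set`.
#' @export
n_patches <- function(patches) nrow(patches$patches)

#' Write a patch attribute table as CSV
#' @param patches a `patch_set`.
#' @param path output file.
#' @export
write_patches_csv <- function(patches, path) {
  utils::write.csv(patches$patches, path, row.names = FALSE)
  invisible(path)
}

#' Write patches as a GeoJSON FeatureCollection
#'
#' Each patch is a MultiPolygon of its member-cell squares with `patch_id`,
#' `area_m2` and `hsi` properties.
#'
#' @param patches a `patch_set`.
#' @param path output file.
#' @export
write_patches_geojson <- function(patches, path) {
  nr <- patches$dim[1L]; cs <- patches$cell_size
  feats <- lapply(seq_len(n_patches(patches)), function(i) {
    cc <- patches$cells[[i]]
    col <- (cc - 1L) %/% nr + 1L
    row <- (cc - 1L) %% nr + 1L
    x0 <- patches$xll + (col - 1L) * cs
    y0 <- patches$yll + (nr - row) * cs
    polys <- lapply(seq_along(cc), function(k) {
      ring <- rbind(c(x0[k], y0[k]), c(x0[k] + cs, y0[k]),
                    c(x0[k] + cs, y0[k] + cs), c(x0[k], y0[k] + cs),
                    c(x0[k], y0[k]))
      list(ring)
    })
    list(type = "Feature",
         properties = list(patch_id = patches$patches$patch_id[i],
                           area_m2 = patches$patches$area_m2[i],
                           hsi = patches$patches$hsi[i]),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
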