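#' Per-patch sampling intensity and focal detections
#'
#' Assigns each observation record to the patch containing it (or, if
#' `snap_distance > 0`, to the nearest patch cell within that distance;
#' otherwise the record is dropped).  A visit is a distinct (patch, date)
#' pair with at least one record of any target-group species — the natural
#' sampling-event unit in opportunistic databases; focal detections are the
#' distinct (patch, date) pairs with at least one focal-species record.
#'
#' @param records data frame with `x`, `y`, `date`, `species`.
#' @param patches a `patch_set` sharing the records' coordinate system.
#' @param snap_distance maximum snapping distance in meters (default 0 =
#'   strict point-in-patch).
#' @param focal_species focal species name.
#' @return Data frame with one row per patch: `patch_id`, `visits`,
#'   `focal_detections`.
#' @export
sampling_intensity <- function(records, patches, snap_distance = 0,
                               focal_species = "focal") {
  stopifnot(all(c("x", "y", "date", "species") %in% names(records)))
  nr <- patches$dim[1L]; nc <- patches$dim[2L]
  r <- hn_raster(matrix(0, nr, nc), patches$cell_size, patches$xll,
                 patches$yll)
  owner <- integer(nr * nc)
  for (i in seq_along(patches$cells))
    owner[patches$cells[[i]]] <- patches$patches$patch_id[i]
  cell <- cell_at_xy(r, records$x, records$y)
  pid <- rep(NA_integer_, nrow(records))
  inside <- !is.na(cell)
  pid[inside] <- owner[cell[inside]]
  pid[pid == 0L] <- NA_integer_
  if (snap_distance > 0 && any(is.na(pid)) && n_patches(patches) > 0) {
    all_cells <- unlist(patches$cells, use.names = FALSE)
    all_owner <- rep(patches$patches$patch_id, lengths(patches$cells))
    xy <- cell_xy(r, all_cells)
    for (k in which(is.na(pid))) {
      d2 <- (xy[, 1L] - records$x[k])^2 + (xy[, 2L] - records$y[k])^2
      m <- which.min(d2)
      if (d2[m] <= snap_distance^2) pid[k] <- all_owner[m]
    }
  }
  keep <- !is.na(pid)
  tab <- data.frame(patch_id = patches$patches$patch_id)
  if (any(keep)) {
    ev <- unique(data.frame(patch_id = pid[keep], date = records$date[keep]))
    vis <- table(factor(ev$patch_id, levels = tab$patch_id))
    fk <- keep & records$species == focal_species
    evf <- unique(data.frame(patch_id = pid[fk], date = records$date[fk]))
    foc <- table(factor(evf$patch_id, levels = tab$patch_id))
    tab$visits <- as.integer(vis)
    tab$focal_detections <- as.integer(foc)
  } else {
    tab$visits <- 0L
    tab$focal_detections <- 0L
  }
  tab
}

#' Detection curve: mean focal detections per visit-count stratum
#'
#' For each observed number of visits `v`, the mean number of focal
#' detections among patches visited exactly `v` times.  The plot of this
#' curve is the basis for choosing the sampling-intensity threshold above
#' which a patch without focal detections is treated as a likely absence.
#'
#' @param table data frame from [sampling_intensity()].
#' @return Data frame `visits`, `mean_focal`, `n_patches`, ordered by
#'   `visits`.
#' @export
detection_curve <- function(table) {
  if (!nrow(table)) stop_input("sampling-intensity table is empty")
  strata <- sort(unique(table$visits))
  data.frame(
    visits = strata,
    mean_focal = vapply(strata, function(v)
      mean(table$focal_detections[table$visits == v]), numeric(1)),
    n_patches = vapply(strata, function(v)
      sum(table$visits == v), integer(1))
  )
}

#' Select the sampling-intensity threshold
#'
#' Heuristic reading of the plot-based choice: the smallest visit count at
#' which the cumulative maximum of the detection curve reaches
#' `saturation_fraction` (default 0.9) of the curve's overall maximum.  A
#' manual override is accepted and recorded in the result's provenance
#' attribute — the recommended path when reproducing a specific study.
#'
#' @param curve data frame from [detection_curve()].
#' @param saturation_fraction fraction of the curve maximum to reach,
#'   in (0, 1\].
#' @param manual optional manual threshold; returned as-is with provenance
#'   `"manual"`.
#' @return Integer visit-count threshold with a `provenance` attribute.
#' @export
select_intensity_threshold <- function(curve, saturation_fraction = 0.9,
                                       manual = NULL) {
  if (!is.null(manual)) {
    if (manual < 1) stop_input("manual threshold must be >= 1")
    return(structure(as.integer(manual),
                     provenance = list(rule = "manual")))
  }
  if (saturation_fraction <= 0 || saturation_fraction > 1)
    stop_input("saturation_fraction must be in (0, 1]")
  if (!nrow(curve)) stop_input("detection curve is empty")
  m <- max(curve$mean_focal)
  if (m <= 0)
    stop_input(paste("detection curve is identically zero; the threshold is",
                     "undefined - supply a manual threshold"))
  cm <- cummax(curve$mean_focal)
  v <- curve$visits[which(cm >= saturation_fraction * m)[1L]]
  structure(as.integer(v),
            provenance = list(rule = "cumulative-maximum saturation",
                              saturation_fraction = saturation_fraction,
                              curve_max = m))
}

#' Assign per-patch occurrence-state
#'
#' Presence (1) wherever the focal species was detected at least once;
#' likely absence (0, a target-group absence) where it was never detected
#' despite at least `threshold` visits; unlabeled (`NA`) otherwise.
#' Unlabeled patches are excluded from model fitting but retained in the
#' table.
#'
#' @param table data frame from [sampling_intensity()].
#' @param threshold visit-count threshold (>= 1).
#' @return The input table with an added integer `state` column (1, 0, or
#'   `NA` for unlabeled).
#' @export
assign_occurrence_state <- function(table, threshold) {
  if (threshold < 1) stop_input("threshold must be >= 1")
  state <- rep(NA_integer_, nrow(table))
  state[table$focal_detections >= 1L] <- 1L
  state[table$focal_detections == 0L & table$visits >= threshold] <- 0L
  table$state <- state
  table
}
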