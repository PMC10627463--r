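make_patch_pair <- function() {
  # two single-cell patches at known locations on a 5x5 grid (cell 100 m)
  sel <- matrix(FALSE, 5, 5)
  sel[3, 2] <- TRUE   # centre (150, 250)
  sel[3, 4] <- TRUE   # centre (350, 250)
  rs <- rasters_from_matrix(sel)
  delineate_patches(rs$bin, rs$mask, rs$suit)
}

test_that("visits are distinct patch-date pairs of any target species", {
  ps <- make_patch_pair()
  none <- data.frame(x = numeric(), y = numeric(), date = character(),
                     species = character())
  tab <- sampling_intensity(none, ps)
  expect_equal(tab$visits, c(0, 0))

  # 3 records, 2 species, one patch, one date -> a single visit
  recs <- data.frame(x = c(150, 151, 149), y = c(250, 250, 251),
                     date = "d1", species = c("sp01", "sp02", "sp01"))
  tab <- sampling_intensity(recs, ps)
  expect_equal(tab$visits, c(1, 0))
  expect_equal(tab$focal_detections, c(0, 0))

  # focal detections counted the same way
  recs <- data.frame(x = rep(150, 4), y = rep(250, 4),
                     date = c("d1", "d1", "d2", "d3"),
                     species = c("focal", "sp01", "focal", "sp02"))
  tab <- sampling_intensity(recs, ps)
  expect_equal(tab$visits[1], 3)
  expect_equal(tab$focal_detections[1], 2)
})

test_that("records snap to the nearest patch only within snap_distance", {
  ps <- make_patch_pair()
  # 10 m outside the patch-1 cell edge (cell spans x in [100, 200])
  rec <- data.frame(x = 90, y = 250, date = "d1", species = "sp01")
  expect_equal(sampling_intensity(rec, ps, snap_distance = 0)$visits,
               c(0, 0))
  expect_equal(sampling_intensity(rec, ps, snap_distance = 70)$visits,
               c(1, 0))
  # nearest-centre distance is 60 m here, so 5 m still drops it
  expect_equal(sampling_intensity(rec, ps, snap_distance = 5)$visits,
               c(0, 0))
})

test_that("detection curve averages focal detections per visit stratum", {
  tab <- data.frame(patch_id = 1:2, visits = c(0, 0),
                    focal_detections = c(0, 0))
  expect_equal(detection_curve(tab),
               data.frame(visits = 0, mean_focal = 0, n_patches = 2L))

  tab <- data.frame(patch_id = 1:4, visits = c(1, 1, 2, 2),
                    focal_detections = c(0, 1, 2, 0))
  curve <- detection_curve(tab)
  expect_equal(curve$mean_focal, c(0.5, 1.0))

  # synthetic closed form: stratum mean ~= occupancy * v * p
  ps <- spaced_patchset(n_side = 35, seed = 3)
  occ <- data.frame(patch_id = ps$patches$patch_id,
                    occupied = rep(c(TRUE, FALSE), length.out = n_patches(ps)))
  p <- 0.6
  obs <- generate_observations(
    ps, occ, sampling_config(mean_visits_per_patch = 4,
                             detection_prob_per_visit = p, seed = 5))
  tab <- sampling_intensity(obs, ps)
  curve <- detection_curve(tab)
  for (v in 1:4) {
    row <- curve[curve$visits == v, ]
    if (!nrow(row) || row$n_patches < 150) next
    expected <- 0.5 * v * p     # half the patches occupied
    se <- sqrt(v * p * (1 - p) / row$n_patches) + 0.05
    expect_lt(abs(row$mean_focal - expected), 3 * se)
  }
})

test_that("intensity threshold saturates the cumulative detection curve", {
  curve <- data.frame(visits = 1:5, mean_focal = c(0.2, 0.5, 0.9, 1, 1),
                      n_patches = rep(10L, 5))
  expect_equal(as.integer(select_intensity_threshold(curve, 0.9)), 3L)
  # constant positive curve: smallest observed visit count
  const <- data.frame(visits = 2:6, mean_focal = rep(0.4, 5),
                      n_patches = rep(5L, 5))
  expect_equal(as.integer(select_intensity_threshold(const)), 2L)
  # manual override wins and records provenance
  manual <- select_intensity_threshold(curve, manual = 4)
  expect_equal(as.integer(manual), 4L)
  expect_equal(attr(manual, "provenance")$rule, "manual")
  # all-zero curve is undefined
  zero <- data.frame(visits = 1:3, mean_focal = rep(0, 3),
                     n_patches = rep(5L, 3))
  expect_error(select_intensity_threshold(zero), "manual")
})

test_that("occurrence-state labels partition presence/absence/unlabeled", {
  tab <- data.frame(patch_id = 1:3,
                    visits = c(1, 6, 3),
                    focal_detections = c(2, 0, 0))
  occ <- assign_occurrence_state(tab, 5)
  expect_equal(occ$state, c(1L, 0L, NA))
  expect_error(assign_occurrence_state(tab, 0), "threshold")

  # monotone label erosion: raising the threshold only moves 0 -> unlabeled
  set.seed(1)
  tab <- data.frame(patch_id = 1:200,
                    visits = rpois(200, 4),
                    focal_detections = rbinom(200, 3, 0.3))
  prev <- assign_occurrence_state(tab, 1)$state
  for (thr in 2:8) {
    cur <- assign_occurrence_state(tab, thr)$state
    expect_true(all(which(cur == 0) %in% which(prev == 0)))
    expect_identical(which(cur == 1), which(prev == 1))
    prev <- cur
  }
})

test_that("perfect detection yields zero label noise", {
  ps <- spaced_patchset(n_side = 20, seed = 9)
  occ <- data.frame(patch_id = ps$patches$patch_id,
                    occupied = rep(c(TRUE, FALSE), length.out = n_patches(ps)))
  obs <- generate_observations(
    ps, occ, sampling_config(detection_prob_per_visit = 1, seed = 2))
  tab <- sampling_intensity(obs, ps)
  st <- assign_occurrence_state(tab, 3)
  truth <- occ$occupied[match(st$patch_id, occ$patch_id)]
  expect_true(all(truth[st$state == 1 & !is.na(st$state)]))
  expect_true(all(!truth[!is.na(st$state) & st$state == 0]))
  # every occupied patch with >= 1 visit is labelled present
  expect_true(all(st$state[truth & st$visits >= 1] == 1))
})
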