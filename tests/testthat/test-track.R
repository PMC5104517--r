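test_that("identical centroid sets link as the identity with zero cost", {
  a <- data.frame(x_um = c(10, 20, 30), y_um = c(5, 5, 5))
  lk <- link_frames(a, a, max_displacement_um = 2)
  expect_identical(lk$matches$i, lk$matches$j)
  expect_equal(sum(lk$matches$dist_um), 0)
  expect_length(lk$unmatched_a, 0)
})

test_that("records displaced beyond the gate stay unmatched on both sides", {
  a <- data.frame(x_um = c(10, 50), y_um = c(0, 0))
  b <- data.frame(x_um = c(10.3, 80), y_um = c(0, 0))
  lk <- link_frames(a, b, max_displacement_um = 2)
  expect_identical(lk$matches$i, 1L)
  expect_identical(lk$unmatched_a, 2L)
  expect_identical(lk$unmatched_b, 2L)
  # conservation: matches + unmatched = records, on both frames
  expect_identical(nrow(lk$matches) + length(lk$unmatched_a), nrow(a))
  expect_identical(nrow(lk$matches) + length(lk$unmatched_b), nrow(b))
  # empty inputs are allowed
  lk0 <- link_frames(a[0, ], b, 2)
  expect_identical(nrow(lk0$matches), 0L)
  expect_identical(lk0$unmatched_b, 1:2)
})

test_that("linking equals exhaustive minimum-cost matching", {
  for (rep in 1:12) {
    set.seed(rep)
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- cbind(runif(na, 0, 12), runif(na, 0, 12))
    b <- cbind(runif(nb, 0, 12), runif(nb, 0, 12))
    gate <- 5
    lk <- link_frames(data.frame(x_um = a[, 1], y_um = a[, 2]),
                      data.frame(x_um = b[, 1], y_um = b[, 2]), gate)
    oracle <- brute_force_matching(a, b, gate)
    expect_identical(nrow(lk$matches), oracle$card)
    expect_equal(sum(lk$matches$dist_um^2), oracle$cost, tolerance = 1e-9)
  }
})

test_that("gapless detections give one track per cell with true endpoints", {
  tl <- gt_run("control", 7)
  gt <- tl$cells
  rec <- data.frame(frame = gt$frame, x_um = gt$x_um, y_um = gt$y_um,
                    cell_id = gt$cell_id)
  tr <- build_tracks(rec, max_displacement_um = 1.5, max_gap = 1)
  # zero identity switches: every track follows a single ground-truth cell
  purity <- tapply(tr$points$cell_id, tr$points$track_id,
                   function(ids) length(unique(ids)))
  expect_true(all(purity == 1))
  # >= 99% of consecutive ground-truth links recovered
  o <- order(rec$cell_id, rec$frame)
  same_cell <- diff(rec$cell_id[o]) == 0 & diff(rec$frame[o]) == 1
  same_track <- diff(tr$points$track_id[order(tr$points$cell_id,
                                              tr$points$frame)]) == 0
  expect_gte(mean(same_track[same_cell]), 0.99)
  # almost every cell forms a single unfragmented track with true endpoints
  tracks_per_cell <- tapply(tr$points$track_id, tr$points$cell_id,
                            function(tk) length(unique(tk)))
  expect_gte(mean(tracks_per_cell == 1), 0.99)
  whole <- names(tracks_per_cell)[tracks_per_cell == 1]
  first_gt <- tapply(gt$frame, gt$cell_id, min)
  p <- tr$points[order(tr$points$track_id, tr$points$frame), ]
  first <- p[!duplicated(p$track_id), ]
  keep <- as.character(first$cell_id) %in% whole
  expect_true(all(first$frame[keep] ==
                    first_gt[as.character(first$cell_id[keep])]))
})

test_that("gap closing bridges a single missed detection", {
  rec <- data.frame(frame = c(0, 1, 2, 4, 5),
                    x_um = 10 + c(0, .1, .2, .3, .4), y_um = 5)
  tr1 <- build_tracks(rec, max_displacement_um = 1.5, max_gap = 1)
  expect_identical(nrow(tr1$summary), 1L)
  expect_identical(tr1$summary$appearance_frame, 0)
  expect_identical(tr1$summary$disappearance_frame, 5)
  tr0 <- build_tracks(rec, max_displacement_um = 1.2, max_gap = 0)
  expect_identical(nrow(tr0$summary), 2L)
})

test_that("a terminal track with two nearby appearances is a division", {
  rec <- rbind(
    data.frame(frame = 0:3, x_um = 50, y_um = 50, label = 1),       # parent
    data.frame(frame = 4:8, x_um = 46, y_um = 50, label = 2),       # d1
    data.frame(frame = 4:8, x_um = 54, y_um = 50.2, label = 3))     # d2
  tr <- build_tracks(rec, max_displacement_um = 1.5, max_gap = 1)
  tr <- annotate_divisions(tr, split_radius_um = 6, split_window_frames = 1)
  expect_identical(nrow(tr$lineage), 1L)
  expect_equal(tr$lineage$split_frame, 3)
  daughters <- sort(c(tr$lineage$daughter1, tr$lineage$daughter2))
  parent <- tr$lineage$parent_track_id
  expect_identical(sum(tr$summary$parent_track_id == parent, na.rm = TRUE), 2L)
  expect_false(parent %in% daughters)
})

test_that("terminations without nearby appearances are plain track ends", {
  rec <- rbind(data.frame(frame = 0:3, x_um = 50, y_um = 50),
               data.frame(frame = 0:8, x_um = 120, y_um = 120))
  tr <- annotate_divisions(build_tracks(rec, 1.2, 1), 6, 1)
  expect_identical(nrow(tr$lineage), 0L)
})

test_that("with three candidates the closest pair becomes the daughters", {
  rec <- rbind(
    data.frame(frame = 0:3, x_um = 50, y_um = 50),
    data.frame(frame = 4:8, x_um = 46, y_um = 50),     # dist 4
    data.frame(frame = 4:8, x_um = 54, y_um = 50),     # dist 4
    data.frame(frame = 4:8, x_um = 50, y_um = 55.5))   # dist 5.5, excluded
  tr <- annotate_divisions(build_tracks(rec, 1.2, 1), 6, 1)
  expect_identical(nrow(tr$lineage), 1L)
  d <- tr$points[tr$points$track_id %in%
                   c(tr$lineage$daughter1, tr$lineage$daughter2), ]
  expect_setequal(unique(d$x_um), c(46, 54))
})

test_that("simulated mitoses are recovered as parent-with-two-daughter splits", {
  # ground-truth positions (no rendering), default jitter, one full movie
  tl <- gt_run("control", 7)
  gt <- tl$cells
  rec <- data.frame(frame = gt$frame, x_um = gt$x_um, y_um = gt$y_um)
  tr <- build_tracks(rec, 1.5, 1)
  tr <- annotate_divisions(tr, split_radius_um = 6, split_window_frames = 1)
  n_gt <- sum(tl$events$type == "mitosis" &
                tl$events$time_h <= max(gt$time_h))
  expect_identical(nrow(tr$lineage), n_gt)
})
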