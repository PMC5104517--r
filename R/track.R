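# Single-cell tracking: optimal frame-to-frame linking (min-cost bipartite
# matching with a displacement gate), gap closing, and geometric division
# (track-split) annotation. Distances are in um so gates are physical.

# Maximum-cardinality, minimum-cost bipartite matching on gated candidate
# pairs. Costs are squared displacements; edges above the gate are excluded.
# Implemented as maximum-weight bipartite matching with weights
# BIG - cost, BIG large enough that cardinality dominates cost.
.match_gated <- function(ax, ay, bx, by, gate_um) {
  na <- length(ax); nb <- length(bx)
  empty <- list(matches = data.frame(i = integer(0), j = integer(0),
                                     dist_um = numeric(0)),
                unmatched_a = seq_len(na), unmatched_b = seq_len(nb))
  if (na == 0 || nb == 0) return(empty)
  d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
  cand <- which(d2 <= gate_um^2, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  cost <- d2[cand]
  big <- gate_um^2 * (min(na, nb) + 1)
  g <- igraph::make_empty_graph(n = na + nb, directed = FALSE)
  g <- igraph::add_edges(g, rbind(cand[, 1], na + cand[, 2]))
  types <- c(rep(FALSE, na), rep(TRUE, nb))
  m <- igraph::max_bipartite_match(g, types = types, weights = big - cost)
  mt <- m$matching[seq_len(na)]
  i <- which(!is.na(mt))
  j <- as.integer(mt[i]) - na
  list(matches = data.frame(i = i, j = j,
                            dist_um = sqrt(d2[cbind(i, j)])),
       unmatched_a = setdiff(seq_len(na), i),
       unmatched_b = setdiff(seq_len(nb), j))
}

#' Link nuclei between two consecutive frames
#'
#' One-to-one assignment minimizing total squared centroid displacement
#' (optimal bipartite matching), with gating: pairs farther apart than
#' `max_displacement_um` are forbidden. Records left unmatched are
#' disappearances (in `a`) or appearances (in `b`).
#'
#' @param records_a,records_b Data frames with `x_um`, `y_um` columns for
#'   the earlier and later frame.
#' @param max_displacement_um Gate distance (um).
#' @return A list with `matches` (data frame `i`, `j`, `dist_um`; row
#'   indices into `records_a` / `records_b`), `unmatched_a`, `unmatched_b`.
#' @export
link_frames <- function(records_a, records_b, max_displacement_um) {
  stopifnot(max_displacement_um > 0)
  .match_gated(records_a$x_um, records_a$y_um,
               records_b$x_um, records_b$y_um, max_displacement_um)
}

#' Build single-cell tracks from per-frame nucleus records
#'
#' Chains optimal frame-to-frame assignments into tracks, then closes gaps:
#' a track disappearing at frame `f` followed by a track appearing at frame
#' `f + g + 1` (`g <= max_gap`) within a widened gate
#' `max_displacement_um * (g + 1)` is bridged into one track.
#'
#' @param records Data frame with `frame` (0-based), `x_um`, `y_um` and
#'   optionally `label`; typically [measure_nuclei()] output over all frames
#'   with pixel coordinates converted via [px_to_um()].
#' @param max_displacement_um Linking gate (um).
#' @param max_gap Maximum number of skipped frames bridged.
#' @return An `sc_tracks` list: `points` (the records plus `track_id`,
#'   ordered by track and frame) and `summary` (`track_id`,
#'   `appearance_frame`, `disappearance_frame`, `n_points`).
#' @export
build_tracks <- function(records, max_displacement_um = 1.5, max_gap = 1) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(records)),
            max_gap >= 0)
  records <- records[order(records$frame), , drop = FALSE]
  rownames(records) <- NULL
  n <- nrow(records)
  track <- integer(n)
  ## link numerically consecutive frames only: records missing in an
  ## intermediate frame create a gap that only gap closing may bridge
  frames <- seq(min(records$frame), max(records$frame))
  idx_by_frame <- split(seq_len(n), factor(records$frame, levels = frames))
  next_id <- 1L
  for (k in seq_along(frames)) {
    ib <- idx_by_frame[[k]]
    if (!length(ib)) next
    ia <- if (k > 1) idx_by_frame[[k - 1]] else integer(0)
    lk <- .match_gated(records$x_um[ia], records$y_um[ia],
                       records$x_um[ib], records$y_um[ib],
                       max_displacement_um)
    if (nrow(lk$matches))
      track[ib[lk$matches$j]] <- track[ia[lk$matches$i]]
    nb_new <- lk$unmatched_b
    if (length(nb_new)) {
      track[ib[nb_new]] <- next_id + seq_along(nb_new) - 1L
      next_id <- next_id + length(nb_new)
    }
  }

  ## gap closing
  if (max_gap > 0) {
    for (g in seq_len(max_gap)) {
      gate <- max_displacement_um * (g + 1)
      summ <- .track_summary(records, track)
      for (f in frames) {
        ends <- summ[summ$disappearance_frame == f, ]
        starts <- summ[summ$appearance_frame == f + g + 1, ]
        if (!nrow(ends) || !nrow(starts)) next
        lk <- .match_gated(ends$x_end, ends$y_end,
                           starts$x_start, starts$y_start, gate)
        if (nrow(lk$matches)) {
          for (r in seq_len(nrow(lk$matches))) {
            old <- starts$track_id[lk$matches$j[r]]
            new <- ends$track_id[lk$matches$i[r]]
            track[track == old] <- new
          }
          summ <- .track_summary(records, track)
        }
      }
    }
  }

  ## renumber 1..K in order of appearance
  summ <- .track_summary(records, track)
  ord <- order(summ$appearance_frame, summ$x_start, summ$y_start)
  remap <- integer(max(summ$track_id))
  remap[summ$track_id[ord]] <- seq_along(ord)
  track <- remap[track]
  records$track_id <- track
  records <- records[order(records$track_id, records$frame), , drop = FALSE]
  rownames(records) <- NULL
  summ <- .track_summary(records, records$track_id)
  summ <- summ[order(summ$track_id), ]
  rownames(summ) <- NULL
  structure(list(points = records,
                 summary = data.frame(track_id = summ$track_id,
                                      appearance_frame = summ$appearance_frame,
                                      disappearance_frame = summ$disappearance_frame,
                                      n_points = summ$n_points),
                 lineage = NULL,
                 max_displacement_um = max_displacement_um,
                 max_gap = max_gap),
            class = "sc_tracks")
}

.track_summary <- function(records, track) {
  ids <- sort(unique(track[track > 0]))
  pos <- match(ids, ids)
  first <- rep(NA_integer_, length(ids)); last <- first
  xs <- numeric(length(ids)); ys <- xs; xe <- xs; ye <- xs
  o <- order(track, records$frame)
  tr <- track[o]; fr <- records$frame[o]
  x <- records$x_um[o]; y <- records$y_um[o]
  starts <- which(!duplicated(tr))
  ends <- c(starts[-1] - 1L, length(tr))
  data.frame(track_id = tr[starts],
             appearance_frame = fr[starts],
             disappearance_frame = fr[ends],
             n_points = ends - starts + 1L,
             x_start = x[starts], y_start = y[starts],
             x_end = x[ends], y_end = y[ends])
}

#' Annotate candidate division (track-split) events
#'
#' A track terminating at frame `f` is marked as a parent when at least two
#' new tracks appear within `split_radius_um` of its terminal centroid in
#' frames `(f, f + split_window_frames]`. The two candidates with the
#' smallest summed distance become the daughters; remaining ties are broken
#' by lower track id. Each appearing track can be the daughter of at most
#' one parent.
#'
#' @param tracks An `sc_tracks` object from [build_tracks()].
#' @param split_radius_um Search radius around the terminal centroid (um).
#' @param split_window_frames Number of frames searched after termination.
#' @return The `sc_tracks` object with `summary$parent_track_id` filled for
#'   daughters and a `lineage` data frame (`parent_track_id`, `daughter1`,
#'   `daughter2`, `split_frame`).
#' @export
annotate_divisions <- function(tracks, split_radius_um = 4,
                               split_window_frames = 1) {
  stopifnot(inherits(tracks, "sc_tracks"))
  summ <- .track_summary(tracks$points, tracks$points$track_id)
  summ <- summ[order(summ$track_id), ]
  last_frame <- max(summ$disappearance_frame)
  parent_of <- rep(NA_integer_, nrow(summ))
  lineage <- list()
  cand_taken <- rep(FALSE, nrow(summ))
  parents <- summ[summ$disappearance_frame < last_frame, ]
  parents <- parents[order(parents$disappearance_frame, parents$track_id), ]
  for (r in seq_len(nrow(parents))) {
    f <- parents$disappearance_frame[r]
    cand <- which(summ$appearance_frame > f &
                    summ$appearance_frame <= f + split_window_frames &
                    !cand_taken & summ$track_id != parents$track_id[r])
    if (length(cand) < 2) next
    d <- sqrt((summ$x_start[cand] - parents$x_end[r])^2 +
                (summ$y_start[cand] - parents$y_end[r])^2)
    ok <- d <= split_radius_um
    cand <- cand[ok]; d <- d[ok]
    if (length(cand) < 2) next
    o <- order(d, summ$track_id[cand])
    pick <- cand[o[1:2]]
    cand_taken[pick] <- TRUE
    parent_of[pick] <- parents$track_id[r]
    lineage[[length(lineage) + 1L]] <- data.frame(
      parent_track_id = parents$track_id[r],
      daughter1 = min(summ$track_id[pick]),
      daughter2 = max(summ$track_id[pick]),
      split_frame = f)
  }
  tracks$summary$parent_track_id <- parent_of[match(tracks$summary$track_id,
                                                    summ$track_id)]
  tracks$lineage <- if (length(lineage)) do.call(rbind, lineage) else
    data.frame(parent_track_id = integer(0), daughter1 = integer(0),
               daughter2 = integer(0), split_frame = integer(0))
  tracks
}

#' @export
print.sc_tracks <- function(x, ...) {
  cat(sprintf("<sc_tracks> %d tracks over frames %d..%d (%d points)%s\n",
              nrow(x$summary), min(x$points$frame), max(x$points$frame),
              nrow(x$points),
              if (!is.null(x$lineage))
                sprintf(", %d divisions", nrow(x$lineage)) else ""))
  invisible(x)
}
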