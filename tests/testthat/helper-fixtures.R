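# Shared fixtures and independent oracles used across the test files.

# Construct a monolayer state directly (bypassing the initializer) so that
# rendering and segmentation can be tested on fully controlled geometry.
make_state <- function(x, y, phase = rep("G0", length(x)),
                       red = as.numeric(phase %in% c("G0", "G1")),
                       green = as.numeric(phase %in% c("S", "G2")),
                       activity = rep(1, length(x)),
                       field = c(200, 200), params = sim_params()) {
  n <- length(x)
  cells <- data.frame(cell_id = seq_len(n), x = x, y = y,
                      phase = as.character(phase),
                      phase_entry = rep(0, n), tau_g1 = rep(NA_real_, n),
                      trigger = rep("basal", n),
                      a0 = activity, committed = rep(FALSE, n),
                      red = red, green = green, activity = activity,
                      stringsAsFactors = FALSE)
  structure(list(time = 0, cells = cells, field_origin_um = c(0, 0),
                 field_size_um = field, events = NULL, maturing = FALSE,
                 stretch_applied = FALSE, n_initial = n,
                 next_id = n + 1L, params = params, seed = 0L,
                 rng = {set.seed(0); get(".Random.seed", globalenv())}),
            class = "sc_monolayer")
}

quiet_ip <- function(fov = c(200, 200), ...)
  imaging_params(fov_um = fov, noise = FALSE, ...)

# Exhaustive maximum-cardinality / minimum-cost gated matching, by recursion
# over all partial injective assignments. Independent of the package's
# bipartite-matching route; feasible for n <= 6.
brute_force_matching <- function(a, b, gate) {
  na <- nrow(a); nb <- nrow(b)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  best <- list(card = -1L, cost = Inf)
  recurse <- function(i, used, card, cost) {
    if (i > na) {
      if (card > best$card || (card == best$card && cost < best$cost - 1e-12))
        best <<- list(card = card, cost = cost)
      return(invisible())
    }
    recurse(i + 1L, used, card, cost)        # leave a_i unmatched
    for (j in seq_len(nb)) {
      if (!used[j] && d2[i, j] <= gate^2) {
        used[j] <- TRUE
        recurse(i + 1L, used, card + 1L, cost + d2[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nb), 0L, 0)
  best
}

# Brute-force k-nearest-neighbour mean distances from the full distance
# matrix (the all-pairs oracle for dnn7).
brute_force_dnn <- function(xy, k = 7) {
  n <- nrow(xy)
  sapply(seq_len(n), function(i) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)[-i]
    mean(sort(d)[seq_len(k)])
  })
}

# Brute-force two-sample KS statistic: maximum ECDF gap over pooled points.
brute_force_ks <- function(a, b) {
  pool <- sort(unique(c(a, b)))
  max(abs(vapply(pool, function(t) mean(a <= t) - mean(b <= t), 0)))
}

# Hexagonal lattice of spacing d with at least `rings` full rings around a
# central point; returns the points and the index of interior points (those
# whose 7th neighbour is at lattice distance sqrt(3)*d).
hex_lattice <- function(d = 30, nx = 9, ny = 9) {
  pts <- do.call(rbind, lapply(seq_len(ny), function(j) {
    off <- if (j %% 2 == 0) d / 2 else 0
    cbind(off + d * seq_len(nx), d * sqrt(3) / 2 * j)
  }))
  interior <- pts[, 1] > 2.1 * d & pts[, 1] < max(pts[, 1]) - 2.1 * d &
    pts[, 2] > 2.1 * d & pts[, 2] < max(pts[, 2]) - 2.1 * d
  list(points = pts, interior = which(interior))
}
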