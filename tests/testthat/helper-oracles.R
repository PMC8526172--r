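# Independent oracles used across the suite.

# Geodesic distance from the line x = x0 to point (px, py) around the open
# disc (cx, cy, R), by Dijkstra-style enumeration over a dense graph of
# circle-boundary nodes: enter horizontally at a visible boundary node,
# follow exact arc lengths, leave on a straight visible segment. Converges
# to the true geodesic as K grows; independent of the closed-form
# tangent-arc construction it is used to check.
geodesic_graph_oracle <- function(px, py, cx, cy, R, x0 = 0, K = 1500) {
  th <- seq(0, 2 * pi, length.out = K + 1)[-(K + 1)]
  bx <- cx + R * cos(th)
  by <- cy + R * sin(th)

  seg_crosses_disc <- function(x1, y1, x2, y2) {
    # strict interior intersection of segment with the disc
    dx <- x2 - x1; dy <- y2 - y1
    tt <- pmin(pmax(-((x1 - cx) * dx + (y1 - cy) * dy) / (dx^2 + dy^2), 0), 1)
    qx <- x1 + tt * dx - cx; qy <- y1 + tt * dy - cy
    sqrt(qx^2 + qy^2) < R - 1e-9
  }

  # direct horizontal path
  best <- if (!seg_crosses_disc(x0, py, px, py)) px - x0 else Inf

  # entry nodes: horizontal from the line must not cross the interior
  entry_ok <- !seg_crosses_disc(x0, by, bx, by)
  # exit nodes: straight segment to P must not cross the interior
  exit_ok <- !seg_crosses_disc(bx, by, px, py)
  if (any(entry_ok) && any(exit_ok)) {
    d_entry <- bx - x0
    d_exit <- sqrt((bx - px)^2 + (by - py)^2)
    ths <- th
    for (e in which(entry_ok)) {
      dth <- abs(ths - ths[e])
      arc <- R * pmin(dth, 2 * pi - dth)
      tot <- d_entry[e] + arc[exit_ok] + d_exit[exit_ok]
      best <- min(best, tot)
    }
  }
  best
}

# far-distance construction behind a disc obstacle: envelope of the planar
# front and two radial waves from (cx, cy +/- R); returns front position
# at row y for planar front position xp = x0 + v t
farfield_front_x <- function(y, xp, cx, cy, R, x0 = 0) {
  r <- xp - x0 - (cx - x0)             # wave radius = distance past centre
  cand <- -Inf
  for (s in c(-1, 1)) {
    dy <- y - (cy + s * R)
    if (abs(dy) < r) cand <- max(cand, cx + sqrt(r^2 - dy^2))
  }
  if (abs(y - cy) >= R) cand <- max(cand, xp)
  cand
}

# deterministic seeds for loops
oracle_seeds <- function(n, base = 7777) base + seq_len(n) * 13

# shorthand for the (internal) density <-> area-fraction inversion
density_for <- function(phi, template) {
  frontscape:::density_for_area_fraction(phi, template)
}
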