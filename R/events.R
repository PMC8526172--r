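# --- segment/rhombus visibility helpers -------------------------------------

# Does the open segment p1-p2 pass through the interior of any rhombus?
# Rhombi are mapped to axis-aligned squares by u = dx/a + dy/b,
# v = dx/a - dy/b; slab clipping then gives the parametric overlap with the
# open square |u| < 1, |v| < 1. Touching the boundary (e.g. grazing a
# corner or an edge) does not count as crossing.
segment_blocked <- function(p1, p2, centers, a, b, Ly, periodic = TRUE,
                            eps = 1e-9) {
  if (nrow(centers) == 0) return(FALSE)
  offs <- if (periodic) c(-Ly, 0, Ly) else 0
  for (off in offs) {
    cx <- centers[, 1]; cy <- centers[, 2] + off
    # transform endpoints relative to each centre
    u1 <- (p1[1] - cx) / a + (p1[2] - cy) / b
    v1 <- (p1[1] - cx) / a - (p1[2] - cy) / b
    u2 <- (p2[1] - cx) / a + (p2[2] - cy) / b
    v2 <- (p2[1] - cx) / a - (p2[2] - cy) / b
    du <- u2 - u1; dv <- v2 - v1
    t0 <- rep(0, length(cx)); t1 <- rep(1, length(cx))
    ok <- rep(TRUE, length(cx))
    for (comp in list(list(p = u1, d = du), list(p = v1, d = dv))) {
      p <- comp$p; d <- comp$d
      par <- abs(d) < eps
      ok <- ok & !(par & abs(p) >= 1 - eps)   # parallel outside the slab
      ta <- (-1 - p) / ifelse(par, 1, d)
      tb <- (1 - p) / ifelse(par, 1, d)
      lo <- pmin(ta, tb); hi <- pmax(ta, tb)
      lo[par] <- 0; hi[par] <- 1
      t0 <- pmax(t0, lo); t1 <- pmin(t1, hi)
    }
    if (any(ok & (t1 - t0 > eps))) return(TRUE)
  }
  FALSE
}

rhombus_corners <- function(fs) {
  n <- nrow(fs$centers)
  a <- fs$template$a; b <- fs$template$b
  cx <- rep(fs$centers[, 1], each = 4)
  cy <- rep(fs$centers[, 2], each = 4)
  dx <- rep(c(-a, a, 0, 0), n)
  dy <- rep(c(0, 0, -b, b), n)
  cbind(x = cx + dx, y = cy + dy)
}

#' Activation times of rhombus corners by corner scattering
#'
#' Each corner of a rhombus-shaped obstacle acts as a scattering point from
#' which a radial wave originates once the front reaches it. Arrival times
#' are computed by Dijkstra over the visibility graph whose nodes are the
#' corners (including periodic transverse images) plus the planar source at
#' x = 0: edges carry Euclidean distance / v1 and exist when the connecting
#' segment does not cross any obstacle interior. Enclosed corners get
#' `Inf`.
#'
#' @param fs a [feature_set()] of rhombus obstacles.
#' @param v1 background speed.
#' @return Object of class `event_state` with per-corner `origins`,
#'   activation times `t0`, radius offsets (0 for corners), and the
#'   landscape.
#' @export
corner_arrival_times <- function(fs, v1 = 1) {
  stopifnot(inherits(fs, "feature_set"))
  if (fs$template$shape != "rhombus" || fs$template$kind != "obstacle") {
    stop("corner scattering applies to rhombus obstacles")
  }
  a <- fs$template$a; b <- fs$template$b
  Ly <- fs$domain$Ly
  periodic <- fs$domain$periodic_y
  base <- rhombus_corners(fs)
  offs <- if (periodic) c(-Ly, 0, Ly) else 0
  nodes <- do.call(rbind, lapply(offs, function(o) {
    cbind(base[, 1], base[, 2] + o)
  }))
  nb <- nrow(base)
  nn <- nrow(nodes)

  # planar-source times: direct horizontal ray when unobstructed
  t <- rep(Inf, nn)
  for (i in seq_len(nn)) {
    p <- nodes[i, ]
    if (!segment_blocked(c(0, p[2]), p, fs$centers, a, b, Ly, periodic)) {
      t[i] <- p[1] / v1
    }
  }

  # pairwise visibility distances (dense Dijkstra; corner counts are small)
  D <- matrix(Inf, nn, nn)
  for (i in seq_len(nn - 1)) {
    for (j in (i + 1):nn) {
      if (!segment_blocked(nodes[i, ], nodes[j, ], fs$centers, a, b, Ly,
                           periodic)) {
        D[i, j] <- D[j, i] <-
          sqrt(sum((nodes[i, ] - nodes[j, ])^2)) / v1
      }
    }
  }
  done <- rep(FALSE, nn)
  for (k in seq_len(nn)) {
    i <- which(!done)[which.min(t[!done])]
    if (!length(i) || !is.finite(t[i])) break
    done[i] <- TRUE
    relax <- t[i] + D[i, ]
    upd <- !done & relax < t
    t[upd] <- relax[upd]
  }

  mid <- if (periodic) nb + seq_len(nb) else seq_len(nb)
  structure(list(origins = base, t0 = t[mid], r_offset = rep(0, nb),
                 fs = fs, v1 = v1, v2 = 0, kind = "obstacle"),
            class = "event_state")
}

#' @export
print.event_state <- function(x, ...) {
  cat(sprintf("<event_state> %s landscape, %d waves (%d activated)\n",
              x$kind, length(x$t0), sum(is.finite(x$t0))))
  invisible(x)
}

#' Event-based front around rhombus obstacles
#'
#' The front at time `t` is, per transverse row, the maximum of the
#' unperturbed planar front and the reach of every activated corner wave
#' whose straight segment to the candidate point is unobstructed; the
#' planar contribution is clipped at the first obstacle on each row.
#'
#' @param state an `event_state` from [corner_arrival_times()].
#' @param t time.
#' @param n_rows number of transverse rows evaluated.
#' @return Data frame with `y` and front position `x` (NA where blocked).
#' @export
obstacle_event_front <- function(state, t, n_rows = 200) {
  fs <- state$fs
  a <- fs$template$a; b <- fs$template$b
  Ly <- fs$domain$Ly
  v1 <- state$v1
  ys <- (seq_len(n_rows) - 0.5) * Ly / n_rows
  xf <- rep(NA_real_, n_rows)

  # planar contribution: v1 t, clipped at the first rhombus on the row
  for (r in seq_len(n_rows)) {
    x_pl <- v1 * t
    if (nrow(fs$centers) > 0) {
      offs <- if (fs$domain$periodic_y) c(-Ly, 0, Ly) else 0
      for (off in offs) {
        dy <- abs(ys[r] - (fs$centers[, 2] + off))
        cut <- dy < b
        if (any(cut)) {
          # left entry point of each rhombus intersected by this row
          x_enter <- fs$centers[cut, 1] - a * (1 - dy[cut] / b)
          ahead <- x_enter >= 0
          if (any(ahead)) x_pl <- min(x_pl, min(x_enter[ahead]))
        }
      }
    }
    xf[r] <- x_pl
  }

  act <- which(is.finite(state$t0) & state$t0 < t)
  offs <- if (fs$domain$periodic_y) c(-Ly, 0, Ly) else 0
  for (i in act) {
    r_i <- v1 * (t - state$t0[i]) + state$r_offset[i]
    if (r_i <= 0) next
    for (off in offs) {
      oy <- state$origins[i, 2] + off
      dy <- ys - oy
      sel <- which(abs(dy) < r_i)
      for (r in sel) {
        xc <- state$origins[i, 1] + sqrt(r_i^2 - dy[r]^2)
        if (xc <= xf[r] && !is.na(xf[r])) next
        p <- c(xc, ys[r])
        if (points_in_features(fs, p[1], p[2])) next
        if (!segment_blocked(c(state$origins[i, 1], oy), p, fs$centers,
                             a, b, Ly, fs$domain$periodic_y)) {
          xf[r] <- max(xf[r], xc, na.rm = TRUE)
        }
      }
    }
  }
  data.frame(y = ys, x = xf)
}

#' Activation cascade for circular hotspots
#'
#' Each hotspot is activated at the earliest moment any existing wavefront
#' reaches its boundary: the planar front at `(x_c - R)/v1`, or a previous
#' radial wave when its radius reaches the nearest boundary point. On
#' activation a radial wave starts from the hotspot centre with radius law
#' `r(t) = v1 (t - t0) + R (1 - 2 v1/v2)`, chosen so that an isolated
#' hotspot reproduces the far-distance bulge r = d + k,
#' `k = 2 R (1 - v1/v2)`. Waves travel between features at `v1`
#' (intervening hotspots do not accelerate them), which makes the
#' construction a documented underestimate of the true front.
#'
#' @param fs a [feature_set()] of circular hotspots.
#' @param v1 background speed.
#' @param v2 speed inside hotspots (> v1).
#' @return An `event_state` with per-hotspot activation times.
#' @export
hotspot_activation_cascade <- function(fs, v1 = 1, v2) {
  stopifnot(inherits(fs, "feature_set"))
  if (fs$template$kind != "hotspot" || fs$template$a != fs$template$b) {
    stop("the cascade applies to circular hotspots")
  }
  if (v2 <= v1) stop("hotspots require v2 > v1 (gamma > 1)")
  R <- fs$template$a
  Ly <- fs$domain$Ly
  n <- nrow(fs$centers)
  r_off <- R * (1 - 2 * v1 / v2)
  if (n == 0) {
    return(structure(list(origins = fs$centers, t0 = numeric(0),
                          r_offset = numeric(0), fs = fs, v1 = v1, v2 = v2,
                          R = R, kind = "hotspot"),
                     class = "event_state"))
  }
  # periodic centre distances
  dy <- abs(outer(fs$centers[, 2], fs$centers[, 2], `-`))
  if (fs$domain$periodic_y) dy <- pmin(dy, Ly - dy)
  dx <- outer(fs$centers[, 1], fs$centers[, 1], `-`)
  dist <- sqrt(dx^2 + dy^2)

  t0 <- unname(fs$centers[, 1] - R) / v1   # tentative: planar activation
  done <- rep(FALSE, n)
  for (k in seq_len(n)) {
    i <- which(!done)[which.min(t0[!done])]
    done[i] <- TRUE
    # touch-to-touch increment along the centre-to-centre path: cross
    # hotspot i at v2, the gap at v1, for overlapping pairs (d < 2R) the
    # connecting segment lies inside the union and is crossed at v2
    d_i <- dist[i, ]
    cand <- t0[i] + ifelse(d_i >= 2 * R,
                           (d_i - 2 * R) / v1 + 2 * R / v2,
                           d_i / v2)
    upd <- !done & cand < t0
    t0[upd] <- cand[upd]
  }
  structure(list(origins = fs$centers, t0 = t0,
                 r_offset = rep(r_off, n), fs = fs, v1 = v1, v2 = v2,
                 R = R, kind = "hotspot"),
            class = "event_state")
}

#' Event-based front and speed for hotspot landscapes
#'
#' The front at time `t` is, per transverse row, the maximum of the planar
#' reach `v1 t` and every activated wave's reach (waves with non-positive
#' radius contribute nothing; periodic transverse images included).
#'
#' @param state an `event_state` from [hotspot_activation_cascade()].
#' @param t time.
#' @param n_rows number of transverse rows.
#' @return Data frame with `y` and front position `x`.
#' @export
hotspot_event_front <- function(state, t, n_rows = 200) {
  Ly <- state$fs$domain$Ly
  v1 <- state$v1
  ys <- (seq_len(n_rows) - 0.5) * Ly / n_rows
  xf <- rep(v1 * t, n_rows)
  act <- which(state$t0 < t)
  offs <- if (state$fs$domain$periodic_y) c(-Ly, 0, Ly) else 0
  for (i in act) {
    r_i <- v1 * (t - state$t0[i]) + state$r_offset[i]
    if (r_i <= 0) next
    ox <- state$origins[i, 1]
    for (off in offs) {
      dy <- ys - (state$origins[i, 2] + off)
      sel <- abs(dy) < r_i
      if (any(sel)) {
        xc <- ox + sqrt(r_i^2 - dy[sel]^2)
        xf[sel] <- pmax(xf[sel], xc)
      }
    }
  }
  data.frame(y = ys, x = xf)
}

#' @rdname hotspot_event_front
#' @param t_grid times at which the mean front position is evaluated.
#' @param fit_window trailing fraction used in the linear fit.
#' @return `event_front_speed`: list with relative speed `nu` and `se`.
#' @export
event_front_speed <- function(state, t_grid, fit_window = 0.5,
                              n_rows = 200) {
  mean_pos <- vapply(t_grid, function(t) {
    fr <- if (state$kind == "hotspot") {
      hotspot_event_front(state, t, n_rows)
    } else {
      obstacle_event_front(state, t, n_rows)
    }
    mean(fr$x, na.rm = TRUE)
  }, numeric(1))
  keep <- t_grid >= t_grid[1] + (1 - fit_window) * diff(range(t_grid))
  fit <- lm(mean_pos[keep] ~ t_grid[keep])
  list(nu = unname(coef(fit)[2]) / state$v1,
       se = sqrt(vcov(fit)[2, 2]) / state$v1,
       times = t_grid, positions = mean_pos)
}
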