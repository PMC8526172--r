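#' Least-time (geodesic) distance around a single disc obstacle
#'
#' Shortest path length from the vertical initial-front line `x = x0` to a
#' point, avoiding the open disc of radius `R` centred at `(cx, cy)`. With
#' an unobstructed line of sight the path is the horizontal segment;
#' otherwise it runs horizontally to the tangent point at the top (or
#' bottom) of the disc, follows the arc, and leaves along the tangent to
#' the target. The front at time t is the level set of this distance at
#' `v1 t`.
#'
#' @param px,py coordinates of the target point(s); must lie outside the
#'   disc and at `x >= x0`.
#' @param cx,cy disc centre.
#' @param R disc radius.
#' @param x0 abscissa of the initial front line.
#' @return Geodesic distance(s), same length as `px`.
#' @export
disc_geodesic_distance <- function(px, py, cx, cy, R, x0 = 0) {
  stop_if_not_positive(R, "R")
  n <- max(length(px), length(py))
  px <- rep_len(px, n); py <- rep_len(py, n)
  dcp <- sqrt((px - cx)^2 + (py - cy)^2)
  if (any(dcp < R - 1e-12)) stop("target point lies inside the disc")
  if (any(px < x0)) stop("target must lie ahead of the initial front")

  # horizontal line of sight from (x0, py) to (px, py)?
  half_chord <- sqrt(pmax(R^2 - (py - cy)^2, 0))
  blocked <- abs(py - cy) < R & px > cx - half_chord & x0 < cx + half_chord
  out <- px - x0

  if (any(blocked)) {
    wrap_len <- function(pxb, pyb) {
      # path over the top tangent point (cx, cy + R)
      d <- sqrt((pxb - cx)^2 + (pyb - cy)^2)
      tangent <- sqrt(d^2 - R^2)
      alpha <- atan2(pyb - cy, pxb - cx)
      theta_t <- alpha + acos(pmin(R / d, 1))   # upper tangent point angle
      arc <- (pi / 2 - theta_t) %% (2 * pi)
      (cx - x0) + R * arc + tangent
    }
    pb <- px[blocked]; yb <- py[blocked]
    upper <- wrap_len(pb, yb)
    lower <- wrap_len(pb, 2 * cy - yb)  # mirror through the axis
    out[blocked] <- pmin(upper, lower)
  }
  out
}

#' Kink opening angle and indent size behind an obstacle
#'
#' Far behind an obstacle of half-width `w`, after the front has travelled
#' a distance `d` past the point of maximum width, the transient kink has
#' opening angle `theta = pi - 2 w / d` and indent depth
#' `s = w^2 / (2 d)`; both describe how the kink heals (`theta -> pi`,
#' `s -> 0` as `d -> Inf`). Valid asymptotically for `d >> w`.
#'
#' @param w obstacle half-width.
#' @param d distance travelled since the widest point was passed (> 0).
#' @return Angle in radians / indent length.
#' @export
kink_angle <- function(w, d) {
  stop_if_not_positive(w, "w"); stop_if_not_positive(d, "d")
  pi - 2 * w / d
}

#' @rdname kink_angle
#' @export
indent_size <- function(w, d) {
  stop_if_not_positive(w, "w"); stop_if_not_positive(d, "d")
  w^2 / (2 * d)
}

#' Bulge created by a hotspot: offset and radius
#'
#' Passing through a hotspot of half-length `l` advances the front
#' permanently by `k = 2 l (1 - v1/v2)` along the symmetry axis. The bulge
#' far downstream is a radial wave from the hotspot centre of radius
#' r = d + k, where `d` is the distance of the unperturbed front past the
#' centre; `k` itself does not depend on `d`.
#'
#' @param l hotspot half-length.
#' @param v1,v2 speeds outside/inside the hotspot (`v2 > 0`).
#' @param d distance of the unperturbed planar front past the centre.
#' @param k bulge offset.
#' @export
bulge_offset <- function(l, v1, v2) {
  stop_if_not_positive(l, "l"); stop_if_not_positive(v2, "v2")
  2 * l * (1 - v1 / v2)
}

#' @rdname bulge_offset
#' @export
bulge_radius <- function(d, k) d + k

#' Interaction parabola of a hotspot
#'
#' A downstream feature inside the region bounded by the sideways parabola
#' `y = +/- sqrt(k^2 + 2 k x)` (hotspot-centred frame) is reached by the
#' bulge before the planar front and will further accelerate the front.
#'
#' @param k bulge offset from [bulge_offset()] (>= 0).
#' @param x downstream coordinate(s), `x >= -k/2`.
#' @return Positive branch `y(x)`; `NaN` where `x < -k/2`.
#' @export
interaction_parabola <- function(k, x) {
  if (any(k < 0)) stop("`k` must be >= 0")
  ifelse(x < -k / 2, NaN, sqrt(k^2 + 2 * k * x))
}

#' Mean-speed formulas for hotspot landscapes
#'
#' `harmonic_mean_speed` is the speed in a linear (one-dimensional) habitat
#' with covered fraction `phi`: the weighted harmonic mean
#' `(phi/gamma + (1-phi))^-1`, a lower bound for the two-dimensional
#' speed-up. `spatial_mean_speed` is the arithmetic spatial average
#' `phi gamma + (1 - phi)`. Always `nu_h <= nu_m`, with equality iff
#' `phi` is 0 or 1 or `gamma = 1`.
#'
#' @param phi hotspot area fraction in `[0, 1]`.
#' @param gamma hotspot strength `v2/v1` (> 0).
#' @export
harmonic_mean_speed <- function(phi, gamma) {
  if (any(phi < 0 | phi > 1)) stop("`phi` must be in [0, 1]")
  stop_if_not_positive(gamma, "gamma")
  1 / (phi / gamma + (1 - phi))
}

#' @rdname harmonic_mean_speed
#' @export
spatial_mean_speed <- function(phi, gamma) {
  if (any(phi < 0 | phi > 1)) stop("`phi` must be in [0, 1]")
  stop_if_not_positive(gamma, "gamma")
  phi * gamma + (1 - phi)
}

#' Snell front tilt at a speed interface
#'
#' For a planar front crossing a 45-degree interface between regions of
#' effective speed `v_left` (dense, upstream) and `v_right` (dilute,
#' downstream), Snell's law predicts the refracted front slope
#' `dy/dx = tan(pi/4 + arcsin(v_right / (sqrt(2) v_left)))`. Requires
#' `v_right <= sqrt(2) v_left` (beyond it refraction is total); equal
#' speeds give a vertical (untilted) front, slope `Inf`.
#'
#' @param v_left,v_right effective speeds on the two sides.
#' @return Front slope `dy/dx`.
#' @export
snell_front_tilt <- function(v_left, v_right) {
  stop_if_not_positive(v_left, "v_left")
  if (any(v_right < 0)) stop("`v_right` must be >= 0")
  arg <- v_right / (sqrt(2) * v_left)
  if (any(arg > 1 + 1e-12)) {
    stop("total refraction: v_right exceeds sqrt(2) * v_left")
  }
  tan(pi / 4 + asin(pmin(arg, 1)))
}
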