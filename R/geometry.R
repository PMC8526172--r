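#' Rectangular channel domain
#'
#' The habitat is a channel: `Lx` long in the propagation direction (x) and
#' `Ly` wide transversally (y). The transverse direction is periodic by
#' default, mimicking an infinitely wide system; x is not periodic.
#'
#' @param Lx length along the propagation axis (dimensionless length units).
#' @param Ly transverse channel width.
#' @param periodic_y logical; wrap the transverse direction?
#' @return An object of class `fs_domain`.
#' @export
#' @examples
#' fs_domain(300, 50)
fs_domain <- function(Lx, Ly, periodic_y = TRUE) {
  stop_if_not_positive(Lx, "Lx")
  stop_if_not_positive(Ly, "Ly")
  structure(list(Lx = Lx, Ly = Ly, periodic_y = isTRUE(periodic_y)),
            class = "fs_domain")
}

#' Feature templates: ellipses, circles and rhombi
#'
#' A feature is a finite axis-aligned patch in which the local front speed
#' differs from the background: an *obstacle* (speed 0, impenetrable) or a
#' *hotspot* (speed `v2 > v1`). `a` and `b` are the half-extents along x and
#' y; for an ellipse these are the semi-axes `Ra`, `Rb`, for a rhombus the
#' half-length `l` and half-width `w`. The full obstacle width is `b = 2w`.
#'
#' @param Ra,Rb ellipse semi-axes along x and y.
#' @param R circle radius.
#' @param l,w rhombus half-length (x) and half-width (y).
#' @param kind `"obstacle"` or `"hotspot"`.
#' @return An object of class `fs_feature`.
#' @export
feature_ellipse <- function(Ra, Rb, kind = c("obstacle", "hotspot")) {
  stop_if_not_positive(Ra, "Ra"); stop_if_not_positive(Rb, "Rb")
  kind <- match.arg(kind)
  structure(list(kind = kind, shape = "ellipse", a = Ra, b = Rb),
            class = "fs_feature")
}

#' @rdname feature_ellipse
#' @export
feature_circle <- function(R, kind = c("obstacle", "hotspot")) {
  feature_ellipse(R, R, kind)
}

#' @rdname feature_ellipse
#' @export
feature_rhombus <- function(l, w, kind = c("obstacle", "hotspot")) {
  stop_if_not_positive(l, "l"); stop_if_not_positive(w, "w")
  kind <- match.arg(kind)
  structure(list(kind = kind, shape = "rhombus", a = l, b = w),
            class = "fs_feature")
}

# area of one feature
feature_area <- function(template) {
  switch(template$shape,
         ellipse = pi * template$a * template$b,
         rhombus = 2 * template$a * template$b)
}

#' Expected area fraction of randomly placed overlapping ellipses
#'
#' For ellipses with semi-axes `Ra`, `Rb` placed uniformly at number density
#' `rho` per unit area (a Poisson process, overlaps allowed), the covered
#' area fraction is `1 - exp(-rho * pi * Ra * Rb)`.
#'
#' @param rho number density of features per unit area (>= 0).
#' @param Ra,Rb ellipse semi-axes (circle: `Ra = Rb = R`).
#' @return Area fraction in `[0, 1)`.
#' @export
#' @examples
#' area_fraction_expected(log(2) / pi, 1, 1)  # exactly 1/2
area_fraction_expected <- function(rho, Ra, Rb) {
  if (!is.numeric(rho) || any(rho < 0)) stop("`rho` must be >= 0")
  stop_if_not_positive(Ra, "Ra"); stop_if_not_positive(Rb, "Rb")
  1 - exp(-rho * pi * Ra * Rb)
}

# inverse: density needed for a target area fraction, for any template
density_for_area_fraction <- function(phi, template) {
  if (any(phi < 0) || any(phi >= 1)) stop("`phi` must be in [0, 1)")
  -log(1 - phi) / feature_area(template)
}

#' Sample a random landscape of features
#'
#' Places `Poisson(rho * Lx * Ly)` copies of `template` uniformly on the
#' domain (overlaps permitted, centres may sit anywhere including the edges;
#' features may protrude past the x boundaries). A fixed seed reproduces the
#' identical landscape.
#'
#' @param domain an [fs_domain()].
#' @param rho number density (features per unit area).
#' @param template an `fs_feature` template (all copies share its shape).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return An object of class `feature_set` with a `centers` matrix.
#' @export
sample_feature_set <- function(domain, rho, template, seed = NULL) {
  stopifnot(inherits(domain, "fs_domain"), inherits(template, "fs_feature"))
  if (!is.numeric(rho) || rho < 0) stop("`rho` must be >= 0")
  with_seed(seed, {
    n <- rpois(1, rho * domain$Lx * domain$Ly)
    centers <- cbind(x = runif(n, 0, domain$Lx), y = runif(n, 0, domain$Ly))
    feature_set(domain, template, centers, rho = rho, seed = seed)
  })
}

#' @rdname sample_feature_set
#' @param centers two-column matrix of feature centres.
#' @export
feature_set <- function(domain, template, centers, rho = NA_real_,
                        seed = NULL) {
  centers <- matrix(as.numeric(centers), ncol = 2,
                    dimnames = list(NULL, c("x", "y")))
  if (nrow(centers) > 0 &&
      (any(centers[, 1] < 0) || any(centers[, 1] > domain$Lx) ||
       any(centers[, 2] < 0) || any(centers[, 2] > domain$Ly))) {
    stop("feature centres must lie inside the domain")
  }
  structure(list(domain = domain, template = template, centers = centers,
                 rho = rho, seed = seed),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d %s %s(s) on %g x %g channel (rho = %g)\n",
              nrow(x$centers), x$template$kind, x$template$shape,
              x$domain$Lx, x$domain$Ly, x$rho))
  invisible(x)
}

# which of the points (px, py) fall inside any feature; periodic wrap in y
points_in_features <- function(fs, px, py) {
  inside <- logical(length(px))
  n <- nrow(fs$centers)
  if (n == 0) return(inside)
  a <- fs$template$a; b <- fs$template$b
  Ly <- fs$domain$Ly
  wrap <- if (fs$domain$periodic_y) c(-Ly, 0, Ly) else 0
  ell <- fs$template$shape == "ellipse"
  for (i in seq_len(n)) {
    dx <- px - fs$centers[i, 1]
    sel <- abs(dx) <= a
    if (!any(sel)) next
    dxs <- dx[sel] / a
    for (dyoff in wrap) {
      dys <- (py[sel] - fs$centers[i, 2] + dyoff) / b
      hit <- if (ell) dxs * dxs + dys * dys <= 1 else abs(dxs) + abs(dys) <= 1
      inside[sel][hit] <- TRUE
    }
  }
  inside
}

#' Rasterize a landscape into a local-speed field
#'
#' Cell centres inside any feature get speed `v2`, all others `v1`
#' (obstacles: `v2 = 0`). The lattice constant `h` should resolve the
#' features; the default working resolution is 1/15 of a unit-sized feature.
#'
#' @param fs a [feature_set()].
#' @param h grid spacing (> 0). A warning is given if features are thinner
#'   than `3 h`.
#' @param v1 background speed.
#' @param v2 speed inside features (0 for obstacles).
#' @return An object of class `speed_field` holding the `nx` x `ny` matrix
#'   `v` (x is the first index), `h`, `v1`, `v2` and the domain.
#' @export
rasterize <- function(fs, h, v1 = 1, v2 = 0) {
  stopifnot(inherits(fs, "feature_set"))
  stop_if_not_positive(h, "h")
  if (min(fs$template$a, fs$template$b) < 1.5 * h) {
    warning("grid spacing `h` barely resolves the features (extent < 3h)")
  }
  nx <- max(1L, round(fs$domain$Lx / h))
  ny <- max(1L, round(fs$domain$Ly / h))
  v <- matrix(v1, nx, ny)
  n <- nrow(fs$centers)
  if (n > 0) {
    a <- fs$template$a; b <- fs$template$b
    Ly <- fs$domain$Ly
    ell <- fs$template$shape == "ellipse"
    wrap <- if (fs$domain$periodic_y) c(-Ly, 0, Ly) else 0
    for (i in seq_len(n)) {
      cx <- fs$centers[i, 1]
      ix0 <- max(1L, floor((cx - a) / h - 0.5) + 1L)
      ix1 <- min(nx, ceiling((cx + a) / h + 0.5))
      if (ix0 > ix1) next
      xs <- ((ix0:ix1) - 0.5) * h
      dxs <- (xs - cx) / a
      for (dyoff in wrap) {
        cy <- fs$centers[i, 2] + dyoff
        iy0 <- max(1L, floor((cy - b) / h - 0.5) + 1L)
        iy1 <- min(ny, ceiling((cy + b) / h + 0.5))
        if (iy0 > iy1) next
        ys <- ((iy0:iy1) - 0.5) * h
        dys <- (ys - cy) / b
        m <- if (ell) {
          outer(dxs^2, dys^2, `+`) <= 1
        } else {
          outer(abs(dxs), abs(dys), `+`) <= 1
        }
        sub <- v[ix0:ix1, iy0:iy1, drop = FALSE]
        sub[m] <- v2
        v[ix0:ix1, iy0:iy1] <- sub
      }
    }
  }
  structure(list(h = h, nx = nx, ny = ny, v = v, v1 = v1, v2 = v2,
                 domain = fs$domain),
            class = "speed_field")
}

#' Uniform speed field without features
#'
#' @param domain an [fs_domain()].
#' @param h grid spacing.
#' @param v1 uniform speed.
#' @export
uniform_speed_field <- function(domain, h, v1 = 1) {
  rasterize(feature_set(domain, feature_circle(1), matrix(numeric(0), 0, 2)),
            h, v1 = v1, v2 = v1)
}

#' @export
print.speed_field <- function(x, ...) {
  cat(sprintf("<speed_field> %d x %d cells, h = %g, v1 = %g, v2 = %g\n",
              x$nx, x$ny, x$h, x$v1, x$v2))
  invisible(x)
}

#' Does a cluster of overlapping obstacles block the channel?
#'
#' The front stops only when overlapping obstacles form a connected cluster
#' that wraps the periodic transverse direction, so no unobstructed
#' left-to-right path remains. Detection is by union-find over pairwise
#' feature overlaps across periodic images.
#'
#' @param fs a [feature_set()] whose template kind is `"obstacle"`.
#' @return `TRUE` if the channel is blocked.
#' @export
spanning_blockage_exists <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  if (fs$template$kind != "obstacle") {
    stop("blockage is defined for obstacle landscapes only")
  }
  if (nrow(fs$centers) == 0) return(FALSE)
  channel_blockage_cpp(fs$centers[, 1], fs$centers[, 2],
                       fs$template$a, fs$template$b,
                       if (fs$template$shape == "ellipse") 0L else 1L,
                       fs$domain$Ly)
}

#' Continuum percolation threshold of overlapping equal discs
#'
#' Estimates the critical area fraction at which randomly placed equal discs
#' form a cluster spanning a square box, by bisecting on the area fraction
#' until the spanning probability crosses 1/2. In an infinite system the
#' threshold is close to 0.68.
#'
#' @param R disc radius.
#' @param box_size box side length (>= 30 R recommended; smaller sizes set a
#'   warning flag in the result).
#' @param trials Monte-Carlo trials per tested area fraction (>= 100).
#' @param seed integer seed.
#' @param lower,upper initial bracketing area fractions.
#' @param iters bisection iterations.
#' @return List with `phi_c`, `se` (standard error, from the binomial
#'   uncertainty at the final point divided by the local slope of the
#'   spanning probability), `trials`, and `warning`.
#' @export
estimate_percolation_threshold <- function(R = 1, box_size = 60 * R,
                                           trials = 400, seed = 1,
                                           lower = 0.55, upper = 0.8,
                                           iters = 9) {
  stop_if_not_positive(R, "R")
  if (trials < 100) stop("`trials` must be at least 100")
  warn <- box_size < 30 * R
  if (warn) warning("box_size < 30 R: threshold estimate will be biased")

  span_prob <- function(phi, salt) {
    rho <- -log(1 - phi) / (pi * R^2)
    seeds <- derive_seeds(seed, trials, salt = salt)
    hits <- vapply(seeds, function(s) {
      with_seed(s, {
        n <- rpois(1, rho * box_size^2)
        discs_span_cpp(runif(n, 0, box_size), runif(n, 0, box_size),
                       R, box_size)
      })
    }, logical(1))
    mean(hits)
  }

  lo <- lower; hi <- upper
  p_lo <- span_prob(lo, 0L); p_hi <- span_prob(hi, 1L)
  history <- data.frame(phi = c(lo, hi), p = c(p_lo, p_hi))
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    p_mid <- span_prob(mid, k + 1L)
    history <- rbind(history, data.frame(phi = mid, p = p_mid))
    if (p_mid < 0.5) {
      lo <- mid; p_lo <- p_mid
    } else {
      hi <- mid; p_hi <- p_mid
    }
  }
  phi_c <- (lo + hi) / 2
  # slope of spanning probability near the crossing, from the visited points
  near <- history[order(abs(history$phi - phi_c)), ][seq_len(min(5, nrow(history))), ]
  slope <- tryCatch(abs(coef(lm(p ~ phi, data = near))[2]), error = function(e) NA)
  se_p <- sqrt(0.25 / trials)
  se <- if (is.finite(slope) && slope > 0) se_p / slope + (hi - lo) / 2 else NA_real_
  list(phi_c = phi_c, se = unname(se), trials = trials, warning = warn,
       history = history)
}
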