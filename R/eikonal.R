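#' Solve the Eikonal equation |grad T| = 1/v by fast marching
#'
#' First-order upwind (Godunov) fast marching on the rasterized speed field.
#' The transverse direction wraps periodically when the domain does. Cells
#' with `v = 0` (obstacles) are never accepted and keep `T = Inf`, as do
#' regions enclosed by obstacles.
#'
#' @param field a `speed_field` from [rasterize()] or
#'   [uniform_speed_field()].
#' @param source front source: `"planar"` (a line at x = 0, the default), a
#'   list `list(type = "point", x =, y =)`, or
#'   `list(type = "mask", idx =, t0 =)` with 1-based cell indices into the
#'   `v` matrix and their initial times.
#' @return Object of class `arrival_field`: the `nx` x `ny` matrix `T` plus
#'   grid metadata.
#' @export
eikonal_solve <- function(field, source = "planar") {
  stopifnot(inherits(field, "speed_field"))
  h <- field$h; nx <- field$nx; ny <- field$ny
  if (identical(source, "planar")) source <- list(type = "planar")
  if (source$type == "planar") {
    idx <- 1L + (0:(ny - 1L)) * nx               # first column, 0-based below
    v0 <- field$v[idx]
    init_idx <- idx[v0 > 0] - 1L
    init_t <- (0.5 * h) / v0[v0 > 0]
  } else if (source$type == "point") {
    cx <- ((1:nx) - 0.5) * h; cy <- ((1:ny) - 0.5) * h
    ix <- pmin(pmax(round(source$x / h + 0.5), 1), nx)
    iy <- pmin(pmax(round(source$y / h + 0.5), 1), ny)
    # seed an exact-distance disc of radius 3h around the point
    span <- 3L
    ixs <- max(1, ix - span):min(nx, ix + span)
    iys <- max(1, iy - span):min(ny, iy + span)
    grid <- expand.grid(ix = ixs, iy = iys)
    d <- sqrt((cx[grid$ix] - source$x)^2 + (cy[grid$iy] - source$y)^2)
    idx <- grid$ix + (grid$iy - 1L) * nx
    vv <- field$v[idx]
    keep <- vv > 0
    init_idx <- idx[keep] - 1L
    init_t <- d[keep] / vv[keep]
  } else if (source$type == "mask") {
    init_idx <- as.integer(source$idx) - 1L
    init_t <- if (is.null(source$t0)) rep(0, length(init_idx)) else source$t0
  } else {
    stop("unknown source type")
  }
  if (length(init_idx) == 0) stop("source is empty or entirely blocked")
  T <- fmm_solve_cpp(as.numeric(field$v), nx, ny, h,
                     isTRUE(field$domain$periodic_y), init_idx, init_t)
  structure(list(T = matrix(T, nx, ny), h = h, nx = nx, ny = ny,
                 v1 = field$v1, v2 = field$v2, domain = field$domain,
                 source = source),
            class = "arrival_field")
}

#' @export
print.arrival_field <- function(x, ...) {
  finite <- is.finite(x$T)
  cat(sprintf("<arrival_field> %d x %d cells, h = %g, T in [%.3g, %.3g] (%.1f%% reachable)\n",
              x$nx, x$ny, x$h, min(x$T[finite]), max(x$T[finite]),
              100 * mean(finite)))
  invisible(x)
}

#' Front contour at a given time
#'
#' Level set `T = t` of the arrival-time field, extracted by marching
#' squares with linear sub-cell interpolation (unreachable cells are treated
#' as above-level).
#'
#' @param af an `arrival_field`.
#' @param t contour time.
#' @return List of polylines, each a data frame with `x`, `y` columns;
#'   empty list when the level set is empty.
#' @export
front_contour <- function(af, t) {
  Tm <- af$T
  finite <- is.finite(Tm)
  if (!any(finite)) return(list())
  big <- 2 * max(Tm[finite]) + 2 * abs(t) + 1
  Tm[!finite] <- big
  xs <- ((1:af$nx) - 0.5) * af$h
  ys <- ((1:af$ny) - 0.5) * af$h
  cl <- contourLines(xs, ys, Tm, levels = t)
  lapply(cl, function(p) data.frame(x = p$x, y = p$y))
}

#' Mean front position at given times
#'
#' Per transverse row the front position is the rightmost reached cell
#' (`T <= t`), sub-cell interpolated; the mean is taken over rows, excluding
#' rows not yet reached at all.
#'
#' @param af an `arrival_field`.
#' @param t time, or vector of times.
#' @return Numeric vector of mean front positions.
#' @export
mean_front_position <- function(af, t) {
  reach <- front_reach_cpp(as.numeric(af$T), af$nx, af$ny, af$h, t)
  colMeans(reach, na.rm = TRUE)
}

# latest time at which the front is still fully inside the grid:
# the earliest arrival in the final column over rows that reach it
front_exit_time <- function(af) {
  last <- af$T[af$nx, ]
  last <- last[is.finite(last)]
  if (length(last) == 0) return(NA_real_)
  min(last)
}

#' Relative front speed from an arrival-time field
#'
#' Fits the mean front position against time over a trailing window (after
#' discarding an initial transient) and reports the slope relative to the
#' background speed `v1`. A transversally blocked channel gives `nu = 0`
#' with `blocked = TRUE`.
#'
#' @param af an `arrival_field` (planar source).
#' @param fit_window trailing fraction of the usable time range to fit.
#' @param transient initial fraction discarded before windowing.
#' @param n_times number of sample times (>= 20).
#' @return List with `nu`, `se`, `blocked`, and the fitted samples.
#' @export
relative_front_speed <- function(af, fit_window = 0.5, transient = 0.2,
                                 n_times = 60) {
  if (n_times < 20) stop("need at least 20 sample times")
  t_end <- front_exit_time(af)
  if (!is.finite(t_end)) {
    return(list(nu = 0, se = NA_real_, blocked = TRUE,
                times = numeric(0), positions = numeric(0)))
  }
  t_end <- 0.995 * t_end
  t0 <- transient * t_end
  tt <- seq(t0 + (1 - fit_window) * (t_end - t0), t_end, length.out = n_times)
  pos <- mean_front_position(af, tt)
  fit <- lm(pos ~ tt)
  list(nu = unname(coef(fit)[2]) / af$v1,
       se = sqrt(vcov(fit)[2, 2]) / af$v1,
       blocked = FALSE, times = tt, positions = pos)
}

#' Landscape-to-speed convenience wrapper
#'
#' Samples a landscape, rasterizes it, solves the Eikonal equation from a
#' planar front and returns the relative front speed.
#'
#' @param domain an [fs_domain()].
#' @param rho number density.
#' @param template an `fs_feature` template.
#' @param gamma speed ratio `v2/v1` for hotspots (ignored for obstacles).
#' @param h grid spacing.
#' @param seed landscape seed.
#' @param ... passed to [relative_front_speed()].
#' @return As [relative_front_speed()], plus the `feature_set` and
#'   blockage detection for obstacle landscapes.
#' @export
landscape_front_speed <- function(domain, rho, template, gamma = NULL,
                                  h = 1 / 15, seed = NULL, ...) {
  fs <- sample_feature_set(domain, rho, template, seed)
  v2 <- if (template$kind == "obstacle") 0 else gamma
  if (template$kind == "hotspot" && (is.null(gamma) || gamma <= 0)) {
    stop("hotspot landscapes need a positive `gamma`")
  }
  field <- rasterize(fs, h, v1 = 1, v2 = v2)
  if (template$kind == "obstacle" && spanning_blockage_exists(fs)) {
    return(list(nu = 0, se = NA_real_, blocked = TRUE, fs = fs))
  }
  out <- relative_front_speed(eikonal_solve(field), ...)
  out$fs <- fs
  out
}
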