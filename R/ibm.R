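#' Parameters of the birth-coagulation individual-based model
#'
#' Individuals duplicate in place at rate `mu`, die by pairwise competition
#' at rate `lambda * n_others` (occupancy of their fixed `delta`-sized
#' interaction cell minus one), and diffuse with coefficient `D`. Updating
#' uses a fixed time step: per step an individual is duplicated with
#' probability `mu * dt`, dies with probability `lambda * n_others * dt`,
#' and moves by a Gaussian displacement of standard deviation
#' `sqrt(2 D dt)` per axis. The y direction wraps periodically; x reflects
#' at the domain ends.
#'
#' @param mu birth rate per individual.
#' @param lambda death-rate coefficient per neighbour.
#' @param delta interaction cell size.
#' @param D diffusion coefficient outside features.
#' @param dt time step. A warning is given when `mu * dt` or the expected
#'   `lambda * n * dt` exceed 0.1 (first-order time-discretization bias).
#' @param domain an [fs_domain()].
#' @return Object of class `ibm_params`.
#' @export
ibm_params <- function(mu = 1, lambda = 1, delta = 1, D = 1, dt = 0.1,
                       domain = fs_domain(400, 50)) {
  stop_if_not_positive(delta, "delta")
  stop_if_not_positive(dt, "dt")
  for (nm in c("mu", "lambda", "D")) {
    v <- get(nm)
    if (!is.numeric(v) || !is.finite(v) || v < 0) {
      stop(sprintf("`%s` must be a non-negative finite number", nm),
           call. = FALSE)
    }
  }
  if (mu * dt > 0.1 || (lambda > 0 && (lambda + mu) * dt > 0.25)) {
    warning("time step is coarse for these rates (p > 0.1 per step)")
  }
  structure(list(mu = mu, lambda = lambda, delta = delta, D = D, dt = dt,
                 domain = domain),
            class = "ibm_params")
}

#' Spatial modification of rates inside features
#'
#' Inside the features of `fs`, the diffusion coefficient becomes `D2`
#' (0 makes the feature an impermeable obstacle: moves ending inside it are
#' rejected) and the birth rate becomes `mu2` (defaults to the background).
#'
#' @param fs a [feature_set()].
#' @param D2 diffusivity inside features (>= 0).
#' @param mu2 birth rate inside features, or `NULL` for unchanged.
#' @export
rate_modifier <- function(fs, D2 = 0, mu2 = NULL) {
  stopifnot(inherits(fs, "feature_set"))
  if (D2 < 0) stop("`D2` must be >= 0")
  if (!is.null(mu2) && mu2 < 0) stop("`mu2` must be >= 0")
  structure(list(fs = fs, D2 = D2, mu2 = mu2), class = "rate_modifier")
}

new_population <- function(x, y, time = 0) {
  structure(list(x = x, y = y, time = time), class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d individuals at t = %g\n", length(x$x), x$time))
  invisible(x)
}

#' Initial band of individuals
#'
#' Uniformly fills `[0, x_max] x [0, Ly]` at the given density. The default
#' density is the mean-field carrying capacity `(1 + mu/lambda) / delta^2`;
#' note that the stochastic model equilibrates below this value (see the
#' package vignette).
#'
#' @param params an [ibm_params()].
#' @param x_max band depth (`0 <= x_max < Lx`; 0 gives an empty population).
#' @param density individuals per unit area.
#' @param seed optional seed.
#' @return A `population`.
#' @export
init_band <- function(params, x_max,
                      density = (1 + params$mu / params$lambda) / params$delta^2,
                      seed = NULL) {
  stopifnot(inherits(params, "ibm_params"))
  if (x_max < 0 || x_max >= params$domain$Lx) stop("`x_max` out of range")
  if (density <= 0) stop("`density` must be > 0")
  with_seed(seed, {
    n <- round(density * x_max * params$domain$Ly)
    new_population(runif(n, 0, x_max), runif(n, 0, params$domain$Ly))
  })
}

# indices of individuals inside features (empty modifier -> none)
ibm_inside <- function(modifier, x, y) {
  if (is.null(modifier) || nrow(modifier$fs$centers) == 0) {
    rep(FALSE, length(x))
  } else {
    points_in_features(modifier$fs, x, y)
  }
}

#' One update step of the individual-based model
#'
#' Applies, in order: births (probability `mu(x) dt`, newborn at the parent
#' position), deaths (all individuals including newborns binned into
#' delta-cells; each dies with probability `lambda * n_others * dt`), and
#' diffusion (Gaussian step with the local `D`; proposals ending inside a
#' `D = 0` feature are rejected; y wraps, x reflects).
#'
#' @param pop a `population`.
#' @param params an [ibm_params()].
#' @param modifier optional [rate_modifier()].
#' @return Updated `population` with `time` advanced by `dt`.
#' @export
ibm_step <- function(pop, params, modifier = NULL) {
  x <- pop$x; y <- pop$y
  dt <- params$dt
  dom <- params$domain
  n <- length(x)

  if (n > 0) {
    # births
    mu_loc <- params$mu
    if (!is.null(modifier) && !is.null(modifier$mu2) &&
        modifier$mu2 != params$mu) {
      inside <- ibm_inside(modifier, x, y)
      mu_loc <- ifelse(inside, modifier$mu2, params$mu)
    }
    born <- runif(n) < mu_loc * dt
    x <- c(x, x[born]); y <- c(y, y[born])
    n <- length(x)

    # deaths: occupancy of fixed delta-cells, origin-anchored
    K <- ceiling(dom$Lx / params$delta)
    cell <- floor(x / params$delta) + K * floor(y / params$delta) + 1
    occ <- tabulate(cell, nbins = max(cell))
    p_die <- pmin(params$lambda * (occ[cell] - 1) * dt, 1)
    keep <- runif(n) >= p_die
    x <- x[keep]; y <- y[keep]
    n <- length(x)

    # diffusion with local D; rejection into impermeable features
    if (n > 0) {
      D_loc <- rep(params$D, n)
      impermeable <- FALSE
      if (!is.null(modifier)) {
        inside <- ibm_inside(modifier, x, y)
        D_loc[inside] <- modifier$D2
        impermeable <- modifier$D2 == 0
      }
      sdv <- sqrt(2 * D_loc * dt)
      nx <- x + rnorm(n, 0, sdv)
      ny <- y + rnorm(n, 0, sdv)
      ny <- ny %% dom$Ly
      nx <- abs(nx)
      nx <- ifelse(nx > dom$Lx, 2 * dom$Lx - nx, nx)
      if (impermeable) {
        reject <- ibm_inside(modifier, nx, ny)
        nx[reject] <- x[reject]
        ny[reject] <- y[reject]
      }
      x <- nx; y <- ny
    }
  }
  new_population(x, y, pop$time + dt)
}

#' Front profile of a population
#'
#' For each transverse delta-bin the front position is the rightmost
#' occupied delta-cell belonging to the population bulk: occupied cells more
#' than `5 delta` ahead of the 95th percentile of occupied cells in that row
#' are discarded as stray diffusers. Empty rows give `NA`.
#'
#' @param pop a `population`.
#' @param delta interaction cell size used for binning.
#' @param Ly channel width.
#' @param stray_gap stray-diffuser cutoff ahead of the row's 95th
#'   percentile, in units of `delta`.
#' @return Numeric vector `x_f(y)`, one entry per delta-row.
#' @export
extract_front <- function(pop, delta = 1, Ly, stray_gap = 5) {
  if (length(pop$x) == 0) stop("population is empty")
  nrow_bins <- max(1L, ceiling(Ly / delta))
  row <- pmin(floor(pop$y / delta), nrow_bins - 1)
  cellx <- floor(pop$x / delta)
  front <- rep(NA_real_, nrow_bins)
  sp <- split(cellx, factor(row, levels = 0:(nrow_bins - 1)))
  for (r in seq_along(sp)) {
    cells <- sp[[r]]
    if (length(cells) == 0) next
    q <- quantile(cells, 0.95, names = FALSE, type = 1)
    bulk <- cells[cells <= q + stray_gap]
    front[r] <- (max(bulk) + 0.5) * delta  # centre of rightmost bulk cell
  }
  front
}

#' Run the individual-based model and record the front
#'
#' Repeats [ibm_step()] until `t_end`, extracting the front profile every
#' `record_every` time units. Terminates early (with `extinct = TRUE`) if
#' the population dies out.
#'
#' @param params an [ibm_params()].
#' @param modifier optional [rate_modifier()].
#' @param t_end final time.
#' @param record_every recording interval (time units).
#' @param x_max initial band depth.
#' @param density initial band density.
#' @param seed seed for the whole run.
#' @param keep_profiles logical; keep per-row front profiles?
#' @return Object of class `front_series` with `times`,
#'   `mean_front_positions`, optional `profiles` matrix (row per record),
#'   final `population`, and flags.
#' @export
ibm_run <- function(params, modifier = NULL, t_end = 100, record_every = 1,
                    x_max = 20, density = NULL, seed = NULL,
                    keep_profiles = FALSE) {
  stopifnot(inherits(params, "ibm_params"))
  with_seed(seed, {
    if (is.null(density)) {
      pop <- init_band(params, x_max)
    } else {
      pop <- init_band(params, x_max, density)
    }
    steps_per_rec <- max(1L, round(record_every / params$dt))
    nsteps <- round(t_end / params$dt)
    times <- c(); mfp <- c(); profiles <- list()
    extinct <- FALSE
    for (s in seq_len(nsteps)) {
      pop <- ibm_step(pop, params, modifier)
      if (length(pop$x) == 0) { extinct <- TRUE; break }
      if (s %% steps_per_rec == 0) {
        prof <- extract_front(pop, params$delta, params$domain$Ly)
        times <- c(times, pop$time)
        mfp <- c(mfp, mean(prof, na.rm = TRUE))
        if (keep_profiles) profiles[[length(profiles) + 1]] <- prof
      }
    }
    structure(list(times = times, mean_front_positions = mfp,
                   profiles = if (keep_profiles) do.call(rbind, profiles),
                   population = pop, extinct = extinct, params = params),
              class = "front_series")
  })
}

#' @export
print.front_series <- function(x, ...) {
  cat(sprintf("<front_series> %d records to t = %g%s\n", length(x$times),
              if (length(x$times)) max(x$times) else 0,
              if (x$extinct) " (extinct)" else ""))
  invisible(x)
}

#' Front speed from a recorded series
#'
#' Ordinary least-squares slope of mean front position versus time over the
#' trailing `window` fraction of the records. Records after the front has
#' come within one interaction cell of the domain end are truncated (with a
#' warning).
#'
#' @param series a `front_series` (or any list with `times` and
#'   `mean_front_positions`).
#' @param window trailing fraction of records used for the fit.
#' @param Lx domain length used for the truncation guard (taken from
#'   `series$params` when present).
#' @return List with `speed`, `se`, and the number of points fitted.
#' @export
front_speed <- function(series, window = 0.5, Lx = NULL) {
  t <- series$times; p <- series$mean_front_positions
  if (is.null(Lx) && !is.null(series$params)) Lx <- series$params$domain$Lx
  if (!is.null(Lx)) {
    ok <- p < Lx - 1
    if (!all(ok)) {
      warning("front reached the domain end; truncating the fit window")
      t <- t[ok]; p <- p[ok]
    }
  }
  keep <- t >= t[1] + (1 - window) * (t[length(t)] - t[1])
  if (sum(keep) < 10) stop("fewer than 10 records in the fit window")
  fit <- lm(p[keep] ~ t[keep])
  list(speed = unname(coef(fit)[2]),
       se = sqrt(vcov(fit)[2, 2]),
       n = sum(keep))
}
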