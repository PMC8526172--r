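test_that("initial band has the requested density and is reproducible", {
  p <- ibm_params(domain = fs_domain(100, 50))
  pop <- init_band(p, 20, density = 2, seed = 1)
  expect_equal(length(pop$x), 2000)   # 2 per unit area on 20 x 50
  expect_true(all(pop$x >= 0 & pop$x <= 20))
  expect_equal(length(init_band(p, 0, density = 2, seed = 1)$x), 0)
  a <- init_band(p, 10, seed = 5); b <- init_band(p, 10, seed = 5)
  expect_identical(a$x, b$x)
  expect_error(init_band(p, 10, density = -1), "density")
  expect_error(init_band(p, 200), "x_max")
})

test_that("step: frozen dynamics, diffusion variance, move rejection", {
  dom <- fs_domain(50, 50)
  # mu = lambda = 0, D ~ 0: population unchanged
  p0 <- ibm_params(mu = 0, lambda = 0, D = 0, domain = dom)
  pop <- init_band(p0, 30, density = 1, seed = 2)
  stepped <- ibm_step(pop, p0)
  expect_equal(sort(stepped$x), sort(pop$x))
  expect_equal(stepped$time, p0$dt)

  # pure diffusion: per-axis displacement variance after t = 10 is 2 D t
  pd <- ibm_params(mu = 0, lambda = 0, D = 1, dt = 0.01,
                   domain = fs_domain(1000, 1000))
  n <- 500
  pop <- structure(list(x = rep(500, n), y = rep(500, n), time = 0),
                   class = "population")
  set.seed(11)
  for (i in 1:1000) pop <- ibm_step(pop, pd)
  v <- var(pop$x - 500)
  expect_lt(abs(v - 20), 4 * 20 * sqrt(2 / (n - 1)))

  # impermeable obstacle: no individual ever strictly inside
  dom2 <- fs_domain(40, 20)
  fs <- feature_set(dom2, feature_circle(3, "obstacle"), cbind(20, 10))
  mod <- rate_modifier(fs, D2 = 0)
  p <- ibm_params(domain = dom2)
  pop <- init_band(p, 15, seed = 3)
  set.seed(12)
  for (i in 1:100) {
    pop <- ibm_step(pop, p, mod)
    expect_false(any(frontscape:::points_in_features(fs, pop$x, pop$y)))
  }
})

test_that("population saturates at a stationary density below mean field", {
  # in-place births correlate same-cell pairs, so the realized carrying
  # capacity sits well below the deterministic (1 + mu/lambda)/delta^2
  p <- ibm_params(domain = fs_domain(30, 30))
  pop <- init_band(p, 29.9, density = 2, seed = 7)
  set.seed(13)
  dens <- numeric(300)
  for (i in 1:300) {
    pop <- ibm_step(pop, p)
    dens[i] <- length(pop$x) / 900
  }
  first <- mean(dens[151:220]); second <- mean(dens[231:300])
  expect_lt(abs(second - first) / first, 0.05)   # stationary
  expect_gt(second, 0.3)
  expect_lt(second, 1 + p$mu / p$lambda)         # below mean field
})

test_that("front extraction: uniform band and stray-diffuser filter", {
  pop <- structure(list(x = runif(5000, 0, 20), y = runif(5000, 0, 50),
                        time = 0), class = "population")
  prof <- extract_front(pop, delta = 1, Ly = 50)
  expect_equal(length(prof), 50)
  expect_true(all(abs(prof - 20) <= 1.5))
  # one far-forward stray is excluded
  pop$x[1] <- 45; pop$y[1] <- 0.5
  prof2 <- extract_front(pop, delta = 1, Ly = 50)
  expect_lt(prof2[1], 25)
  expect_error(extract_front(structure(list(x = numeric(0), y = numeric(0)),
                                       class = "population"), 1, 50),
               "empty")
})

test_that("front speed fitting: exact slope and domain-end truncation", {
  jitter <- sin(1:40) * 1e-6   # avoid a degenerate exact fit
  s <- list(times = 1:40, mean_front_positions = 3 + 0.9 * (1:40) + jitter)
  expect_equal(front_speed(s)$speed, 0.9, tolerance = 1e-6)
  s2 <- list(times = 1:40, mean_front_positions = 2.6 * (1:40) + jitter)
  expect_warning(front_speed(s2, Lx = 80), "domain end")
})

test_that("homogeneous front: linearity, FKPP bound, cutoff ordering", {
  p <- ibm_params(domain = fs_domain(150, 30))
  run <- ibm_run(p, t_end = 60, record_every = 1, x_max = 15, seed = 21)
  t <- run$times; x <- run$mean_front_positions
  half <- t > max(t) / 2
  fit <- lm(x[half] ~ t[half])
  expect_gt(summary(fit)$r.squared, 0.99)
  v <- front_speed(run)$speed
  expect_gt(v, 0)
  expect_lt(v, 2 * sqrt(p$D * p$mu))  # continuum FKPP bound

  # reproducibility across seeds (same generative settings)
  v2 <- front_speed(ibm_run(p, t_end = 60, record_every = 1, x_max = 15,
                            seed = 22))$speed
  expect_lt(abs(v - v2) / mean(c(v, v2)), 0.1)

  # stronger competition (smaller occupancy) slows the front
  p4 <- suppressWarnings(ibm_params(lambda = 4, domain = fs_domain(150, 30)))
  v_l4 <- front_speed(ibm_run(p4, t_end = 60, record_every = 1, x_max = 15,
                              seed = 21))$speed
  expect_lt(v_l4, v)

  # recording interval does not change the estimate materially
  v_rec <- front_speed(ibm_run(p, t_end = 60, record_every = 2, x_max = 15,
                               seed = 21))$speed
  expect_lt(abs(v_rec - v) / v, 0.1)
})

test_that("an IBM front wraps a blocking disc and heals (least-time shape)", {
  # one impermeable disc; the ensemble front behind it lags and then heals,
  # qualitatively matching the geodesic level set
  dom <- fs_domain(120, 40)
  fs <- feature_set(dom, feature_circle(8, "obstacle"), cbind(50, 20))
  mod <- rate_modifier(fs, D2 = 0)
  p <- ibm_params(domain = dom)
  run <- ibm_run(p, mod, t_end = 70, record_every = 5, x_max = 20,
                 seed = 31, keep_profiles = TRUE)
  prof <- run$profiles[nrow(run$profiles), ]   # final profile
  mid <- mean(prof[c(20, 21)], na.rm = TRUE)   # shadow rows
  side <- mean(prof[c(5, 35)], na.rm = TRUE)   # unobstructed rows
  expect_gt(side, 50)          # front has passed the obstacle
  expect_lt(mid, side + 2)     # shadow still lags (or has healed to ~equal)
  expect_gt(mid, 50 - 8)       # but the population has invaded the shadow
})
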