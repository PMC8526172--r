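test_that("expected area fraction formula and its Monte-Carlo check", {
  expect_equal(area_fraction_expected(0, 2, 3), 0)
  expect_equal(area_fraction_expected(log(2) / pi, 1, 1), 0.5)
  expect_equal(area_fraction_expected(0.2, 1, 1), 1 - exp(-0.2 * pi),
               tolerance = 1e-12)
  expect_error(area_fraction_expected(-0.1, 1, 1), "rho")

  # rasterized coverage of sampled landscapes is an unbiased estimate
  dom <- fs_domain(60, 60)
  tem <- feature_circle(1, "obstacle")
  cov <- vapply(oracle_seeds(20), function(s) {
    fs <- sample_feature_set(dom, 0.2, tem, seed = s)
    f <- rasterize(fs, 1 / 10, 1, 0)
    mean(f$v == 0)
  }, numeric(1))
  se <- sd(cov) / sqrt(length(cov))
  expect_lt(abs(mean(cov) - area_fraction_expected(0.2, 1, 1)), 3 * se)
})

test_that("landscape sampling is Poisson-uniform and reproducible", {
  dom <- fs_domain(100, 50)
  tem <- feature_circle(1, "hotspot")
  expect_equal(nrow(sample_feature_set(dom, 0, tem, seed = 1)$centers), 0)
  a <- sample_feature_set(dom, 0.1, tem, seed = 42)
  b <- sample_feature_set(dom, 0.1, tem, seed = 42)
  expect_identical(a$centers, b$centers)
  # count is Poisson(rho Lx Ly): pooled counts within 4 sd of the mean
  n <- vapply(oracle_seeds(30), function(s)
    nrow(sample_feature_set(dom, 0.1, tem, seed = s)$centers), numeric(1))
  expect_lt(abs(mean(n) - 500), 4 * sqrt(500 / 30))
  expect_error(feature_set(dom, tem, cbind(200, 10)), "inside the domain")
})

test_that("rasterization: cell counts, periodic wrap, scale invariance", {
  dom <- fs_domain(10, 10)
  # empty landscape -> uniform background
  f0 <- rasterize(feature_set(dom, feature_circle(1), matrix(numeric(0), 0, 2)),
                  1 / 15, v1 = 2, v2 = 0)
  expect_true(all(f0$v == 2))

  # one unit disc covers ~ pi R^2 / h^2 cells
  fs <- feature_set(dom, feature_circle(1, "obstacle"), cbind(5, 5))
  f <- rasterize(fs, 1 / 15, 1, 0)
  expect_equal(sum(f$v == 0), pi * 15^2, tolerance = 0.03)

  # feature straddling y = 0 wraps to y ~ Ly
  fs2 <- feature_set(dom, feature_circle(1, "obstacle"), cbind(5, 0.2))
  f2 <- rasterize(fs2, 1 / 15, 1, 0)
  expect_true(any(f2$v[, f2$ny] == 0))
  # and not when the channel is closed
  dom_np <- fs_domain(10, 10, periodic_y = FALSE)
  f3 <- rasterize(feature_set(dom_np, feature_circle(1, "obstacle"),
                              cbind(5, 0.2)), 1 / 15, 1, 0)
  expect_false(any(f3$v[, f3$ny] == 0))

  # scale invariance: scaling the landscape and the lattice together
  # reproduces the identical occupancy mask
  fs4 <- sample_feature_set(fs_domain(20, 10), 0.1,
                            feature_ellipse(1.5, 1, "obstacle"), seed = 3)
  m1 <- rasterize(fs4, 1 / 10, 1, 0)$v == 0
  fs4s <- feature_set(fs_domain(60, 30), feature_ellipse(4.5, 3, "obstacle"),
                      fs4$centers * 3)
  m2 <- rasterize(fs4s, 3 / 10, 1, 0)$v == 0
  expect_identical(m1, m2)

  expect_error(rasterize(fs, -1), "h")
  expect_warning(rasterize(fs, 0.9), "resolves")
})

test_that("transverse blockage detection: wrap clusters, monotonicity", {
  dom <- fs_domain(40, 20)
  tem <- feature_circle(1.5, "obstacle")
  empty <- feature_set(dom, tem, matrix(numeric(0), 0, 2))
  expect_false(spanning_blockage_exists(empty))

  # a chain of discs spaced < 2R across the full width blocks the channel
  chain <- feature_set(dom, tem, cbind(20, seq(0.5, 19.5, by = 2)))
  expect_true(spanning_blockage_exists(chain))
  # remove one link -> a gap opens (wrap accounted for)
  gap <- feature_set(dom, tem, cbind(20, seq(0.5, 19.5, by = 2)[-5]))
  expect_false(spanning_blockage_exists(gap))

  expect_error(
    spanning_blockage_exists(feature_set(dom, feature_circle(1, "hotspot"),
                                         cbind(5, 5))),
    "obstacle")

  # monotone: adding an obstacle never unblocks
  for (s in oracle_seeds(10)) {
    fs <- sample_feature_set(dom, 0.12, tem, seed = s)
    if (spanning_blockage_exists(fs)) {
      more <- feature_set(dom, tem, rbind(fs$centers, c(10, 10)))
      expect_true(spanning_blockage_exists(more))
    }
  }
})

test_that("blockage agrees with Eikonal reachability up to unresolved gaps", {
  # all disagreements must be continuum-open landscapes whose narrow gaps
  # (< h) close on the grid; a blocked verdict with a reachable far end
  # would be a genuine error
  tem <- feature_circle(1.5, "obstacle")
  dom <- fs_domain(40, 20)
  agree <- 0
  for (s in oracle_seeds(25, base = 2000)) {
    fs <- sample_feature_set(dom, density_for(0.58, tem), tem, seed = s)
    blocked <- spanning_blockage_exists(fs)
    af <- eikonal_solve(rasterize(fs, 1 / 30, 1, 0))
    reach <- any(is.finite(af$T[af$nx, ]))
    expect_false(blocked && reach)   # exact direction
    agree <- agree + (blocked == !reach)
  }
  expect_gte(agree, 22)
})

test_that("spanning probability saturates in the dense and dilute limits", {
  box <- 40
  span_at <- function(phi, seeds) {
    rho <- -log(1 - phi) / pi
    mean(vapply(seeds, function(s) {
      set.seed(s)
      n <- rpois(1, rho * box^2)
      frontscape:::discs_span_cpp(runif(n, 0, box), runif(n, 0, box), 1, box)
    }, logical(1)))
  }
  expect_gte(span_at(0.95, oracle_seeds(40)), 0.95)
  expect_lte(span_at(0.10, oracle_seeds(40)), 0.05)
})
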