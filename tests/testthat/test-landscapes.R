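test_that("pure landscapes hit their control points and plateau exactly", {
  L <- pmf_landscape(plateau = 0, well_depth = 40, well_pos = 2.0,
                     center_G = 150)
  expect_equal(L$evaluate(2.0), -40)
  expect_equal(L$evaluate(-2.0), -40)
  expect_equal(L$evaluate(0), 150)
  expect_equal(L$evaluate(4.5), 0)
  expect_equal(L$evaluate(-4.5), 0)

  # symmetric parameters give an exactly symmetric landscape
  z <- seq(-4.5, 4.5, by = 0.01)
  expect_equal(max(abs(L$evaluate(z) - L$evaluate(-z))), 0)

  # degenerate flat landscape
  F0 <- pmf_landscape(well_depth = 0, center_G = 0)
  expect_equal(max(abs(F0$evaluate(z))), 0)

  # nonzero plateau shifts the whole profile gauge
  Lp <- pmf_landscape(plateau = 10, well_depth = 40, center_G = 150)
  expect_equal(Lp$evaluate(4.5), 10)
  expect_equal(Lp$evaluate(2.0), -30)

  expect_error(pmf_landscape(widths = list(well = -1)), "widths")
})

test_that("landscape derivative matches a numerical derivative", {
  L <- pmf_landscape(well_depth = 40, center_G = 150,
                     headgroup_barrier = 20)
  z <- seq(-4.4, 4.4, by = 0.05)
  h <- 1e-6
  num <- (L$evaluate(z + h) - L$evaluate(z - h)) / (2 * h)
  expect_lt(max(abs(L$deriv(z) - num)), 1e-5)
})

test_that("blending is an exact convex combination with sigmoid weight", {
  up <- pmf_landscape(well_depth = 40, center_G = 166)
  lo <- pmf_landscape(well_depth = 10, center_G = 140)
  z <- seq(-4.5, 4.5, by = 0.02)

  # identity blend
  same <- blend_landscapes(up, up, blend_spec(0.3, 0.7))
  expect_equal(same$evaluate(z), up$evaluate(z))

  # step limit: lambda -> 0 selects one parent on each side
  stepb <- blend_landscapes(up, lo, blend_spec(0, 1e-6))
  zp <- z[z > 0.01]; zm <- z[z < -0.01]
  expect_lt(max(abs(stepb$evaluate(zp) - up$evaluate(zp))), 1e-6)
  expect_lt(max(abs(stepb$evaluate(zm) - lo$evaluate(zm))), 1e-6)

  # midpoint is the exact average at the switch center
  b <- blend_landscapes(up, lo, blend_spec(0, 0.25))
  expect_equal(b$evaluate(0), (up$evaluate(0) + lo$evaluate(0)) / 2)

  # pointwise convex combination for many random blend parameters
  set.seed(42)
  for (i in 1:10) {
    bs <- blend_spec(runif(1, -1, 1), runif(1, 0.05, 1))
    bi <- blend_landscapes(up, lo, bs)
    g <- bi$evaluate(z)
    expect_true(all(g >= pmin(up$evaluate(z), lo$evaluate(z)) - 1e-12))
    expect_true(all(g <= pmax(up$evaluate(z), lo$evaluate(z)) + 1e-12))
  }

  lo2 <- pmf_landscape(well_depth = 10, center_G = 140, support = c(-5, 5))
  expect_error(blend_landscapes(up, lo2, blend_spec()), "support")
  expect_error(blend_spec(0, 0), "lambda")
})

test_that("window schemes honour spacing, tiers and reproducibility", {
  sch <- window_scheme(c(-2.3, 2.3), center_band = c(-0.5, 0.5),
                       spacing_surface = 0.1, spacing_center = 0.05)
  gaps <- diff(sch$z0)
  expect_true(all(abs(gaps - 0.05) < 1e-9 | abs(gaps - 0.1) < 1e-9))
  expect_true(all(sch$k[sch$z0 > -0.5 + 1e-9 & sch$z0 < 0.5 - 1e-9] == 5000))

  # simple arithmetic case: 0.1 nm over [0, 1] gives 11 windows
  sch2 <- window_scheme(c(0, 1), spacing_surface = 0.1)
  expect_equal(nrow(sch2), 11)
  expect_equal(sch2$z0, seq(0, 1, 0.1))
  expect_true(all(sch2$tier == "intermediate"))

  # tiers: surface / intermediate / center carry their force constants
  sch3 <- tier_scheme()
  expect_true(all(sch3$k[sch3$tier == "center"] == 5000))
  expect_true(all(sch3$k[sch3$tier == "surface"] == 1000))
  expect_true(all(sch3$k[sch3$tier == "intermediate"] == 3000))
  expect_equal(diff(range(sch3$z0)), 9)

  # bit-exact reproducibility from parameters
  expect_identical(tier_scheme(), tier_scheme())

  expect_error(
    window_scheme(c(-1, 1), center_band = c(-0.5, 0.5),
                  surface_band = c(-0.6, 0)),
    "overlap")
  expect_error(window_scheme(c(-1, 1), center_band = c(0, 2)), "support")
})

test_that("harmonic-window sampling matches the Gaussian limit", {
  flat <- pmf_landscape(well_depth = 0, center_G = 0)
  sp <- sampler_params(n_steps = 40000, n_equil = 2000)
  ts <- sample_window(flat, list(z0 = 1.0, k = 5000), sp, seed = 7)
  z <- ts$z[-seq_len(2000)]
  expect_equal(mean(z), 1.0, tolerance = 0.01)
  expect_equal(var(z), kT310 / 5000, tolerance = 0.1)

  # linear landscape with a stiff spring: mean shifts by -c/k
  cslope <- 20
  lin <- raw_landscape(function(z) cslope * z, function(z) rep(cslope, length(z)))
  ts2 <- sample_window(lin, list(z0 = 1.0, k = 5000), sp, seed = 8)
  z2 <- ts2$z[-seq_len(2000)]
  expect_equal(mean(z2), 1.0 - cslope / 5000, tolerance = 0.01)

  # determinism: identical seeds give identical chains
  ts3 <- sample_window(flat, list(z0 = 1.0, k = 5000), sp, seed = 7)
  expect_identical(ts$z, ts3$z)
  ts4 <- sample_window(flat, list(z0 = 1.0, k = 5000), sp, seed = 9)
  expect_false(identical(ts$z, ts4$z))
})

test_that("sampling a window at a barrier top reproduces Boltzmann lobe masses", {
  # asymmetric double well: minima near +/-0.55 nm differing by ~3 kJ/mol
  dw <- raw_landscape(
    function(z) 25 * (z^2 - 0.3)^2 + 3 * z,
    function(z) 100 * z * (z^2 - 0.3) + 3,
    support = c(-2, 2))
  w <- list(z0 = 0, k = 50)
  oracle <- boltzmann_density(dw, w$z0, w$k, kT310)
  mass_pos_true <- sum(oracle$dens[oracle$z > 0]) / sum(oracle$dens)

  sp <- sampler_params(n_steps = 150000, n_equil = 5000)
  ts <- sample_window(dw, w, sp, seed = 21)
  z <- ts$z[-seq_len(5000)]
  mass_pos <- mean(z > 0)
  expect_equal(log(mass_pos / (1 - mass_pos)),
               log(mass_pos_true / (1 - mass_pos_true)),
               tolerance = 0.1)
})

test_that("empirical distributions approach the quadrature Boltzmann density", {
  L <- double_well_landscape()
  w <- list(z0 = 1.2, k = 1000)
  oracle <- boltzmann_density(L, w$z0, w$k, kT310)
  cdf_true <- cumsum(oracle$dens) / sum(oracle$dens)

  ks_dist <- function(n, seed) {
    sp <- sampler_params(n_steps = n, n_equil = 0)
    z <- sample_window(L, w, sp, seed = seed)$z
    ec <- stats::ecdf(z)
    max(abs(ec(oracle$z) - cdf_true))
  }
  seeds <- 1:4
  small <- mean(vapply(seeds, function(s) ks_dist(2000, s), numeric(1)))
  large <- mean(vapply(seeds, function(s) ks_dist(40000, s), numeric(1)))
  expect_lt(large, small)
  expect_lt(large, 0.03)
})

test_that("the Langevin scheme samples the harmonic window and flags instability", {
  flat <- pmf_landscape(well_depth = 0, center_G = 0)
  sp <- sampler_params(n_steps = 60000, n_equil = 5000,
                       scheme = "overdamped-langevin", D = 2e-4, dt = 1)
  ts <- sample_window(flat, list(z0 = 1.0, k = 1000), sp, seed = 5)
  z <- ts$z[-seq_len(5000)]
  expect_equal(mean(z), 1.0, tolerance = 0.02)
  expect_equal(var(z), kT310 / 1000, tolerance = 0.2)

  steep <- raw_landscape(function(z) 5000 * z, function(z) rep(5000, length(z)))
  sp_bad <- sampler_params(scheme = "overdamped-langevin", D = 0.05, dt = 1)
  expect_error(sample_window(steep, list(z0 = 0, k = 100), sp_bad, seed = 1),
               "Reduce dt")
})

test_that("landscape tabulation and sampler input validation behave", {
  L <- double_well_landscape()
  prof <- landscape_profile(L, dz = 0.05)
  expect_s3_class(prof, "fep")
  expect_equal(prof$G, L$evaluate(prof$z))

  expect_error(sample_window(L, list(z0 = 9, k = 100), sampler_params(), 1),
               "support")
  expect_error(sample_window(L, list(z0 = 0, k = 100), sampler_params()),
               "seed")
  expect_error(sampler_params(n_steps = 10, n_equil = 10), "n_steps")
})
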