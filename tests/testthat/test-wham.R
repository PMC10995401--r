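fake_ts <- function(z, n_equil = 0L, z0 = mean(z), k = 1000, label = "w") {
  out <- tibble::tibble(step = seq_along(z), z = z)
  class(out) <- c("window_timeseries", class(out))
  attr(out, "window") <- list(z0 = z0, k = k, label = label)
  attr(out, "n_equil") <- as.integer(n_equil)
  attr(out, "seed") <- 0L
  out
}

test_that("histogramming discards equilibration and covers sampled ranges", {
  set <- wham_settings(bin_width = 0.1)

  h1 <- histogram_windows(list(fake_ts(rep(1.0, 50))), set)
  expect_equal(sum(h1$counts > 0), 1)
  nz <- which(h1$counts[1, ] > 0)
  expect_true(h1$bin_edges[nz] <= 1.0 && 1.0 < h1$bin_edges[nz + 1])

  # n_equil = len - 1 leaves exactly one counted sample
  h2 <- histogram_windows(list(fake_ts(c(5, 5, 5, 2.05), n_equil = 3)), set)
  expect_equal(sum(h2$counts), 1)
  expect_equal(h2$n_samples, 1L)

  # disjoint windows share no nonzero bin
  h3 <- histogram_windows(list(fake_ts(runif(100, 0, 0.4)),
                               fake_ts(runif(100, 2, 2.4))), set)
  expect_equal(sum(h3$counts[1, ] > 0 & h3$counts[2, ] > 0), 0)

  expect_error(
    histogram_windows(list(fake_ts(c(1, 2), n_equil = 2, label = "w07")), set),
    "w07")
})

test_that("overlap matrix is the summed minimum of normalized histograms", {
  h <- structure(list(counts = rbind(c(5, 5, 0), c(5, 5, 0))),
                 class = "histogram_set")
  expect_equal(overlap_matrix(h), matrix(1, 2, 2))

  h2 <- structure(list(counts = rbind(c(10, 0, 0), c(0, 0, 10))),
                  class = "histogram_set")
  expect_equal(overlap_matrix(h2)[1, 2], 0)

  h3 <- structure(list(counts = rbind(c(1, 1, 0), c(0, 1, 1))),
                  class = "histogram_set")
  expect_equal(overlap_matrix(h3)[1, 2], 0.5)
  expect_equal(diag(overlap_matrix(h3)), c(1, 1))
})

test_that("a single unbiased window reproduces -kT log(histogram) exactly", {
  set.seed(1)
  z <- runif(5000, 0, 2)
  set <- wham_settings(bin_width = 0.1)
  h <- histogram_windows(list(fake_ts(z, k = 0)), set)
  fit <- solve_wham(h, tibble::tibble(z0 = 1, k = 0), set,
                    reference_region = c(0, 2))
  counts <- h$counts[1, h$counts[1, ] > 0]
  expected <- -set$kT * log(counts / sum(counts))
  d <- fit$profile$G - expected
  expect_lt(max(abs(d - mean(d))), 1e-9)
})

test_that("WHAM is gauge-invariant under constant bias offsets", {
  L <- double_well_landscape()
  sch <- window_scheme(c(-1, 3), spacing_surface = 0.2,
                       k_tiers = c(surface = 1000, intermediate = 1000,
                                   center = 1000))
  sp <- sampler_params(n_steps = 4000, n_equil = 500)
  ts <- sample_windows(L, sch, sp, seed = 3)
  set <- wham_settings(tol = 1e-8)
  h <- histogram_windows(ts, set)

  fit0 <- solve_wham(h, sch, set, reference_region = c(2.5, 3))
  sch_off <- sch
  sch_off$u_offset <- 17.3
  fit1 <- solve_wham(h, sch_off, set, reference_region = c(2.5, 3))
  expect_equal(fit1$profile$G, fit0$profile$G, tolerance = 1e-6)
})

test_that("WHAM recovers a flat landscape to within noise", {
  flat <- pmf_landscape(well_depth = 0, center_G = 0)
  sch <- window_scheme(c(-2, 2), spacing_surface = 0.2,
                       k_tiers = c(surface = 200, intermediate = 200,
                                   center = 200))
  sp <- sampler_params(n_steps = 10000, n_equil = 1000)
  ts <- sample_windows(flat, sch, sp, seed = 17)
  set <- wham_settings()
  fit <- solve_wham(histogram_windows(ts, set), sch, set,
                    reference_region = c(-2, 2))
  # inside the window-covered range the profile is flat to within noise;
  # the sparsely sampled fringe beyond the outermost windows is noisier
  inside <- abs(fit$profile$z) <= 2
  expect_lt(max(abs(fit$profile$G[inside])), 2)
  expect_lt(sqrt(mean(fit$profile$G[inside]^2)), 0.5)
  expect_lt(fit$residual, set$tol)
  expect_gt(fit$iterations, 1)
})

test_that("WHAM agrees with an independent maximum-likelihood solution", {
  L <- pmf_landscape(well_depth = 15, center_G = 40, support = c(-4.5, 4.5))
  sch <- window_scheme(c(-0.5, 3), spacing_surface = 0.15,
                       k_tiers = c(surface = 300, intermediate = 300,
                                   center = 300))
  sp <- sampler_params(n_steps = 3000, n_equil = 300)
  ts <- sample_windows(L, sch, sp, seed = 5)
  set <- wham_settings(tol = 1e-9)
  h <- histogram_windows(ts, set)
  fit <- solve_wham(h, sch, set, reference_region = c(2.5, 3))
  ref <- reference_wham(h, sch, set$kT)
  expect_true(ref$converged)
  expect_lt(max_gauge_dev(fit$profile$z, fit$profile$G, ref$z, ref$G), 0.05)
})

test_that("disconnected window sets and non-convergence raise errors", {
  set <- wham_settings(bin_width = 0.1)
  ts <- list(fake_ts(seq(0, 0.3, 0.01), z0 = 0.15),
             fake_ts(seq(2, 2.3, 0.01), z0 = 2.15))
  h <- histogram_windows(ts, set)
  expect_error(solve_wham(h, tibble::tibble(z0 = c(0.15, 2.15), k = 1000), set),
               "disconnected")

  L <- double_well_landscape()
  sch <- window_scheme(c(1, 3), spacing_surface = 0.1,
                       k_tiers = c(surface = 500, intermediate = 500,
                                   center = 500))
  sp <- sampler_params(n_steps = 2000, n_equil = 200)
  ts2 <- sample_windows(L, sch, sp, seed = 2)
  tight <- wham_settings(tol = 1e-12, max_iter = 3)
  expect_error(solve_wham(histogram_windows(ts2, tight), sch, tight),
               "converge")
})

test_that("bootstrap errors behave: zero for constant data, honest otherwise", {
  set <- wham_settings(bin_width = 0.05, n_bootstrap = 4)
  # constant chains resample to themselves: err is identically zero
  ts_const <- list(fake_ts(rep(1.0, 200), z0 = 1, k = 1000),
                   fake_ts(rep(1.02, 200), z0 = 1.02, k = 1000))
  fit0 <- bootstrap_error(ts_const, tibble::tibble(z0 = c(1, 1.02), k = 1000),
                          set, seed = 1, reference_region = c(0.9, 1.1))
  expect_true(all(fit0$profile$err == 0))

  flat <- pmf_landscape(well_depth = 0, center_G = 0)
  sch <- window_scheme(c(-1, 1), spacing_surface = 0.2,
                      k_tiers = c(surface = 200, intermediate = 200,
                                  center = 200))
  sp <- sampler_params(n_steps = 8000, n_equil = 800)
  ts <- sample_windows(flat, sch, sp, seed = 31)
  set2 <- wham_settings(n_bootstrap = 8)
  fit <- bootstrap_error(ts, sch, set2, seed = 4,
                         reference_region = c(-1, 1))
  expect_true(all(is.finite(fit$profile$err)))
  expect_lt(median(fit$profile$err), 1)

  # the error band has the scale of the actual deviations from flatness
  # over the window-covered range (not an order of magnitude off)
  inside <- abs(fit$profile$z) <= 1
  dev <- abs(fit$profile$G - mean(fit$profile$G[inside]))
  ratio <- median(dev[inside]) / median(fit$profile$err[inside])
  expect_gt(ratio, 0.2)
  expect_lt(ratio, 5)

  expect_error(bootstrap_error(ts, sch, wham_settings(n_bootstrap = 1),
                               seed = 1), "n_bootstrap")
})

test_that("more sampling shrinks the bootstrap error band", {
  flat <- pmf_landscape(well_depth = 0, center_G = 0)
  sch <- window_scheme(c(-0.5, 0.5), spacing_surface = 0.25,
                       k_tiers = c(surface = 150, intermediate = 150,
                                   center = 150))
  set <- wham_settings(n_bootstrap = 6)
  med_err <- function(n) {
    sp <- sampler_params(n_steps = n, n_equil = n %/% 10)
    ts <- sample_windows(flat, sch, sp, seed = 13)
    median(bootstrap_error(ts, sch, set, seed = 2,
                           reference_region = c(-0.5, 0.5))$profile$err)
  }
  expect_lt(med_err(16000), med_err(2000))
})

test_that("tidy and glance expose the fit profile and solver summary", {
  flat <- pmf_landscape(well_depth = 0, center_G = 0)
  sch <- window_scheme(c(-0.5, 0.5), spacing_surface = 0.25,
                       k_tiers = c(surface = 150, intermediate = 150,
                                   center = 150))
  sp <- sampler_params(n_steps = 2000, n_equil = 200)
  ts <- sample_windows(flat, sch, sp, seed = 1)
  set <- wham_settings()
  fit <- solve_wham(histogram_windows(ts, set), sch, set)
  td <- tidy(fit)
  expect_true(all(c("z", "G") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_windows, nrow(sch))
  expect_lt(gl$residual, gl$tol)
})
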