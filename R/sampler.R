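#' Sampler controls for biased window sampling
#'
#' @param kT Thermal energy (kJ/mol); default is kT at 310 K.
#' @param D Diffusion coefficient for the Langevin scheme (nm2 per step
#'   unit).
#' @param dt Time step (step units) for the Langevin scheme.
#' @param n_steps Chain length per window (samples recorded every step).
#' @param n_equil Leading samples marked as equilibration; they are kept
#'   in the timeseries but discarded by [histogram_windows()].
#' @param scheme `"metropolis"` (random-walk Metropolis, exact
#'   discrete-time Boltzmann stationary distribution, the default) or
#'   `"overdamped-langevin"` (Euler--Maruyama; carries an O(dt)
#'   stationary bias, provided for completeness).
#' @param proposal_sd Metropolis proposal standard deviation (nm); by
#'   default scaled to the window stiffness as 2 sqrt(kT / k).
#' @param grid_dz Spacing of the potential tabulation used by the
#'   compiled samplers (nm).
#' @return A list of class `sampler_params`.
#' @export
sampler_params <- function(kT = kT_at(310), D = 5e-4, dt = 1,
                           n_steps = 20000, n_equil = 1000,
                           scheme = c("metropolis", "overdamped-langevin"),
                           proposal_sd = NULL, grid_dz = 5e-4) {
  scheme <- match.arg(scheme)
  if (kT <= 0 || D <= 0 || dt <= 0) {
    abort("`kT`, `D` and `dt` must all be positive.")
  }
  if (n_equil < 0 || n_steps <= n_equil) {
    abort("Need n_steps > n_equil >= 0.")
  }
  structure(list(kT = kT, D = D, dt = dt, n_steps = as.integer(n_steps),
                 n_equil = as.integer(n_equil), scheme = scheme,
                 proposal_sd = proposal_sd, grid_dz = grid_dz),
            class = "sampler_params")
}

#' Sample one umbrella window on a landscape
#'
#' Draws a reproducible Markov chain from the biased Boltzmann
#' distribution exp(-U(z)/kT) with U(z) = G(z) + (k/2)(z - z0)^2, the
#' stand-in for a per-window MD trajectory of the collective variable.
#' The chain is the Metropolis or Euler--Maruyama scheme from
#' [sampler_params()]; the first `n_equil` samples are flagged as
#' equilibration (mirroring the discard of the initial stretch of each
#' umbrella window in production free-energy calculations).
#'
#' @param landscape A `pmf_landscape` (the unbiased free energy).
#' @param window One-row data frame (or list) with `z0` and `k`, e.g. a
#'   row of a [window_scheme()] tibble.
#' @param sp A [sampler_params()] object.
#' @param seed Integer seed; required, no global RNG state is consumed.
#' @return A tibble of class `window_timeseries` with columns `step` and
#'   `z` (nm), carrying `window`, `seed` and `n_equil` attributes.
#' @examples
#' L <- pmf_landscape(well_depth = 0, center_G = 0)
#' ts <- sample_window(L, list(z0 = 1, k = 5000),
#'                     sampler_params(n_steps = 2000, n_equil = 100), seed = 1)
#' mean(ts$z[-(1:100)])
#' @export
sample_window <- function(landscape, window, sp = sampler_params(), seed) {
  stopifnot(inherits(landscape, "pmf_landscape"))
  if (missing(seed)) abort("`seed` must be given explicitly.")
  z0 <- as.numeric(window$z0)
  k <- as.numeric(window$k)
  if (!is.finite(z0) || !is.finite(k) || k < 0) {
    abort("Window needs finite `z0` and non-negative `k`.")
  }
  if (z0 < landscape$support[1] || z0 > landscape$support[2]) {
    abort("Window reference position lies outside the landscape support.")
  }

  zg <- seq(landscape$support[1], landscape$support[2], by = sp$grid_dz)
  U <- landscape$evaluate(zg) + umbrella_bias(zg, z0, k)
  z_init <- zg[which.min(U)]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  z <- switch(sp$scheme,
    "metropolis" = {
      psd <- sp$proposal_sd %||%
        min(2 * sqrt(sp$kT / max(k, 1e-8)), 0.5)
      metropolis_chain(U, zg[1], sp$grid_dz, sp$kT, z_init,
                       sp$n_steps, psd)
    },
    "overdamped-langevin" =
      langevin_chain(U, zg[1], sp$grid_dz, sp$kT, z_init,
                     sp$n_steps, sp$D, sp$dt, drift_max = 0.5)
  )

  out <- tibble(step = seq_along(z), z = z)
  class(out) <- c("window_timeseries", class(out))
  attr(out, "window") <- list(z0 = z0, k = k,
                              label = window$label %||% NA_character_)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_equil") <- sp$n_equil
  out
}

#' Sample every window of a scheme
#'
#' @param landscape A `pmf_landscape`.
#' @param scheme A [window_scheme()] tibble.
#' @param sp A [sampler_params()].
#' @param seed Base integer seed; window i uses `seed + i - 1`.
#' @return A list of `window_timeseries`, one per window, in scheme order.
#' @export
sample_windows <- function(landscape, scheme, sp = sampler_params(), seed) {
  if (missing(seed)) abort("`seed` must be given explicitly.")
  purrr::map(seq_len(nrow(scheme)), function(i) {
    sample_window(landscape, scheme[i, ], sp, seed = seed + i - 1L)
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
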