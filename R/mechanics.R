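#' Stress-tensor profile container
#'
#' @param df Data frame with columns `z` (nm) and `sigma_xx`, `sigma_yy`,
#'   `sigma_zz` (bar).
#' @param gamma_true Optional named numeric `c(gamma_plus=, gamma_minus=)`
#'   (mN/m): the closed-form leaflet tensions implied by the generating
#'   parameters of a synthetic profile.
#' @return A tibble of class `stress_profile`.
#' @export
as_stress_profile <- function(df, gamma_true = NULL) {
  df <- as_tibble(df)
  need <- c("z", "sigma_xx", "sigma_yy", "sigma_zz")
  if (!all(need %in% names(df))) {
    abort(sprintf("Stress profile needs columns: %s.",
                  paste(need, collapse = ", ")))
  }
  if (any(!is.finite(as.matrix(df[need])))) {
    abort("Stress profile values must be finite.")
  }
  if (any(diff(df$z) <= 0)) abort("`z` must be strictly increasing.")
  class(df) <- c("stress_profile", class(df))
  attr(df, "gamma_true") <- gamma_true
  df
}

# half-space integral of a Gaussian lobe: amp * integral_{lo}^{hi} g dz
gauss_halfspace <- function(center, width, lo = -Inf, hi = Inf) {
  width * sqrt(2 * pi) * (pnorm(hi, center, width) - pnorm(lo, center, width))
}

#' Generate a synthetic stress profile with prescribed leaflet tensions
#'
#' Builds sigma(z) so that the differential stress P_N - P_L consists of
#' two Gaussian lobes centered in the two leaflets, with amplitudes
#' solved in closed form (Gaussian half-space integrals) so that the
#' leaflet tensions take exactly the requested values.  The implied
#' gamma's are recorded in the profile metadata for downstream checks.
#' Sign convention: a negative gamma_plus means a compressed upper
#' leaflet.  Units: bar and nm in, mN/m targets (1 bar nm = 0.1 mN/m).
#'
#' @param gamma_plus,gamma_minus Target leaflet tensions (mN/m); tensions
#'   of a few mN/m are typical of area-matched asymmetric bilayers, while
#'   number-asymmetric ones can reach tens of mN/m.
#' @param lobe_z Distance of the lobe centers from the midplane (nm).
#' @param lobe_width Gaussian width of each lobe (nm).
#' @param midplane True midplane position (nm); the grid is laid out
#'   around it.
#' @param half_range Grid half-extent around the midplane (nm).
#' @param dz Grid spacing (nm).
#' @param P_N Constant normal pressure (bar); sigma_zz = -P_N.
#' @return A `stress_profile` with `gamma_true` metadata.
#' @examples
#' s <- make_stress_profile(gamma_plus = -4, gamma_minus = 4)
#' attr(s, "gamma_true")
#' @export
make_stress_profile <- function(gamma_plus = -4, gamma_minus = 4,
                                lobe_z = 1.0, lobe_width = 0.3,
                                midplane = 0, half_range = 4,
                                dz = 0.01, P_N = 0) {
  if (lobe_width <= 0 || lobe_z <= 0 || dz <= 0) {
    abort("`lobe_z`, `lobe_width` and `dz` must be positive.")
  }
  # lobes at midplane +/- lobe_z; solve amplitudes so the half-space
  # integrals (in bar nm, converted by 0.1 to mN/m) hit the targets,
  # accounting for each lobe's leakage across the midplane
  Ipp <- gauss_halfspace(lobe_z, lobe_width, lo = 0)    # upper lobe, upper side
  Ipm <- gauss_halfspace(lobe_z, lobe_width, hi = 0)    # upper lobe, lower side
  A <- matrix(c(Ipp, Ipm,
                Ipm, Ipp), 2, 2, byrow = TRUE) * 0.1    # bar nm -> mN/m
  amps <- solve(A, c(gamma_plus, gamma_minus))

  z <- seq(midplane - half_range, midplane + half_range, by = dz)
  zc <- z - midplane
  diffstress <- amps[1] * exp(-(zc - lobe_z)^2 / (2 * lobe_width^2)) +
                amps[2] * exp(-(zc + lobe_z)^2 / (2 * lobe_width^2))
  # P_N - P_L = diffstress; with sigma_zz = -P_N, sigma_xx = sigma_yy = -P_L
  P_L <- P_N - diffstress
  as_stress_profile(
    tibble(z = z, sigma_xx = -P_L, sigma_yy = -P_L, sigma_zz = -P_N),
    gamma_true = c(gamma_plus = gamma_plus, gamma_minus = gamma_minus)
  )
}

#' Lateral and normal pressure from a stress profile
#'
#' Pointwise application of P_L = -(sigma_xx + sigma_yy)/2 and
#' P_N = -sigma_zz.
#'
#' @param s A `stress_profile`.
#' @return A tibble of class `pressure_profile` with columns `z`, `P_L`,
#'   `P_N` (bar); synthetic-tension metadata is carried through.
#' @export
pressures_from_stress <- function(s) {
  stopifnot(inherits(s, "stress_profile"))
  out <- tibble(z = s$z,
                P_L = -(s$sigma_xx + s$sigma_yy) / 2,
                P_N = -s$sigma_zz)
  class(out) <- c("pressure_profile", class(out))
  attr(out, "gamma_true") <- attr(s, "gamma_true")
  out
}

#' Membrane midplane from a lipid tail density profile
#'
#' The midplane is taken as the density-weighted mean position of the
#' lipid tail density (the membrane core).  An alternative convention --
#' the midpoint between the two outermost density peaks, for use with
#' headgroup densities -- is available via `method = "peaks"`.  Both are
#' documented conventions, not unique definitions.
#'
#' @param d Data frame with columns `z` (nm) and `rho` (>= 0).
#' @param method `"mean"` (default) or `"peaks"`.
#' @return Midplane position z0 (nm).
#' @export
midplane_from_density <- function(d, method = c("mean", "peaks")) {
  method <- match.arg(method)
  if (!all(c("z", "rho") %in% names(d))) {
    abort("Density profile needs columns `z` and `rho`.")
  }
  if (any(d$rho < 0)) abort("Density must be non-negative.")
  if (sum(d$rho) == 0) abort("Density profile is identically zero.")
  if (method == "mean") {
    sum(d$z * d$rho) / sum(d$rho)
  } else {
    pk <- local_extrema(-d$rho, "min")  # maxima of rho
    pk <- pk[d$rho[pk] > 0.1 * max(d$rho)]
    if (length(pk) < 2) {
      abort("Need two density peaks for the 'peaks' midplane convention.")
    }
    (d$z[pk[1]] + d$z[pk[length(pk)]]) / 2
  }
}

#' Leaflet tensions from a pressure profile
#'
#' Integrates the differential stress P_N - P_L above the midplane for
#' the upper-leaflet tension gamma_plus and below it for gamma_minus
#' (trapezoidal quadrature; a grid point is inserted at the midplane by
#' linear interpolation so the split is exact and the total
#' gamma_plus + gamma_minus is independent of the midplane choice).
#' Units: input bar and nm; output mN/m with 1 bar nm = 0.1 mN/m.
#'
#' @param p A `pressure_profile` from [pressures_from_stress()].
#' @param z0 Midplane position (nm), e.g. from [midplane_from_density()].
#' @return One-row tibble of class `leaflet_tensions`: `gamma_plus`,
#'   `gamma_minus`, `total` (mN/m) and `midplane_z` (nm).
#' @export
leaflet_tensions <- function(p, z0) {
  stopifnot(inherits(p, "pressure_profile"))
  if (z0 < min(p$z) || z0 > max(p$z)) {
    abort("Midplane `z0` lies outside the pressure-profile grid.")
  }
  z <- p$z
  ds <- p$P_N - p$P_L
  if (!z0 %in% z) {
    d0 <- approx(z, ds, xout = z0)$y
    ord <- order(c(z, z0))
    ds <- c(ds, d0)[ord]
    z <- c(z, z0)[ord]
  }
  trap <- function(x, y) {
    if (length(x) < 2) return(0)
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  }
  up <- z >= z0
  lo <- z <= z0
  gp <- 0.1 * trap(z[up] - z0, ds[up])
  gm <- 0.1 * trap(z[lo] - z0, ds[lo])
  out <- tibble(gamma_plus = gp, gamma_minus = gm,
                total = gp + gm, midplane_z = z0)
  class(out) <- c("leaflet_tensions", class(out))
  out
}

#' Synthetic lipid tail density profile
#'
#' A single Gaussian lobe centered at the membrane midplane, the shape a
#' lipid tail density takes along the membrane normal.
#'
#' @param midplane Center (nm).
#' @param width Gaussian width (nm).
#' @param half_range Grid half-extent (nm).
#' @param dz Grid spacing (nm).
#' @return A tibble with columns `z` and `rho`.
#' @export
make_density_profile <- function(midplane = 0, width = 1.0,
                                 half_range = 4, dz = 0.01) {
  z <- seq(midplane - half_range, midplane + half_range, by = dz)
  tibble(z = z, rho = exp(-(z - midplane)^2 / (2 * width^2)))
}
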