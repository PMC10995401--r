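#' Free-energy profile objects
#'
#' A free-energy profile is a tibble with columns `z` (position along the
#' collective variable, nm), `G` (free energy, kJ/mol) and optionally
#' `err` (pointwise uncertainty, kJ/mol), carrying a `reference` attribute
#' describing where G was anchored to zero.  Only free-energy
#' *differences* are physical; the reference fixes the gauge.
#'
#' @param z Numeric grid, strictly increasing (nm).
#' @param G Free energy at each grid point (kJ/mol).
#' @param err Optional pointwise error band (kJ/mol).
#' @param reference Text describing the zero-reference convention.
#' @param kT Thermal energy the profile was computed at (kJ/mol), if known.
#' @return A tibble of class `fep`.
#' @examples
#' fep(z = seq(-3, 3, 0.1), G = 150 * exp(-seq(-3, 3, 0.1)^2))
#' @export
fep <- function(z, G, err = NULL, reference = "unreferenced", kT = NULL) {
  z <- as.numeric(z)
  G <- as.numeric(G)
  if (length(z) != length(G)) {
    abort("`z` and `G` must have the same length.")
  }
  if (length(z) < 1 || any(diff(z) <= 0)) {
    abort("`z` must be non-empty and strictly increasing.")
  }
  if (!is.null(err) && length(err) != length(z)) {
    abort("`err` must match the grid length.")
  }
  out <- tibble(z = z, G = G)
  if (!is.null(err)) out$err <- as.numeric(err)
  new_fep(out, reference = reference, kT = kT)
}

new_fep <- function(x, reference = "unreferenced", kT = NULL) {
  x <- as_tibble(x)
  class(x) <- c("fep", class(x))
  attr(x, "reference") <- reference
  attr(x, "kT") <- kT
  x
}

#' @export
is_fep <- function(x) inherits(x, "fep")

# reapply fep attributes after dplyr/tidyr operations strip them
restore_fep <- function(x, template) {
  new_fep(x,
          reference = attr(template, "reference") %||% "unreferenced",
          kT = attr(template, "kT"))
}

#' Interpolate a free-energy profile onto new positions
#'
#' Monotone (Fritsch--Carlson) cubic interpolation is used for `G`, which
#' cannot overshoot between grid points -- important near sharp headgroup
#' and central barriers.  The error band, when present, is interpolated
#' linearly.  Positions outside the profile's support return `NA`.
#'
#' @param p A [fep] profile.
#' @param z_out Positions to evaluate at (nm).
#' @return A tibble with columns `z`, `G` and (if present in `p`) `err`.
#' @export
fep_interp <- function(p, z_out) {
  stopifnot(is_fep(p))
  z_out <- as.numeric(z_out)
  f <- splinefun(p$z, p$G, method = "monoH.FC")
  G <- f(z_out)
  G[z_out < min(p$z) - 1e-12 | z_out > max(p$z) + 1e-12] <- NA_real_
  out <- tibble(z = z_out, G = G)
  if ("err" %in% names(p)) {
    out$err <- approx(p$z, p$err, xout = z_out, rule = 1)$y
  }
  out
}

fep_range <- function(p) range(p$z)

#' Shift a profile so its mean over a solvent region is zero
#'
#' Free-energy profiles are anchored so that the solvent plateau sits at
#' G = 0; this applies the constant shift `-mean(G)` over the stated
#' region.  The error band is unchanged (a constant shift carries no
#' uncertainty of its own in the gauge convention used here).
#'
#' @param p A [fep] profile.
#' @param region Length-2 numeric interval (nm) to average over.
#' @return The shifted [fep], with its `reference` attribute updated.
#' @examples
#' p <- fep(z = seq(0, 5, 0.1), G = rep(7, 51))
#' zero_reference(p, c(4, 5))$G[1]
#' @export
zero_reference <- function(p, region) {
  stopifnot(is_fep(p))
  region <- check_interval(region)
  sel <- p$z >= region[1] & p$z <= region[2]
  if (!any(sel)) {
    abort(sprintf("Reference region [%g, %g] contains no grid points.",
                  region[1], region[2]))
  }
  shift <- mean(p$G[sel])
  p$G <- p$G - shift
  attr(p, "reference") <- sprintf("mean G over [%g, %g] nm set to 0",
                                  region[1], region[2])
  attr(p, "shift_applied") <- -shift
  p
}

check_interval <- function(x, arg = "region") {
  if (!is.numeric(x) || length(x) != 2 || any(!is.finite(x)) || x[1] > x[2]) {
    abort(sprintf("`%s` must be a finite numeric interval c(lo, hi).", arg))
  }
  as.numeric(x)
}

#' @export
print.fep <- function(x, ...) {
  cat(sprintf("# Free-energy profile: %d points on [%.3g, %.3g] nm\n",
              nrow(x), min(x$z), max(x$z)))
  cat(sprintf("# reference: %s\n", attr(x, "reference") %||% "unreferenced"))
  NextMethod()
}
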