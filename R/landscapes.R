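#' Parametric ground-truth translocation landscapes
#'
#' Builds an analytic potential of mean force G(z) with the features seen
#' in peptide translocation profiles: a solvent plateau, two adsorption
#' minima at the membrane surfaces, optional headgroup barriers, and a
#' central barrier.  The landscape is a sum of Gaussian wells/barriers
#' whose amplitudes are solved from the requested control-point values,
#' so `G(well_pos) = plateau - well_depth`, `G(0) = center_G` and
#' `G(headgroup_pos) = plateau + headgroup_barrier` hold exactly.  A
#' smooth C1 taper forces G to the plateau value exactly beyond the
#' solvent boundary.  Symmetric parameters give a landscape symmetric
#' under z -> -z; asymmetric-membrane landscapes are obtained by
#' [blend_landscapes()].
#'
#' @param plateau Solvent plateau free energy (kJ/mol), the gauge zero.
#' @param well_depth Depth of the adsorption minima below the plateau
#'   (kJ/mol, positive = attractive).
#' @param well_pos Position of the adsorption minima at `+/- well_pos` (nm).
#' @param center_G Free energy at the membrane center z = 0 (kJ/mol).
#' @param headgroup_barrier Height of the headgroup barriers above the
#'   plateau (kJ/mol); 0 disables them.
#' @param headgroup_pos Position of the headgroup barriers (nm); defaults
#'   to half the well position.
#' @param widths Named list of Gaussian widths in nm: `well`, `center`,
#'   `head`.  All must be positive.
#' @param support Interval (nm) on which the landscape is defined.
#' @param solvent_boundary |z| beyond which G equals the plateau exactly (nm).
#' @param taper_width Width of the C1 taper to the plateau (nm).
#' @param label Text label.
#' @return An object of class `pmf_landscape` with elements `label`,
#'   `params`, `support` and vectorised functions `evaluate(z)` and
#'   `deriv(z)`.
#' @examples
#' L <- pmf_landscape(well_depth = 40, center_G = 150)
#' L$evaluate(c(-2, 0, 2, 4.5))
#' @export
pmf_landscape <- function(plateau = 0,
                          well_depth = 0,
                          well_pos = 2.0,
                          center_G = 0,
                          headgroup_barrier = 0,
                          headgroup_pos = well_pos / 2,
                          widths = list(well = 0.35, center = 0.5, head = 0.2),
                          support = c(-4.5, 4.5),
                          solvent_boundary = 4.0,
                          taper_width = 0.5,
                          label = "landscape") {
  widths <- utils::modifyList(list(well = 0.35, center = 0.5, head = 0.2),
                              as.list(widths))
  if (any(unlist(widths) <= 0)) {
    abort("All landscape `widths` must be positive.")
  }
  support <- check_interval(support, "support")
  if (well_pos <= 0 || well_pos > solvent_boundary - taper_width) {
    abort("`well_pos` must lie inside the untapered region.")
  }
  if (solvent_boundary > max(abs(support))) {
    abort("`solvent_boundary` must lie within the support.")
  }

  use_head <- headgroup_barrier != 0
  # symmetric Gaussian basis: paired wells, paired headgroup bumps, center
  basis <- list(
    well = function(z) exp(-(z - well_pos)^2 / (2 * widths$well^2)) +
                       exp(-(z + well_pos)^2 / (2 * widths$well^2)),
    center = function(z) exp(-z^2 / (2 * widths$center^2))
  )
  ctrl_z <- c(well_pos, 0)
  ctrl_target <- c(-well_depth, center_G - plateau)
  if (use_head) {
    basis$head <- function(z) exp(-(z - headgroup_pos)^2 / (2 * widths$head^2)) +
                              exp(-(z + headgroup_pos)^2 / (2 * widths$head^2))
    ctrl_z <- c(ctrl_z, headgroup_pos)
    ctrl_target <- c(ctrl_target, headgroup_barrier)
  }
  A <- vapply(basis, function(f) f(ctrl_z), numeric(length(ctrl_z)))
  A <- matrix(A, nrow = length(ctrl_z))
  amps <- tryCatch(solve(A, ctrl_target), error = function(e) {
    abort("Landscape control points are degenerate; adjust positions/widths.")
  })

  dev <- function(z) {
    out <- 0
    for (i in seq_along(basis)) out <- out + amps[[i]] * basis[[i]](z)
    out
  }
  dbasis <- list(
    well = function(z) -(z - well_pos) / widths$well^2 *
             exp(-(z - well_pos)^2 / (2 * widths$well^2)) -
             (z + well_pos) / widths$well^2 *
             exp(-(z + well_pos)^2 / (2 * widths$well^2)),
    center = function(z) -z / widths$center^2 * exp(-z^2 / (2 * widths$center^2))
  )
  if (use_head) {
    dbasis$head <- function(z) -(z - headgroup_pos) / widths$head^2 *
        exp(-(z - headgroup_pos)^2 / (2 * widths$head^2)) -
        (z + headgroup_pos) / widths$head^2 *
        exp(-(z + headgroup_pos)^2 / (2 * widths$head^2))
  }
  ddev <- function(z) {
    out <- 0
    for (i in seq_along(basis)) out <- out + amps[[i]] * dbasis[[i]](z)
    out
  }

  zs <- solvent_boundary
  tw <- taper_width
  taper <- function(z) {
    u <- pmin(pmax((abs(z) - (zs - tw)) / tw, 0), 1)
    1 - (3 * u^2 - 2 * u^3)
  }
  dtaper <- function(z) {
    u <- (abs(z) - (zs - tw)) / tw
    inside <- u > 0 & u < 1
    out <- numeric(length(z))
    out[inside] <- -(6 * u[inside] - 6 * u[inside]^2) / tw * sign(z[inside])
    out
  }

  structure(
    list(
      label = label,
      params = list(solvent_plateau_G = plateau,
                    adsorption_well_depth = well_depth,
                    adsorption_well_pos = well_pos,
                    headgroup_barrier = headgroup_barrier,
                    headgroup_pos = headgroup_pos,
                    center_G = center_G,
                    widths = widths,
                    solvent_boundary = solvent_boundary,
                    taper_width = taper_width),
      support = support,
      evaluate = function(z) plateau + taper(z) * dev(z),
      deriv = function(z) dtaper(z) * dev(z) + taper(z) * ddev(z)
    ),
    class = "pmf_landscape"
  )
}

#' @export
print.pmf_landscape <- function(x, ...) {
  p <- x$params
  cat(sprintf("<pmf_landscape '%s'> support [%g, %g] nm\n",
              x$label, x$support[1], x$support[2]))
  if (!is.null(p)) {
    cat(sprintf("  plateau %g, wells %g at +/-%g nm, center %g kJ/mol\n",
                p$solvent_plateau_G, -p$adsorption_well_depth,
                p$adsorption_well_pos, p$center_G))
  }
  invisible(x)
}

#' Sigmoidal blend specification for asymmetric landscapes
#'
#' Defines the weight w(z) = 1 / (1 + exp((z - z_c) / lambda)) used to
#' blend two pure-membrane landscapes into an asymmetric one.  w -> 1
#' well below the switch (lower-leaflet side), w -> 0 well above it.
#'
#' @param z_c Switch center (nm).
#' @param lambda Switch width (nm), > 0.
#' @return A `blend_spec` object with a vectorised `weight(z)` function.
#' @export
blend_spec <- function(z_c = 0, lambda = 0.25) {
  if (!is.numeric(lambda) || lambda <= 0) {
    abort("Blend width `lambda` must be > 0.")
  }
  structure(
    list(z_c = z_c, lambda = lambda,
         weight = function(z) stats::plogis((z_c - z) / lambda)),
    class = "blend_spec"
  )
}

#' Blend two pure-membrane landscapes into an asymmetric landscape
#'
#' Realises the three-region structure of asymmetric-membrane
#' translocation profiles: near each leaflet the blended landscape
#' coincides with the corresponding pure-membrane landscape, and it
#' transitions gradually between them across the switch region.
#' G_asym(z) = w(z) G_lower(z) + (1 - w(z)) G_upper(z), a pointwise
#' convex combination.
#'
#' @param upper Landscape governing the upper-leaflet side (z > z_c).
#' @param lower Landscape governing the lower-leaflet side (z < z_c).
#' @param blend A [blend_spec()].
#' @return A `pmf_landscape` whose `params` records the parents and blend.
#' @examples
#' up <- pmf_landscape(well_depth = 40, center_G = 166)
#' lo <- pmf_landscape(well_depth = 10, center_G = 140)
#' asym <- blend_landscapes(up, lo, blend_spec(0, 0.25))
#' @export
blend_landscapes <- function(upper, lower, blend = blend_spec()) {
  stopifnot(inherits(upper, "pmf_landscape"), inherits(lower, "pmf_landscape"),
            inherits(blend, "blend_spec"))
  if (!isTRUE(all.equal(upper$support, lower$support))) {
    abort("Landscapes to blend must share the same support.")
  }
  w <- blend$weight
  lam <- blend$lambda
  structure(
    list(
      label = sprintf("%s/%s blend", upper$label, lower$label),
      params = list(upper = upper$params, lower = lower$params,
                    blend = list(z_c = blend$z_c, lambda = lam)),
      support = upper$support,
      evaluate = function(z) {
        wz <- w(z)
        wz * lower$evaluate(z) + (1 - wz) * upper$evaluate(z)
      },
      deriv = function(z) {
        wz <- w(z)
        dw <- -wz * (1 - wz) / lam
        dw * (lower$evaluate(z) - upper$evaluate(z)) +
          wz * lower$deriv(z) + (1 - wz) * upper$deriv(z)
      }
    ),
    class = "pmf_landscape"
  )
}

#' Tabulate a landscape as a free-energy profile
#'
#' @param landscape A `pmf_landscape`.
#' @param dz Grid spacing (nm).
#' @return A [fep] profile on a regular grid over the landscape support.
#' @export
landscape_profile <- function(landscape, dz = 0.02) {
  stopifnot(inherits(landscape, "pmf_landscape"), dz > 0)
  z <- seq(landscape$support[1], landscape$support[2], by = dz)
  fep(z = z, G = landscape$evaluate(z),
      reference = sprintf("analytic landscape '%s'", landscape$label))
}
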