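#' Coordinate snapshots for collective-variable evaluation
#'
#' A snapshot is a tibble of particles with columns `x`, `y`, `z` (nm),
#' `mass` (amu) and `role` (one of `"membrane"`, `"probe"`, `"other"`),
#' plus a `box` attribute `c(Lx, Ly, Lz)` in nm.  The `probe` role marks
#' the group whose insertion depth is measured (e.g. the three terminal
#' backbone beads of a peptide).
#'
#' @param particles Data frame with the columns above.
#' @param box Numeric length-3 box vector (nm).
#' @return A tibble of class `snapshot`.
#' @export
snapshot <- function(particles, box) {
  particles <- as_tibble(particles)
  need <- c("x", "y", "z", "mass", "role")
  if (!all(need %in% names(particles))) {
    abort(sprintf("Snapshot needs columns: %s.", paste(need, collapse = ", ")))
  }
  if (any(particles$mass <= 0)) abort("Particle masses must be positive.")
  if (any(!is.finite(particles$x) | !is.finite(particles$y) |
          !is.finite(particles$z))) {
    abort("Particle coordinates must be finite.")
  }
  if (!any(particles$role == "membrane") || !any(particles$role == "probe")) {
    abort("Snapshot needs at least one membrane and one probe particle.")
  }
  if (length(box) != 3 || any(box <= 0)) {
    abort("`box` must be c(Lx, Ly, Lz) with positive lengths.")
  }
  out <- particles
  class(out) <- c("snapshot", class(out))
  attr(out, "box") <- as.numeric(box)
  out
}

#' Collective-variable definition
#'
#' @param cylinder_radius Radius (nm) of the cylinder, aligned with the
#'   membrane normal (z), used to select the lipid beads that define the
#'   local membrane center of mass.  The production value is 2.0 nm.
#' @return A list of class `cv_definition`.
#' @export
cv_definition <- function(cylinder_radius = 2.0) {
  if (cylinder_radius <= 0) abort("`cylinder_radius` must be positive.")
  structure(list(cylinder_radius = cylinder_radius, axis = "z"),
            class = "cv_definition")
}

# minimum-image displacement in one periodic dimension
min_image <- function(d, L) d - L * round(d / L)

#' Local membrane center of mass along z
#'
#' Mass-weighted mean z of the membrane particles whose xy distance from
#' the cylinder axis (minimum-image in x and y) is at most the cylinder
#' radius.  z is treated as non-periodic (it is the membrane normal).
#'
#' @param snap A [snapshot()].
#' @param axis_xy Length-2 numeric, the xy position of the cylinder axis (nm).
#' @param cv A [cv_definition()].
#' @return Local membrane center-of-mass z (nm).
#' @export
local_membrane_com_z <- function(snap, axis_xy, cv = cv_definition()) {
  stopifnot(inherits(snap, "snapshot"), inherits(cv, "cv_definition"))
  box <- attr(snap, "box")
  mem <- snap[snap$role == "membrane", ]
  dx <- min_image(mem$x - axis_xy[1], box[1])
  dy <- min_image(mem$y - axis_xy[2], box[2])
  inside <- sqrt(dx^2 + dy^2) <= cv$cylinder_radius + 1e-12
  if (!any(inside)) {
    abort("No membrane particles inside the cylinder: pathological geometry.")
  }
  sum(mem$z[inside] * mem$mass[inside]) / sum(mem$mass[inside])
}

#' Oriented probe--membrane distance (the collective variable)
#'
#' The oriented distance between the probe group's center of mass and the
#' local membrane center of mass on the z axis.  The cylinder selecting
#' the local membrane beads is centered on the probe group's xy center of
#' mass.  Positive values place the probe above the local membrane center.
#'
#' @inheritParams local_membrane_com_z
#' @return The collective variable xi (nm).
#' @export
oriented_distance <- function(snap, cv = cv_definition()) {
  stopifnot(inherits(snap, "snapshot"))
  probe <- snap[snap$role == "probe", ]
  w <- probe$mass / sum(probe$mass)
  axis_xy <- c(sum(probe$x * w), sum(probe$y * w))
  z_probe <- sum(probe$z * w)
  z_probe - local_membrane_com_z(snap, axis_xy, cv)
}

#' Read a snapshot from a minimal whitespace table
#'
#' Expects a first non-comment line `box Lx Ly Lz` followed by rows
#' `id role mass x y z`.  Lines starting with `#` or `@` are ignored.
#'
#' @param path File path.
#' @return A [snapshot()].
#' @export
read_snapshot <- function(path) {
  lines <- read_data_lines(path)
  if (!grepl("^box\\s", lines[1])) {
    abort("Snapshot file must start with a 'box Lx Ly Lz' line.")
  }
  box <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]][-1])
  df <- parse_table(lines[-1], c("id", "role", "mass", "x", "y", "z"),
                    numeric_cols = c("mass", "x", "y", "z"), path = path)
  snapshot(df[, c("x", "y", "z", "mass", "role")], box = box)
}
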