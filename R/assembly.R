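#' Tag a free-energy profile as a translocation subprocess
#'
#' Full translocation profiles are assembled from separately converged
#' subprocess calculations: adsorption (surface to solvent) and insertion
#' (surface across the membrane center), for each terminus and each
#' leaflet.  Each subprocess profile lives on its own oriented
#' coordinate, with positive values toward the solvent on the leaflet it
#' operates from.
#'
#' @param profile A [fep] profile on the subprocess's own coordinate.
#' @param terminus `"N"` or `"C"` -- which peptide terminus the collective
#'   variable tracks.
#' @param side `"upper"` or `"lower"` -- the leaflet the subprocess
#'   operates from.
#' @param process `"adsorption"` or `"insertion"`.
#' @return The profile with class `subprocess_profile` and role attributes.
#' @export
subprocess_profile <- function(profile, terminus = c("N", "C"),
                               side = c("upper", "lower"),
                               process = c("adsorption", "insertion")) {
  stopifnot(is_fep(profile))
  out <- profile
  attr(out, "terminus") <- match.arg(terminus)
  attr(out, "side") <- match.arg(side)
  attr(out, "process") <- match.arg(process)
  class(out) <- unique(c("subprocess_profile", class(out)))
  out
}

#' Least-squares constant offset between two overlapping profiles
#'
#' Only free-energy differences are physical, so independently converged
#' segments differ by arbitrary constants.  The offset minimizing the
#' mean squared difference between `a` and `b + offset` over the overlap
#' is the mean of (a - b) there, evaluated on `a`'s grid points inside
#' the overlap with `b` interpolated onto them.
#'
#' @param a,b [fep] profiles covering `overlap`.
#' @param overlap Interval (nm) over which to match.
#' @return One-row tibble: `offset` (kJ/mol, add to `b`), `rms` residual
#'   (kJ/mol) and `n` grid points used.
#' @export
align_segments <- function(a, b, overlap) {
  stopifnot(is_fep(a), is_fep(b))
  overlap <- check_interval(overlap, "overlap")
  zs <- a$z[a$z >= overlap[1] - 1e-12 & a$z <= overlap[2] + 1e-12]
  if (length(zs) < 3) {
    abort("Insufficient overlap: need >= 3 common grid points.")
  }
  Ga <- a$G[match(zs, a$z)]
  Gb <- fep_interp(b, zs)$G
  if (anyNA(Gb)) abort("Profile `b` does not cover the requested overlap.")
  offset <- mean(Ga - Gb)
  tibble(offset = offset,
         rms = sqrt(mean((Ga - Gb - offset)^2)),
         n = length(zs))
}

#' Join subprocess profiles into a full directional translocation path
#'
#' Maps the four segments of one directional path -- adsorption and
#' insertion from the entry leaflet (for the inserting terminus), and the
#' mirrored insertion and adsorption of the opposite terminus on the exit
#' leaflet -- onto a single path coordinate, removes the per-segment
#' gauge constants by least-squares alignment over the declared overlap
#' intervals, and anchors the entry solvent plateau at zero.
#'
#' The path coordinate runs from the entry-side solvent (positive) down
#' through the membrane center (0) to the exit-side solvent (negative);
#' exit-side segments are reversed and sign-flipped before alignment.
#'
#' @param subs List of [subprocess_profile()] objects containing the four
#'   segments of the requested path.
#' @param terminus Terminus that inserts first (`"N"` or `"C"`).
#' @param entry_side Leaflet the peptide enters from (`"upper"` or
#'   `"lower"`).
#' @param overlaps Optional list of 3 intervals (entry junction, central
#'   junction, exit junction) on the path coordinate; by default the
#'   central 0.3 nm of each pairwise range intersection.
#' @param solvent_width Width (nm) of the entry-solvent referencing
#'   region at the outer end of the path.
#' @return An object of class `translocation_assembly`: the joined [fep]
#'   (`$profile`), per-segment `$offsets`, schematic `$states`
#'   annotations (1, 2a, 3a, 4a) and the junction mismatch diagnostic.
#' @export
join_translocation <- function(subs, terminus = c("N", "C"),
                               entry_side = c("upper", "lower"),
                               overlaps = NULL, solvent_width = 0.5) {
  terminus <- match.arg(terminus)
  entry_side <- match.arg(entry_side)
  other_t <- if (terminus == "N") "C" else "N"
  other_s <- if (entry_side == "upper") "lower" else "upper"

  pick <- function(process, side, term) {
    hit <- purrr::keep(subs, function(s) {
      attr(s, "process") == process && attr(s, "side") == side &&
        attr(s, "terminus") == term
    })
    if (length(hit) == 0) {
      abort(sprintf("Missing segment: %s(%s, %s-terminus).",
                    process, side, term))
    }
    hit[[1]]
  }
  flip <- function(p) {
    # exit-side segment: reverse and sign-flip onto the path coordinate
    fep(rev(-p$z), rev(p$G), err = if ("err" %in% names(p)) rev(p$err),
        reference = attr(p, "reference"))
  }
  segs <- list(
    ads_entry = pick("adsorption", entry_side, terminus),
    ins_entry = pick("insertion", entry_side, terminus),
    ins_exit = flip(pick("insertion", other_s, other_t)),
    ads_exit = flip(pick("adsorption", other_s, other_t))
  )
  for (s in segs) {
    if (any(diff(s$z) <= 0)) abort("Segment grids must be strictly increasing.")
  }

  default_overlap <- function(a, b) {
    lo <- max(min(a$z), min(b$z))
    hi <- min(max(a$z), max(b$z))
    if (hi - lo <= 0) abort("Adjacent segments do not overlap.")
    mid <- (lo + hi) / 2
    half <- min(0.15, (hi - lo) / 2)
    c(mid - half, mid + half)
  }
  overlaps <- overlaps %||% list(
    default_overlap(segs$ads_entry, segs$ins_entry),
    default_overlap(segs$ins_entry, segs$ins_exit),
    default_overlap(segs$ins_exit, segs$ads_exit)
  )

  # zero-reference the entry adsorption segment at the entry solvent,
  # then chain offsets down the path
  top <- max(segs$ads_entry$z)
  segs$ads_entry <- zero_reference(segs$ads_entry, c(top - solvent_width, top))
  offs <- c(ads_entry = attr(segs$ads_entry, "shift_applied"))
  chain <- c("ins_entry", "ins_exit", "ads_exit")
  mismatch <- 0
  for (i in seq_along(chain)) {
    prev <- segs[[c("ads_entry", chain)[i]]]
    cur <- segs[[chain[i]]]
    al <- align_segments(prev, cur, overlaps[[i]])
    cur$G <- cur$G + al$offset
    segs[[chain[i]]] <- cur
    offs[chain[i]] <- al$offset
    mismatch <- max(mismatch, al$rms)
  }

  grid <- sort(unique(unlist(purrr::map(segs, "z"))))
  vals <- vapply(segs, function(s) fep_interp(s, grid)$G, numeric(length(grid)))
  G <- rowMeans(vals, na.rm = TRUE)
  err <- NULL
  if (all(vapply(segs, function(s) "err" %in% names(s), logical(1)))) {
    errs <- vapply(segs, function(s) fep_interp(s, grid)$err,
                   numeric(length(grid)))
    err <- apply(errs, 1, function(e) {
      e <- e[!is.na(e)]
      sqrt(sum(e^2)) / length(e)
    })
  }
  prof <- fep(grid, G, err = err,
              reference = sprintf("entry (%s) solvent plateau = 0", entry_side),
              kT = attr(segs$ads_entry, "kT"))

  entry_half <- prof[prof$z > 0.5, ]
  z_2a <- entry_half$z[which.min(entry_half$G)]
  states <- tibble(
    state = c("1", "2a", "3a", "4a"),
    x = c(max(grid), z_2a, z_2a / 2, 0),
    G = approx(prof$z, prof$G, xout = c(max(grid), z_2a, z_2a / 2, 0))$y
  )

  structure(list(profile = prof,
                 offsets = tibble(segment = names(offs), offset = unname(offs)),
                 states = states,
                 terminus = terminus, entry_side = entry_side,
                 junction_mismatch = mismatch),
            class = "translocation_assembly")
}

#' @export
print.translocation_assembly <- function(x, ...) {
  cat(sprintf("<translocation_assembly> %s-terminus first, entering the %s leaflet\n",
              x$terminus, x$entry_side))
  cat(sprintf("  %d points on [%.2f, %.2f]; junction mismatch %.2g kJ/mol\n",
              nrow(x$profile), min(x$profile$z), max(x$profile$z),
              x$junction_mismatch))
  invisible(x)
}

#' Compare two profiles over a region
#'
#' Both profiles are independently zero-referenced over `ref_region`
#' (constants are gauge, so only shape differences are meaningful), then
#' deviations are measured over `region` on the first profile's grid.
#' Used e.g. for hysteresis checks between forward- and backward-
#' generated umbrella runs.
#'
#' @param p,q [fep] profiles.
#' @param region Interval (nm) over which to measure deviations.
#' @param ref_region Interval used for zero-referencing both inputs;
#'   defaults to `region`.
#' @return One-row tibble: `max_abs_dev` and `rmsd` (kJ/mol), and `n`.
#' @export
compare_profiles <- function(p, q, region, ref_region = region) {
  stopifnot(is_fep(p), is_fep(q))
  region <- check_interval(region)
  p <- zero_reference(p, ref_region)
  q <- zero_reference(q, ref_region)
  zs <- p$z[p$z >= region[1] - 1e-12 & p$z <= region[2] + 1e-12]
  if (length(zs) == 0) abort("Comparison region contains no grid points.")
  d <- p$G[match(zs, p$z)] - fep_interp(q, zs)$G
  d <- d[!is.na(d)]
  if (length(d) == 0) abort("Profiles do not overlap in the region.")
  tibble(max_abs_dev = max(abs(d)), rmsd = sqrt(mean(d^2)), n = length(d))
}

#' Classify mimicking and intermediate regions of an asymmetric profile
#'
#' An asymmetric-membrane translocation profile divides into three
#' regions: a span near the upper leaflet where it is indistinguishable
#' (within `threshold`) from the pure upper-leaflet membrane profile, the
#' analogous span near the lower leaflet, and an intermediate region that
#' matches neither.  Mimicking intervals are the maximal contiguous runs
#' inward from each solvent end with |G_asym - G_pure| <= threshold.
#'
#' @param asym Asymmetric-membrane [fep] profile.
#' @param pure_upper,pure_lower Pure-membrane profiles, oriented so the
#'   compared leaflet faces the matching side, each referenced to its own
#'   solvent plateau consistently with `asym`.
#' @param threshold Agreement threshold (kJ/mol); default 5, the working
#'   error level of the production free-energy profiles.
#' @return A tibble of class `region_decomposition` with columns
#'   `region` (`mimic_lower`, `intermediate`, `mimic_upper`), `z_lo`,
#'   `z_hi` and `width`; `threshold` is stored as an attribute.
#' @export
classify_regions <- function(asym, pure_upper, pure_lower, threshold = 5) {
  stopifnot(is_fep(asym), is_fep(pure_upper), is_fep(pure_lower))
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("`threshold` must be positive.")
  }
  z <- asym$z
  d_up <- abs(asym$G - fep_interp(pure_upper, z)$G)
  d_lo <- abs(asym$G - fep_interp(pure_lower, z)$G)

  n <- length(z)
  ok_up <- !is.na(d_up) & d_up <= threshold
  ok_lo <- !is.na(d_lo) & d_lo <= threshold
  # run inward from the upper (+z) end / lower (-z) end
  i_up <- n
  while (i_up >= 1 && ok_up[i_up]) i_up <- i_up - 1
  i_up <- i_up + 1              # first index of the upper mimicking run
  i_lo <- 1
  while (i_lo <= n && ok_lo[i_lo]) i_lo <- i_lo + 1
  i_lo <- i_lo - 1              # last index of the lower mimicking run

  z_up_start <- if (i_up <= n) z[i_up] else z[n]
  z_lo_end <- if (i_lo >= 1) z[i_lo] else z[1]
  if (z_lo_end > z_up_start) {  # runs overlap: no intermediate region
    mid <- (z_lo_end + z_up_start) / 2
    z_lo_end <- mid
    z_up_start <- mid
  }
  out <- tibble(
    region = c("mimic_lower", "intermediate", "mimic_upper"),
    z_lo = c(z[1], z_lo_end, z_up_start),
    z_hi = c(z_lo_end, z_up_start, z[n])
  )
  out$width <- out$z_hi - out$z_lo
  class(out) <- c("region_decomposition", class(out))
  attr(out, "threshold") <- threshold
  out
}
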