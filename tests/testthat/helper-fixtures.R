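# Shared fixtures: small analytic landscapes, window schemes and a
# quadrature Boltzmann oracle used to check the sampler and WHAM.

kT310 <- kT_at(310)

double_well_landscape <- function() {
  pmf_landscape(well_depth = 40, center_G = 150)
}

# production-style window tiers: 0.1 nm spacing at the surface, 0.05 nm
# at the center; force constants 1000 / 3000 / 5000 kJ/mol/nm2
tier_scheme <- function(support = c(-4.5, 4.5)) {
  window_scheme(support,
                center_band = c(-0.8, 0.8),
                surface_band = list(c(support[1], -1.6), c(1.6, support[2])),
                spacing_surface = 0.1, spacing_center = 0.05,
                k_tiers = c(surface = 1000, intermediate = 3000,
                            center = 5000))
}

# custom landscape wrapper for arbitrary analytic G (sampler tests)
raw_landscape <- function(f, df, support = c(-4.5, 4.5), label = "raw") {
  structure(list(label = label, params = NULL, support = support,
                 evaluate = f, deriv = df),
            class = "pmf_landscape")
}

# normalized Boltzmann density of a biased potential by direct quadrature
boltzmann_density <- function(landscape, z0, k, kT, dz = 1e-3) {
  z <- seq(landscape$support[1], landscape$support[2], by = dz)
  U <- landscape$evaluate(z) + umbrella_bias(z, z0, k)
  w <- exp(-(U - min(U)) / kT)
  Z <- sum(diff(z) * (head(w, -1) + tail(w, -1)) / 2)
  list(z = z, dens = w / Z)
}

# cut a segment [lo, hi] out of a continuous path profile, optionally
# mapping it to the segment's own frame (exit side: xi = -path coord)
cut_path_segment <- function(truth, lo, hi, flip = FALSE, offset = 0) {
  sel <- truth$z >= lo - 1e-12 & truth$z <= hi + 1e-12
  z <- truth$z[sel]
  G <- truth$G[sel] + offset
  if (flip) fep(rev(-z), rev(G)) else fep(z, G)
}

# the four subprocess segments of one directional path, cut from a
# continuous ground-truth profile with arbitrary gauge offsets
path_segments <- function(truth, terminus = "N", entry_side = "upper",
                          offsets = c(0, 0, 0, 0)) {
  other_t <- if (terminus == "N") "C" else "N"
  other_s <- if (entry_side == "upper") "lower" else "upper"
  list(
    subprocess_profile(cut_path_segment(truth, 1.5, max(truth$z),
                                        offset = offsets[1]),
                       terminus, entry_side, "adsorption"),
    subprocess_profile(cut_path_segment(truth, -0.9, 2.1,
                                        offset = offsets[2]),
                       terminus, entry_side, "insertion"),
    subprocess_profile(cut_path_segment(truth, -2.1, 0.9, flip = TRUE,
                                        offset = offsets[3]),
                       other_t, other_s, "insertion"),
    subprocess_profile(cut_path_segment(truth, min(truth$z), -1.5,
                                        flip = TRUE, offset = offsets[4]),
                       other_t, other_s, "adsorption")
  )
}
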