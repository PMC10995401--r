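#' Membrane composition specification
#'
#' Per-leaflet lipid counts, e.g. the charge-asymmetric bilayer with 144
#' POPE lipids in the upper leaflet and 135 POPG lipids in the lower
#' leaflet, or a number-asymmetric POPC bilayer (144 vs 106 lipids).
#'
#' @param upper,lower Named integer vectors of lipid counts per leaflet,
#'   e.g. `c(POPE = 144)`.
#' @return A list of class `membrane_spec`.
#' @examples
#' membrane_spec(upper = c(POPE = 144), lower = c(POPG = 135))
#' @export
membrane_spec <- function(upper, lower) {
  check_leaflet <- function(x, side) {
    if (length(x) == 0 || is.null(names(x)) || any(!nzchar(names(x)))) {
      abort(sprintf("`%s` leaflet needs named lipid counts.", side))
    }
    if (any(x != round(x)) || any(x <= 0)) {
      abort(sprintf("`%s` leaflet counts must be positive integers.", side))
    }
    as.integer(round(x)) |> setNames(names(x))
  }
  structure(list(upper = check_leaflet(upper, "upper"),
                 lower = check_leaflet(lower, "lower")),
            class = "membrane_spec")
}

#' Lipid-number asymmetry of a membrane
#'
#' Computes the total lipid count and the number asymmetry
#' 100 |N_up - N_low| / (N_up + N_low), the convention under which a
#' bilayer with 144 lipids in one leaflet and 106 in the other has 15%
#' asymmetry.
#'
#' @param spec A [membrane_spec()].
#' @return One-row tibble with `n_upper`, `n_lower`, `total_lipids`,
#'   `asymmetry_percent` (unrounded) and `asymmetry_percent_rounded`.
#' @examples
#' membrane_asymmetry(membrane_spec(c(POPC = 144), c(POPC = 106)))
#' @export
membrane_asymmetry <- function(spec) {
  stopifnot(inherits(spec, "membrane_spec"))
  n_up <- sum(spec$upper)
  n_low <- sum(spec$lower)
  asym <- 100 * abs(n_up - n_low) / (n_up + n_low)
  tibble(n_upper = n_up, n_lower = n_low,
         total_lipids = n_up + n_low,
         asymmetry_percent = asym,
         asymmetry_percent_rounded = round(asym))
}

#' Peptide specification
#'
#' @param sequence One-letter amino-acid sequence (20 standard residues).
#' @param n_term `"charged"` (free amine, +1) or `"neutral"`.
#' @param c_term `"amidated"` (neutral) or `"free"` (carboxylate, -1).
#' @return A list of class `peptide_spec`.
#' @examples
#' peptide_spec("LKKLLKLLKKLLKLLKKLLKL")   # the LK peptide, net charge +10
#' @export
peptide_spec <- function(sequence, n_term = c("charged", "neutral"),
                         c_term = c("amidated", "free")) {
  n_term <- match.arg(n_term)
  c_term <- match.arg(c_term)
  sequence <- toupper(gsub("\\s", "", sequence))
  if (!nzchar(sequence)) abort("Peptide sequence must be non-empty.")
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  if (length(bad)) {
    abort(sprintf("Unknown residue letter(s): %s",
                  paste(unique(bad), collapse = ", ")))
  }
  structure(list(sequence = sequence, n_term = n_term, c_term = c_term),
            class = "peptide_spec")
}

#' Net charge of a peptide at neutral pH
#'
#' Counts +1 per Lys/Arg, -1 per Asp/Glu, +1 for a charged N-terminus and
#' -1 for a free (non-amidated) C-terminus.  Histidine is treated as
#' neutral.
#'
#' @param spec A [peptide_spec()].
#' @return Integer net charge in elementary charges.
#' @examples
#' peptide_net_charge(peptide_spec("LKKLLKLLKKLLKLLKKLLKL"))  # +10
#' @export
peptide_net_charge <- function(spec) {
  stopifnot(inherits(spec, "peptide_spec"))
  aa <- strsplit(spec$sequence, "")[[1]]
  q <- sum(aa %in% c("K", "R")) - sum(aa %in% c("D", "E"))
  q <- q + (spec$n_term == "charged") - (spec$c_term == "free")
  as.integer(q)
}
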