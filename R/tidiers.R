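#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a WHAM fit into its free-energy profile
#'
#' @param x A `wham_fit`.
#' @param ... Unused.
#' @return The profile tibble (`z`, `G`, optionally `err`).
#' @export
tidy.wham_fit <- function(x, ...) as_tibble(x$profile)

#' One-row summary of a WHAM fit
#'
#' @param x A `wham_fit`.
#' @param ... Unused.
#' @return Tibble with iteration count, final residual, solver settings
#'   and problem size.
#' @export
glance.wham_fit <- function(x, ...) {
  tibble(n_windows = nrow(x$f),
         n_bins = nrow(x$profile),
         iterations = x$iterations,
         residual = x$residual,
         kT = x$settings$kT,
         tol = x$settings$tol,
         bin_width = x$settings$bin_width)
}

#' Tidy a translocation assembly into its joined profile
#'
#' @param x A `translocation_assembly`.
#' @param ... Unused.
#' @return The joined path profile as a tibble.
#' @export
tidy.translocation_assembly <- function(x, ...) as_tibble(x$profile)

#' One-row summary of a translocation assembly
#'
#' @param x A `translocation_assembly`.
#' @param ... Unused.
#' @return Tibble with terminus, entry side, segment count, junction
#'   mismatch and path extent.
#' @export
glance.translocation_assembly <- function(x, ...) {
  tibble(terminus = x$terminus,
         entry_side = x$entry_side,
         n_segments = nrow(x$offsets),
         junction_mismatch = x$junction_mismatch,
         path_min = min(x$profile$z),
         path_max = max(x$profile$z))
}
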