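#' WHAM solver controls
#'
#' @param kT Thermal energy (kJ/mol).
#' @param tol Convergence tolerance: maximum change of any window
#'   free-energy constant per iteration (kJ/mol).
#' @param max_iter Iteration cap.
#' @param bin_width Histogram bin width (nm).  The default 0.02 nm is at
#'   most half the finest production window spacing (0.05 nm).
#' @param n_bootstrap Number of bootstrap replicates for [bootstrap_error()].
#' @return A list of class `wham_settings`.
#' @export
wham_settings <- function(kT = kT_at(310), tol = 1e-6, max_iter = 100000L,
                          bin_width = 0.02, n_bootstrap = 20L) {
  if (tol <= 0 || bin_width <= 0) abort("`tol` and `bin_width` must be > 0.")
  structure(list(kT = kT, tol = tol, max_iter = as.integer(max_iter),
                 bin_width = bin_width, n_bootstrap = as.integer(n_bootstrap)),
            class = "wham_settings")
}

#' Histogram umbrella-window timeseries on a shared grid
#'
#' Discards the leading `n_equil` equilibration samples of each window
#' (the umbrella-sampling analogue of dropping the initial stretch of
#' each trajectory), then bins the production samples into half-open bins
#' `[lo, hi)` on a grid covering the union of sampled ranges.
#'
#' @param ts_list List of `window_timeseries` (see [sample_window()]).
#' @param settings A [wham_settings()].
#' @return A list of class `histogram_set`: `bin_edges`, `mids`, `counts`
#'   (windows x bins integer matrix) and `n_samples`.
#' @export
histogram_windows <- function(ts_list, settings = wham_settings()) {
  bw <- settings$bin_width
  prod <- purrr::imap(ts_list, function(ts, i) {
    ne <- attr(ts, "n_equil") %||% 0L
    if (length(ts$z) <= ne) {
      lab <- attr(ts, "window")$label %||% as.character(i)
      abort(sprintf("Window %s is empty after discarding %d equilibration samples.",
                    lab, ne))
    }
    if (ne > 0) ts$z[-seq_len(ne)] else ts$z
  })
  zr <- range(unlist(prod))
  lo <- floor(zr[1] / bw) * bw
  n_bins <- ceiling((zr[2] - lo) / bw + 1e-9)
  if (lo + n_bins * bw <= zr[2]) n_bins <- n_bins + 1  # max sample stays inside
  edges <- lo + bw * (0:n_bins)
  counts <- do.call(rbind, lapply(prod, function(z) {
    tabulate(findInterval(z, edges, left.open = FALSE), nbins = n_bins)
  }))
  structure(list(bin_edges = edges,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts,
                 n_samples = vapply(prod, length, integer(1))),
            class = "histogram_set")
}

#' Pairwise window-overlap matrix
#'
#' Overlap between two windows is the sum over bins of the minimum of
#' their normalized histograms: 1 for identical sampling, 0 for disjoint
#' sampling.  Adequate window spacing shows as a banded matrix with
#' sizeable first off-diagonal entries.
#'
#' @param h A `histogram_set`.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
overlap_matrix <- function(h) {
  stopifnot(inherits(h, "histogram_set"))
  p <- h$counts / rowSums(h$counts)
  n <- nrow(p)
  out <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <- sum(pmin(p[i, ], p[j, ]))
    }
  }
  out
}

# window bias energies at bin centers: rows windows, cols bins
bias_matrix <- function(windows, mids) {
  U <- outer(seq_len(nrow(windows)), seq_along(mids), function(i, j) {
    umbrella_bias(mids[j], windows$z0[i], windows$k[i])
  })
  if ("u_offset" %in% names(windows)) U <- U + windows$u_offset
  U
}

# connected components of the window-overlap graph (shared nonzero bin)
overlap_components <- function(counts) {
  n <- nrow(counts)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (j in seq_len(ncol(counts))) {
    idx <- which(counts[, j] > 0)
    if (length(idx) > 1) {
      r <- find(idx[1])
      for (i in idx[-1]) comp[find(i)] <- r
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Solve the WHAM equations for a free-energy profile
#'
#' Self-consistent iteration of the coupled weighted-histogram equations
#' for the unbiased bin probabilities p_j and per-window free-energy
#' constants f_i:
#'
#'   p_j = M_j / sum_i N_i exp((f_i - U_i(z_j)) / kT)
#'   f_i = -kT log sum_j p_j exp(-U_i(z_j) / kT)
#'
#' iterated until the largest change in any f_i drops below `tol`.  The
#' returned profile is G(z) = -kT log p(z), shifted so that the mean over
#' the reference region (the solvent plateau) is zero.  Bins never
#' sampled by any window are dropped from the profile.
#'
#' @param h A `histogram_set` from [histogram_windows()].
#' @param windows Data frame with one row per histogram row: `z0`, `k`
#'   (and optionally `u_offset`, a constant added to that window's bias).
#' @param settings A [wham_settings()].
#' @param reference_region Interval (nm) where G is anchored to zero;
#'   default: the outermost 0.5 nm at the upper end of the sampled range.
#' @param f_init Optional warm-start window constants.
#' @return An object of class `wham_fit`: the [fep] profile plus window
#'   constants, iteration count and final residual.  Use [tidy()] and
#'   [glance()] to extract them.
#' @export
solve_wham <- function(h, windows, settings = wham_settings(),
                       reference_region = NULL, f_init = NULL) {
  stopifnot(inherits(h, "histogram_set"))
  windows <- as_tibble(windows)
  if (nrow(windows) != nrow(h$counts)) {
    abort("`windows` must have one row per histogram row.")
  }
  comp <- overlap_components(h$counts)
  if (length(unique(comp)) > 1) {
    groups <- split(seq_along(comp), comp)
    abort(paste0("Window overlap graph is disconnected; components: ",
                 paste(vapply(groups, function(g)
                   paste0("{", paste(g, collapse = ","), "}"), character(1)),
                   collapse = " ")))
  }

  kT <- settings$kT
  M <- colSums(h$counts)
  N <- h$n_samples
  U <- bias_matrix(windows, h$mids)
  # per-window shift keeps exp() in range; shifts cancel in the update
  Umin <- apply(U, 1, min)
  D <- exp(-(U - Umin) / kT)

  f <- f_init %||% numeric(nrow(windows))
  iter <- 0L
  resid <- Inf
  repeat {
    iter <- iter + 1L
    v <- N * exp(f / kT)
    denom <- as.numeric(crossprod(D, v))      # sum_i v_i D_ij
    p <- ifelse(denom > 0, M / denom, 0)
    f_new <- -kT * log(as.numeric(D %*% p))
    f_new <- f_new - f_new[1]                 # fix the gauge
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < settings$tol || iter >= settings$max_iter) break
  }
  if (resid >= settings$tol) {
    abort(sprintf("WHAM did not converge in %d iterations (residual %.3g kJ/mol).",
                  iter, resid))
  }

  sampled <- M > 0
  z <- h$mids[sampled]
  G <- -kT * log(p[sampled] / sum(p[sampled]))
  prof <- fep(z, G, reference = "unreferenced", kT = kT)
  reference_region <- reference_region %||% c(max(z) - 0.5, max(z))
  prof <- zero_reference(prof, reference_region)

  structure(list(profile = prof,
                 f = tibble(z0 = windows$z0, k = windows$k, f = f),
                 iterations = iter, residual = resid,
                 settings = settings, reference_region = reference_region,
                 hist = h, windows = windows),
            class = "wham_fit")
}

#' @export
print.wham_fit <- function(x, ...) {
  cat(sprintf("<wham_fit> %d windows, %d sampled bins, %d iterations (residual %.2g kJ/mol)\n",
              nrow(x$f), nrow(x$profile), x$iterations, x$residual))
  cat(sprintf("  reference: %s\n", attr(x$profile, "reference")))
  invisible(x)
}

# integrated autocorrelation time (steps), for block-length selection
integrated_act <- function(z, max_lag = min(length(z) - 1, 1000)) {
  a <- acf(z, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1]
  a[!is.finite(a)] <- 0     # constant series: no correlation structure
  pos <- which(a <= 0)[1]
  if (!is.na(pos)) a <- a[seq_len(pos - 1)]
  1 + 2 * sum(a)
}

#' Bootstrap error band for a WHAM profile
#'
#' Moving-block bootstrap within each window (block length set from the
#' integrated autocorrelation time of that window's chain, capped at a
#' tenth of its length), re-solving WHAM on each resample and taking the
#' pointwise standard deviation over replicates after re-anchoring each
#' replicate to the reference region.
#'
#' @inheritParams solve_wham
#' @param ts_list List of `window_timeseries`.
#' @param windows Window table matching `ts_list` (`z0`, `k`).
#' @param seed Integer seed for the resampling.
#' @return A `wham_fit` whose profile carries an `err` column.
#' @export
bootstrap_error <- function(ts_list, windows, settings = wham_settings(),
                            seed, reference_region = NULL) {
  if (missing(seed)) abort("`seed` must be given explicitly.")
  if (settings$n_bootstrap < 2) abort("Need n_bootstrap >= 2.")
  base_h <- histogram_windows(ts_list, settings)
  base <- solve_wham(base_h, windows, settings, reference_region)
  edges <- base_h$bin_edges
  n_bins <- length(base_h$mids)

  prod <- purrr::map(ts_list, function(ts) {
    ne <- attr(ts, "n_equil") %||% 0L
    if (ne > 0) ts$z[-seq_len(ne)] else ts$z
  })
  block_len <- vapply(prod, function(z) {
    max(1L, min(as.integer(ceiling(2 * integrated_act(z))),
                as.integer(length(z) / 10)))
  }, integer(1))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  n_rep <- settings$n_bootstrap
  reps <- vector("list", n_rep)
  failed <- 0L
  for (r in seq_len(n_rep)) {
    counts <- do.call(rbind, lapply(seq_along(prod), function(i) {
      z <- block_resample(prod[[i]], block_len[i])
      tabulate(findInterval(z, edges, left.open = FALSE), nbins = n_bins)
    }))
    h_r <- structure(list(bin_edges = edges, mids = base_h$mids,
                          counts = counts,
                          n_samples = rowSums(counts)),
                     class = "histogram_set")
    fit_r <- tryCatch(
      solve_wham(h_r, windows, settings, base$reference_region,
                 f_init = base$f$f),
      error = function(e) NULL)
    if (is.null(fit_r)) failed <- failed + 1L else reps[[r]] <- fit_r
  }
  if (failed > 0.2 * n_rep) {
    abort(sprintf("%d of %d bootstrap replicates failed to converge.",
                  failed, n_rep))
  }
  reps <- purrr::compact(reps)

  # align replicate profiles on the base grid (bins are shared)
  Gmat <- vapply(reps, function(fit) {
    if (nrow(fit$profile) < 2) {
      ifelse(base$profile$z %in% fit$profile$z, fit$profile$G, NA_real_)
    } else {
      approx(fit$profile$z, fit$profile$G, xout = base$profile$z, rule = 1)$y
    }
  }, numeric(nrow(base$profile)))
  Gmat <- matrix(Gmat, nrow = nrow(base$profile))
  err <- apply(Gmat, 1, sd, na.rm = TRUE)
  base$profile$err <- err
  base$n_bootstrap_used <- length(reps)
  base
}

block_resample <- function(z, block_len) {
  n <- length(z)
  if (block_len >= n) return(z[sample.int(n, n, replace = TRUE)])
  n_blocks <- ceiling(n / block_len)
  starts <- sample.int(n - block_len + 1, n_blocks, replace = TRUE)
  idx <- as.vector(outer(0:(block_len - 1), starts, `+`))
  z[idx[seq_len(n)]]
}
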