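# Independent reference WHAM: instead of the package's self-consistent
# iteration, minimize the WHAM negative log-likelihood
#
#   A(g) = -sum_i N_i g_i + sum_j M_j log sum_i N_i exp(g_i - u_ij)
#
# over the reduced window constants g_i = f_i / kT (g_1 fixed at 0) with
# BFGS and an analytic gradient, then read off the bin probabilities
# p_j = M_j / sum_i N_i exp(g_i - u_ij).  Same input histograms, a
# different algorithm and code path.
reference_wham <- function(h, windows, kT) {
  M <- colSums(h$counts)
  N <- h$n_samples
  U <- outer(seq_len(nrow(windows)), seq_along(h$mids), function(i, j) {
    umbrella_bias(h$mids[j], windows$z0[i], windows$k[i])
  })
  if ("u_offset" %in% names(windows)) U <- U + windows$u_offset
  u <- U / kT
  lognu <- log(N)
  W <- nrow(u)
  keep <- M > 0

  col_lse <- function(A) {
    m <- apply(A, 2, max)
    m + log(colSums(exp(sweep(A, 2, m))))
  }
  objfun <- function(g_free) {
    g <- c(0, g_free)
    lse <- col_lse(g + lognu - u)
    -sum(N * g) + sum(M[keep] * lse[keep])
  }
  gradfun <- function(g_free) {
    g <- c(0, g_free)
    A <- g + lognu - u
    m <- apply(A, 2, max)
    E <- exp(sweep(A, 2, m))
    S <- colSums(E)
    # d/dg_k = -N_k + sum_j M_j * E_kj / S_j
    gr <- -N + as.numeric(E[, keep, drop = FALSE] %*%
                            (M[keep] / S[keep]))
    gr[-1]
  }
  opt <- stats::optim(numeric(W - 1), objfun, gradfun, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  g <- c(0, opt$par)
  A <- g + lognu - u
  m <- apply(A, 2, max)
  S <- colSums(exp(sweep(A, 2, m))) * exp(m)
  p <- ifelse(M > 0, M / S, 0)
  z <- h$mids[keep]
  G <- -kT * log(p[keep] / sum(p[keep]))
  list(z = z, G = G, converged = opt$convergence == 0)
}

# max |dG| between two profiles on the same grid, after removing the
# arbitrary constant (gauge) by matching means
max_gauge_dev <- function(z1, G1, z2, G2) {
  stopifnot(isTRUE(all.equal(z1, z2)))
  d <- G1 - G2
  max(abs(d - mean(d)))
}
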