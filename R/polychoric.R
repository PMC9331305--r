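# Bivariate standard-normal CDF P(Z1 <= h, Z2 <= k | rho), vectorized over
# h and k (scalar rho). One-dimensional reduction
#   Phi2(h,k,rho) = int_{-inf}^{h} phi(z) Phi((k - rho z)/sqrt(1-rho^2)) dz
# evaluated by fixed Gauss-Legendre quadrature on [-8.5, h]; absolute error
# well below 1e-9, which is ample for likelihood work on count tables.
.pbvnorm <- function(h, k, rho, n_nodes = 64L) {
  L <- max(length(h), length(k))
  h <- rep_len(pmin(pmax(h, -8.5), 8.5), L)
  k <- rep_len(pmin(pmax(k, -8.5), 8.5), L)
  if (abs(rho) < 1e-12) return(stats::pnorm(h) * stats::pnorm(k))
  if (rho > 0.99999) return(stats::pnorm(pmin(h, k)))
  if (rho < -0.99999) return(pmax(stats::pnorm(h) + stats::pnorm(k) - 1, 0))
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  s <- sqrt(1 - rho^2)
  half <- (h + 8.5) / 2
  # z: L x n_nodes node matrix, row i spans [-8.5, h_i]
  z <- outer(half, gl$x + 1) - 8.5
  f <- stats::dnorm(z) * stats::pnorm((k - rho * z) / s)
  as.vector((f %*% gl$w) * half)
}

#' Polychoric correlation matrix
#'
#' Two-step maximum-likelihood polychorics: item thresholds are estimated
#' from each item's marginal category proportions as normal quantiles, then
#' each pairwise correlation maximizes the bivariate-normal likelihood of
#' the observed (pairwise-complete) contingency table with the thresholds
#' held fixed. Empty cells receive a 0.5 continuity correction. If the
#' resulting matrix is not positive semidefinite it is smoothed by
#' eigenvalue clipping (and the smoothing is reported).
#'
#' @param responses a [response_matrix()] (reverse-scored internally).
#' @return list of class `"polychoric"`: `rho` (correlation matrix),
#'   `thresholds` (per-item normal quantiles), `smoothed` (logical),
#'   `n_pairs` (pairwise-complete counts).
#' @export
polychoric_corr <- function(responses) {
  X <- observed(ensure_reversed(responses))
  m <- n_categories(responses)
  k <- ncol(X)
  labs <- colnames(X)
  thresholds <- vector("list", k)
  for (i in seq_len(k)) {
    x <- X[, i]
    obs <- x[!is.na(x)]
    if (length(unique(obs)) < 2L)
      stop("item ", labs[i], " has fewer than 2 observed categories")
    p <- tabulate(obs + 1L, nbins = m[i]) / length(obs)
    thresholds[[i]] <- stats::qnorm(pmin(pmax(cumsum(p)[seq_len(m[i] - 1L)],
                                              1e-6), 1 - 1e-6))
  }
  rho <- diag(1, k)
  dimnames(rho) <- list(labs, labs)
  npairs <- matrix(nrow(X), k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- !is.na(X[, i]) & !is.na(X[, j])
      npairs[i, j] <- npairs[j, i] <- sum(ok)
      tab <- table(factor(X[ok, i], levels = 0:(m[i] - 1L)),
                   factor(X[ok, j], levels = 0:(m[j] - 1L)))
      r <- .polychoric_pair(tab, thresholds[[i]], thresholds[[j]])
      rho[i, j] <- rho[j, i] <- r
    }
  }
  sm <- .psd_smooth(rho)
  structure(list(rho = sm$mat, thresholds = thresholds,
                 smoothed = sm$smoothed, n_pairs = npairs),
            class = "polychoric")
}

.polychoric_pair <- function(tab, tau_r, tau_c) {
  tab <- as.matrix(tab)
  if (any(tab == 0)) tab <- tab + 0.5  # continuity correction
  tr <- c(-Inf, tau_r, Inf)
  tc <- c(-Inf, tau_c, Inf)
  nr <- length(tr); nc <- length(tc)
  hh <- rep(tr, times = nc); kk <- rep(tc, each = nr)
  nll <- function(rho) {
    cdf <- matrix(.pbvnorm(hh, kk, rho), nr, nc)
    p <- cdf[-1L, -1L] - cdf[-nr, -1L] - cdf[-1L, -nc] + cdf[-nr, -nc]
    -sum(tab * log(pmax(p, 1e-12)))
  }
  stats::optimize(nll, c(-0.999, 0.999))$minimum
}

# nearest-PSD smoothing by eigenvalue clipping, unit diagonal restored
.psd_smooth <- function(R, tol = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= -tol) return(list(mat = R, smoothed = FALSE))
  v <- pmax(e$values, tol)
  M <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  dimnames(M) <- dimnames(R)
  list(mat = M, smoothed = TRUE)
}

#' @export
print.polychoric <- function(x, ...) {
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf("<polychoric: %d items, rho in [%.2f, %.2f]%s>\n",
              ncol(x$rho), min(off), max(off),
              if (x$smoothed) ", PSD-smoothed" else ""))
  invisible(x)
}
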