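#' Calibrate an item bank by marginal maximum likelihood (EM)
#'
#' Fits the generalized partial credit model (GPCM) or the partial credit
#' model (PCM, common discrimination) to a polytomous response matrix by
#' marginal maximum likelihood, integrating the latent trait over a fixed
#' quadrature grid with a standard-normal prior (which also identifies the
#' latent metric — no post-hoc rescaling). The E-step forms each person's
#' posterior over the grid; the M-step maximizes the expected complete-data
#' log-likelihood per item by quasi-Newton updates in slope/intercept
#' parameterization (converted to slope/threshold `a`, `b_k` on output).
#' The marginal log-likelihood is non-decreasing across cycles.
#'
#' Missing and not-applicable responses are ignored by the likelihood.
#' Items calibrated with `a < 0.50` are flagged as low-discrimination (they
#' are reported, never auto-removed; dropping them is the caller's call —
#' content relevance can outweigh low information).
#'
#' @param responses a [response_matrix()] (screened and, if applicable,
#'   recoded); every item must show every category `0..m-1` at least once.
#' @param model `"GPCM"` or `"PCM"`.
#' @param grid a [quadrature_grid()].
#' @param tol convergence tolerance: largest absolute change in any `a` or
#'   `b` parameter (default 1e-4).
#' @param max_iter maximum EM cycles (default 500); hitting it returns the
#'   result with `converged = FALSE` rather than failing.
#' @param low_disc_cut discrimination flag threshold (default 0.50).
#' @return list of class `"calibration"`: `bank` ([item_bank()]),
#'   `model`, `log_likelihood`, `n_parameters`, `aic`, `bic`, `infit`,
#'   `low_discrimination` (labels), `converged`, `trace` (log-likelihood
#'   per cycle), `n_persons`, `grid`.
#' @export
calibrate <- function(responses, model = c("GPCM", "PCM"),
                      grid = quadrature_grid(), tol = 1e-4,
                      max_iter = 500L, low_disc_cut = 0.50) {
  model <- match.arg(model)
  rm <- ensure_reversed(responses)
  X <- observed(rm)
  m <- n_categories(rm)
  labs <- colnames(X)
  k <- ncol(X)
  n <- nrow(X)
  for (i in seq_len(k)) {
    obs <- X[!is.na(X[, i]), i]
    if (length(obs) == 0L) stop("item ", labs[i], " has no observed responses")
    cnt <- tabulate(obs + 1L, nbins = m[i])
    if (any(cnt == 0L))
      stop("item ", labs[i], ": category ", which(cnt == 0L)[1L] - 1L,
           " has no observations; collapse categories before calibrating")
  }

  nodes <- grid$nodes
  logw <- log(grid$weights)
  Q <- length(nodes)

  # starting values: a = 1, thresholds from marginal cumulative proportions
  a <- rep(1, k)
  b <- lapply(seq_len(k), function(i) {
    obs <- X[!is.na(X[, i]), i]
    p <- cumsum(tabulate(obs + 1L, nbins = m[i]) / length(obs))
    sort(stats::qnorm(pmin(pmax(p[seq_len(m[i] - 1L)], 0.02), 0.98)))
  })

  obs_idx <- lapply(seq_len(k), function(i) which(!is.na(X[, i])))
  trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    lp <- lapply(seq_len(k), function(i) gpcm_logprob(nodes, a[i], b[[i]]))
    ll <- matrix(0, n, Q)
    for (i in seq_len(k)) {
      oi <- obs_idx[[i]]
      ll[oi, ] <- ll[oi, ] + t(lp[[i]])[X[oi, i] + 1L, , drop = FALSE]
    }
    lw <- sweep(ll, 2L, logw, `+`)
    mx <- .row_max(lw)
    post <- exp(lw - mx)
    rs <- rowSums(post)
    trace <- c(trace, sum(mx + log(rs)))
    post <- post / rs

    # expected counts R[[i]]: Q x m_i
    Rcnt <- lapply(seq_len(k), function(i) {
      oi <- obs_idx[[i]]
      t(rowsum(post[oi, , drop = FALSE],
               group = factor(X[oi, i], levels = 0:(m[i] - 1L))))
    })

    a_new <- a
    b_new <- b
    if (model == "GPCM") {
      for (i in seq_len(k)) {
        upd <- .mstep_item(Rcnt[[i]], nodes, a[i], b[[i]], free_a = TRUE)
        a_new[i] <- upd$a
        b_new[[i]] <- upd$b
      }
    } else {
      for (i in seq_len(k)) {
        upd <- .mstep_item(Rcnt[[i]], nodes, a[1L], b[[i]], free_a = FALSE)
        b_new[[i]] <- upd$b
      }
      a_common <- .mstep_common_a(Rcnt, nodes, a[1L], b_new)
      a_new <- rep(a_common, k)
    }
    delta <- max(abs(a_new - a),
                 max(vapply(seq_len(k),
                            function(i) max(abs(b_new[[i]] - b[[i]])), 0)))
    a <- a_new
    b <- b_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter,
            " cycles (last parameter change ", signif(delta, 3), ")")

  # final log-likelihood at the accepted parameters
  lp <- lapply(seq_len(k), function(i) gpcm_logprob(nodes, a[i], b[[i]]))
  ll <- matrix(0, n, Q)
  for (i in seq_len(k)) {
    oi <- obs_idx[[i]]
    ll[oi, ] <- ll[oi, ] + t(lp[[i]])[X[oi, i] + 1L, , drop = FALSE]
  }
  lw <- sweep(ll, 2L, logw, `+`)
  mx <- .row_max(lw)
  logL <- sum(mx + log(rowSums(exp(lw - mx))))
  trace <- c(trace, logL)

  npar <- if (model == "GPCM") sum(m) else 1L + sum(m - 1L)
  bank <- item_bank(a, b, labels = labs, polarity = attr(rm, "polarity"))
  fit <- structure(list(bank = bank, model = model, log_likelihood = logL,
                        n_parameters = npar,
                        aic = -2 * logL + 2 * npar,
                        bic = -2 * logL + npar * log(n),
                        low_discrimination = labs[a < low_disc_cut],
                        converged = converged, trace = trace,
                        n_persons = n, grid = grid),
                   class = "calibration")
  fit$infit <- infit(fit, rm)
  fit
}

# maximize the expected complete-data log-likelihood for one item.
# Rcnt: Q x m expected counts; parameters (log a, d_1..d_{m-1}) with
# d_x = -a * cumsum(b)_x; quasi-Newton with analytic gradient.
.mstep_item <- function(Rcnt, nodes, a0, b0, free_a = TRUE) {
  m <- ncol(Rcnt)
  x <- 0:(m - 1L)
  Nq <- rowSums(Rcnt)
  Sx <- as.vector(Rcnt %*% x)
  d0 <- -a0 * cumsum(b0)
  eloglik <- function(a, d) {
    eta <- outer(nodes, x) * a + rep(c(0, d), each = length(nodes))
    mxr <- .row_max(eta)
    logZ <- mxr + log(rowSums(exp(eta - mxr)))
    sum(Rcnt * eta) - sum(Nq * logZ)
  }
  probs <- function(a, d) {
    eta <- outer(nodes, x) * a + rep(c(0, d), each = length(nodes))
    mxr <- .row_max(eta)
    p <- exp(eta - mxr)
    p / rowSums(p)
  }
  if (free_a) {
    par0 <- c(log(a0), d0)
    fn <- function(par) -eloglik(exp(par[1L]), par[-1L])
    gr <- function(par) {
      a <- exp(par[1L]); d <- par[-1L]
      P <- probs(a, d)
      Ex <- as.vector(P %*% x)
      g_loga <- a * sum(nodes * (Sx - Nq * Ex))
      g_d <- colSums(Rcnt - Nq * P)[-1L]
      -c(g_loga, g_d)
    }
  } else {
    par0 <- d0
    fn <- function(par) -eloglik(a0, par)
    gr <- function(par) {
      P <- probs(a0, par)
      -colSums(Rcnt - Nq * P)[-1L]
    }
  }
  opt <- stats::optim(par0, fn, gr, method = "BFGS",
                      control = list(maxit = 50, reltol = 1e-10))
  if (free_a) {
    a <- exp(opt$par[1L]); d <- opt$par[-1L]
  } else {
    a <- a0; d <- opt$par
  }
  b <- (c(0, d[-length(d)]) - d) / a
  list(a = a, b = b)
}

# PCM: one-dimensional maximization of the common discrimination given the
# current intercepts (d implied by b at the current common a is refit here
# in threshold form, which is invariant to a)
.mstep_common_a <- function(Rcnt, nodes, a0, b) {
  total <- function(a) {
    s <- 0
    for (i in seq_along(Rcnt)) {
      m <- ncol(Rcnt[[i]])
      x <- 0:(m - 1L)
      eta <- outer(nodes, x) * a - rep(a * c(0, cumsum(b[[i]])),
                                       each = length(nodes))
      mxr <- .row_max(eta)
      logZ <- mxr + log(rowSums(exp(eta - mxr)))
      s <- s + sum(Rcnt[[i]] * eta) - sum(rowSums(Rcnt[[i]]) * logZ)
    }
    -s
  }
  stats::optimize(total, c(a0 / 3, a0 * 3))$minimum
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration: %s, %d items, n = %d, logL = %.2f, AIC = %.2f, BIC = %.2f%s>\n",
              x$model, length(x$bank$a), x$n_persons, x$log_likelihood,
              x$aic, x$bic, if (x$converged) "" else ", NOT CONVERGED"))
  if (length(x$low_discrimination))
    cat("  low discrimination (a < 0.50):",
        paste(x$low_discrimination, collapse = ", "), "\n")
  invisible(x)
}

#' Likelihood-ratio comparison of nested calibrations
#'
#' Compares a GPCM fit with its nested PCM fit on the same data:
#' `X2 = 2 (logL_GPCM - logL_PCM)` on `df` = difference in parameter
#' counts, with AIC/BIC deltas. The preferred model is the one with the
#' lower AIC, corroborated by the LRT at `alpha`.
#'
#' @param fit_full,fit_restricted [calibrate()] results on identical
#'   responses (the restricted model must be nested in the full one).
#' @param alpha LRT level used for the "preferred" call (default 0.001,
#'   the conventional reporting gate for this comparison).
#' @return list: `statistic`, `df`, `p_value`, `delta_aic` (full −
#'   restricted), `delta_bic`, `preferred`.
#' @export
compare_models <- function(fit_full, fit_restricted, alpha = 0.001) {
  if (!identical(fit_full$bank$labels, fit_restricted$bank$labels) ||
      fit_full$n_persons != fit_restricted$n_persons)
    stop("fits are not nested: different items or sample")
  stat <- 2 * (fit_full$log_likelihood - fit_restricted$log_likelihood)
  df <- fit_full$n_parameters - fit_restricted$n_parameters
  p <- if (df <= 0 || stat <= 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  d_aic <- fit_full$aic - fit_restricted$aic
  d_bic <- fit_full$bic - fit_restricted$bic
  preferred <- if (d_aic < 0 && p < alpha) fit_full$model else fit_restricted$model
  list(statistic = stat, df = df, p_value = p,
       delta_aic = d_aic, delta_bic = d_bic, preferred = preferred)
}

#' Infit mean-square item fit statistics
#'
#' Information-weighted mean square
#' `Infit_i = sum_p (x_pi - E_pi)^2 / sum_p W_pi` over observed responses,
#' where `E` and `W` are the model mean and variance at each person's EAP
#' trait estimate. Values near 1 indicate fit; the conventional acceptable
#' range is 0.7–1.3. An item with no observed responses gets `NA`.
#'
#' @param fit a [calibrate()] result.
#' @param responses the [response_matrix()] the fit was computed on.
#' @param scores optional [eap_score()] data frame (recomputed if missing).
#' @return named numeric vector, one infit per item.
#' @export
infit <- function(fit, responses, scores = NULL) {
  rm <- ensure_reversed(responses)
  X <- observed(rm)
  bank <- fit$bank
  if (is.null(scores)) scores <- eap_score(rm, bank, fit$grid)
  theta <- scores$theta
  out <- stats::setNames(numeric(length(bank$a)), bank$labels)
  for (i in seq_along(bank$a)) {
    oi <- which(!is.na(X[, i]))
    if (!length(oi)) { out[i] <- NA_real_; next }
    p <- category_probs(theta[oi], bank$a[i], bank$b[[i]])
    x <- 0:(bank$m[i] - 1L)
    E <- as.vector(p %*% x)
    W <- as.vector(p %*% x^2) - E^2
    out[i] <- sum((X[oi, i] - E)^2) / sum(W)
  }
  out
}
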