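#' Eigenvalues, first-factor share and parallel analysis
#'
#' Sorted eigenvalues of a correlation matrix, the first-to-second
#' eigenvalue ratio and the percentage of variance carried by the first
#' factor, together with parallel-analysis reference eigenvalues: the
#' stated percentile of eigenvalues of correlation matrices from random
#' standard-normal data of the same dimensions. The number of factors
#' "suggested" is the count of observed eigenvalues exceeding their
#' reference.
#'
#' @param pc a [polychoric_corr()] result or a plain correlation matrix.
#' @param n_persons sample size behind the correlations.
#' @param reps random replicates (>= 100; default 500).
#' @param percentile reference percentile (default 95).
#' @param seed integer seed for the random-data eigenvalues.
#' @return list: `eigenvalues` (descending), `ratio_1_2`,
#'   `explained_variance_first` (%), `pa_thresholds`, `n_factors_pa`,
#'   `n_factors_kaiser`.
#' @export
eigen_and_parallel <- function(pc, n_persons, reps = 500L, percentile = 95,
                               seed = 1L) {
  R <- if (inherits(pc, "polychoric")) pc$rho else as.matrix(pc)
  if (reps < 100L) stop("'reps' must be >= 100")
  k <- ncol(R)
  ev <- sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sims <- matrix(0, reps, k)
  for (r in seq_len(reps)) {
    Z <- matrix(stats::rnorm(n_persons * k), n_persons, k)
    sims[r, ] <- sort(eigen(stats::cor(Z), symmetric = TRUE,
                            only.values = TRUE)$values, decreasing = TRUE)
  }
  pa <- apply(sims, 2L, stats::quantile, probs = percentile / 100)
  list(eigenvalues = ev,
       ratio_1_2 = ev[1L] / ev[2L],
       explained_variance_first = 100 * ev[1L] / k,
       pa_thresholds = pa,
       n_factors_pa = sum(ev > pa),
       n_factors_kaiser = sum(ev > 1))
}

# Unweighted-least-squares fit of Sigma = L L' + Psi structures: minimizes
# the sum of squared off-diagonal residuals over the free loadings.
# 'pattern' is a k x f logical matrix of free entries.
.uls_fit <- function(R, pattern, start, restarts = 3L) {
  k <- nrow(pattern)
  free <- which(pattern)
  obj <- function(par) {
    L <- matrix(0, k, ncol(pattern)); L[free] <- par
    Res <- R - tcrossprod(L)
    diag(Res) <- 0
    sum(Res^2) / 2
  }
  grad <- function(par) {
    L <- matrix(0, k, ncol(pattern)); L[free] <- par
    Res <- R - tcrossprod(L)
    diag(Res) <- 0
    G <- -2 * Res %*% L
    G[free]
  }
  best <- NULL
  par0 <- start[free]
  for (r in seq_len(restarts)) {
    fit <- try(stats::optim(par0, obj, grad, method = "BFGS",
                            control = list(maxit = 2000, reltol = 1e-12)),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      # accept a maxit return whose gradient is already negligible (flat
      # directions are common when group factors carry little variance)
      if (fit$convergence != 0 && sqrt(sum(grad(fit$par)^2)) < 1e-6)
        fit$convergence <- 0
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (!is.null(best) && best$convergence == 0) break
    par0 <- start[free] * stats::runif(length(free), 0.5, 1.5)
  }
  if (is.null(best)) stop("ULS factor fit failed to converge after restarts")
  L <- matrix(0, k, ncol(pattern)); L[free] <- best$par
  # sign convention: dominant direction positive per factor
  for (f in seq_len(ncol(L))) if (sum(L[, f]) < 0) L[, f] <- -L[, f]
  list(loadings = L, value = best$value, converged = best$convergence == 0)
}

#' One-factor fit with ULS discrepancy-based fit indices
#'
#' Fits a single common factor to a (polychoric) correlation matrix by
#' unweighted least squares and reports approximate fit indices: a chi-square
#' formed from the ULS discrepancy with the usual `n - 1` scaling, RMSEA
#' with a noncentrality-based confidence interval, CFI/TLI against the
#' independence baseline, and the residual correlation matrix for the
#' local-independence check (residuals above `resid_flag` are flagged).
#' These indices are estimator-dependent: they are comparable across models
#' fit by this function, not numerically interchangeable with indices from
#' other estimators.
#'
#' A Heywood loading (|loading| >= 1) is clamped to 0.999 with a warning.
#'
#' @param pc a [polychoric_corr()] result or correlation matrix.
#' @param n_persons sample size.
#' @param resid_flag local-independence flag threshold (default 0.25).
#' @param ci_level RMSEA confidence level (default 0.95).
#' @return list: `loadings`, `chi_square`, `df`, `rmsea`, `rmsea_ci`,
#'   `cfi`, `tli`, `residuals`, `flagged_pairs`, `heywood`.
#' @export
fit_one_factor <- function(pc, n_persons, resid_flag = 0.25, ci_level = 0.95) {
  R <- if (inherits(pc, "polychoric")) pc$rho else as.matrix(pc)
  k <- ncol(R)
  if (k < 4L) stop("one-factor fit needs >= 4 items")
  ev <- eigen(R, symmetric = TRUE)
  start <- matrix(ev$vectors[, 1L] * sqrt(max(ev$values[1L], 0.1)), k, 1L)
  fit <- .uls_fit(R, matrix(TRUE, k, 1L), start)
  lam <- fit$loadings[, 1L]
  heywood <- abs(lam) >= 1
  if (any(heywood)) {
    warning("Heywood case: ", sum(heywood), " loading(s) clamped to 0.999")
    lam[heywood] <- sign(lam[heywood]) * 0.999
  }
  Res <- R - tcrossprod(lam)
  diag(Res) <- 0
  Fmin <- sum(Res^2) / 2
  df <- k * (k - 1) / 2 - k
  chi2 <- (n_persons - 1) * Fmin
  # baseline: zero correlations
  Fb <- sum(R[upper.tri(R)]^2)
  dfb <- k * (k - 1) / 2
  chib <- (n_persons - 1) * Fb
  rmsea <- sqrt(max(chi2 - df, 0) / (df * (n_persons - 1)))
  rmsea_ci <- .rmsea_ci(chi2, df, n_persons, ci_level)
  cfi <- 1 - max(chi2 - df, 0) / max(chib - dfb, chi2 - df, .Machine$double.eps)
  tli <- if (chib / dfb - 1 > 0) (chib / dfb - chi2 / df) / (chib / dfb - 1) else 1
  tli <- min(tli, 1)
  flg <- which(abs(Res) > resid_flag & upper.tri(Res), arr.ind = TRUE)
  flagged <- if (nrow(flg)) data.frame(item1 = colnames(R)[flg[, 1L]],
                                       item2 = colnames(R)[flg[, 2L]],
                                       residual = Res[flg])
             else data.frame(item1 = character(), item2 = character(),
                             residual = numeric())
  list(loadings = stats::setNames(lam, colnames(R)), chi_square = chi2,
       df = df, rmsea = rmsea, rmsea_ci = rmsea_ci, cfi = max(min(cfi, 1), 0),
       tli = tli, residuals = Res, flagged_pairs = flagged,
       heywood = any(heywood))
}

# noncentrality-inversion CI for RMSEA
.rmsea_ci <- function(chi2, df, n, level = 0.95) {
  a <- (1 - level) / 2
  up <- function(p) {
    if (stats::pchisq(chi2, df) < p) return(0)
    stats::uniroot(function(nc) stats::pchisq(chi2, df, ncp = nc) - p,
                   c(0, max(chi2 * 10, 100)), extendInt = "downX")$root
  }
  lo_nc <- up(1 - a)
  hi_nc <- up(a)
  c(lower = sqrt(lo_nc / (df * (n - 1))), upper = sqrt(hi_nc / (df * (n - 1))))
}

#' Default bifactor group assignment
#'
#' Assigns each item to one of `n_groups` group factors by its largest
#' absolute loading in an obliquely rotated (promax) principal-axis
#' exploratory solution of the correlation matrix.
#'
#' @param pc a [polychoric_corr()] result or correlation matrix.
#' @param n_groups number of group factors (default 3).
#' @return integer vector of group indices named by item.
#' @export
assign_groups <- function(pc, n_groups = 3L) {
  R <- if (inherits(pc, "polychoric")) pc$rho else as.matrix(pc)
  k <- ncol(R)
  # principal-axis: iterate communalities a few times
  h2 <- 1 - 1 / diag(solve(R))
  for (it in 1:25) {
    Rh <- R; diag(Rh) <- h2
    e <- eigen(Rh, symmetric = TRUE)
    L <- e$vectors[, seq_len(n_groups), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(n_groups)], 0)), n_groups)
    h2_new <- pmin(rowSums(L^2), 0.998)
    if (max(abs(h2_new - h2)) < 1e-6) break
    h2 <- h2_new
  }
  Lr <- tryCatch(stats::promax(L)$loadings, error = function(e) L)
  g <- apply(abs(unclass(Lr)), 1L, which.max)
  stats::setNames(as.integer(g), colnames(R))
}

#' Confirmatory bifactor model with omega-hierarchical and ECV
#'
#' Fits an orthogonal bifactor structure by unweighted least squares: a
#' general factor loading every item plus one group factor per cluster
#' loading only its items. From the loadings it computes hierarchical
#' omega for the general factor, per-group omega-hierarchical (within each
#' item cluster), and the explained common variance (ECV) split between
#' the general and group factors. Items whose general loading is at or
#' below `load_cut` are reported as exclusion candidates.
#'
#' @param pc a [polychoric_corr()] result or correlation matrix.
#' @param n_persons sample size (carried through for reporting).
#' @param groups item-to-group assignment (integer vector); defaults to
#'   [assign_groups()] with 3 groups.
#' @param load_cut general-loading exclusion threshold (default 0.40).
#' @return list: `loadings` (items x (1 + G)), `omega_h_general`,
#'   `omega_total`, `omega_h_group`, `ecv_general` (%), `ecv_group` (%),
#'   `low_general_items`, `converged`.
#' @export
bifactor <- function(pc, n_persons, groups = NULL, load_cut = 0.40) {
  R <- if (inherits(pc, "polychoric")) pc$rho else as.matrix(pc)
  k <- ncol(R)
  if (is.null(groups)) groups <- assign_groups(pc)
  groups <- as.integer(groups)
  if (length(groups) != k) stop("each item needs exactly one group")
  G <- max(groups)
  pattern <- cbind(TRUE, vapply(seq_len(G), function(g) groups == g,
                                logical(k)))
  # staged starting values: the general factor from a one-factor ULS fit,
  # each group factor from the first principal axis of its residual block
  # (a zero group loading is a saddle of the ULS surface, so starts matter)
  ev <- eigen(R, symmetric = TRUE)
  g0 <- matrix(ev$vectors[, 1L] * sqrt(max(ev$values[1L], 0.5)), k, 1L)
  gfit <- .uls_fit(R, matrix(TRUE, k, 1L), g0)
  start <- matrix(0, k, G + 1L)
  start[, 1L] <- gfit$loadings[, 1L]
  Res <- R - tcrossprod(start[, 1L])
  for (g in seq_len(G)) {
    idx <- which(groups == g)
    if (length(idx) == 1L) { start[idx, g + 1L] <- 0.3; next }
    eb <- eigen(Res[idx, idx], symmetric = TRUE)
    sg <- eb$vectors[, 1L] * sqrt(max(eb$values[1L], 0.09))
    if (sum(sg) < 0) sg <- -sg
    start[idx, g + 1L] <- sg
  }
  fit <- .uls_fit(R, pattern, start, restarts = 5L)
  if (!fit$converged) stop("bifactor ULS fit did not converge after restarts")
  L <- fit$loadings
  colnames(L) <- c("general", paste0("group", seq_len(G)))
  rownames(L) <- colnames(R)
  g <- L[, 1L]
  S <- L[, -1L, drop = FALSE]
  psi <- pmax(1 - rowSums(L^2), 0)
  tot_var <- sum(g)^2 + sum(colSums(S)^2) + sum(psi)
  omega_h <- sum(g)^2 / tot_var
  omega_t <- (sum(g)^2 + sum(colSums(S)^2)) / tot_var
  omega_h_group <- vapply(seq_len(G), function(gr) {
    idx <- groups == gr
    denom <- sum(g[idx])^2 + sum(S[idx, gr])^2 + sum(psi[idx])
    sum(S[idx, gr])^2 / denom
  }, 0)
  common <- sum(g^2) + sum(S^2)
  ecv_gen <- 100 * sum(g^2) / common
  ecv_grp <- vapply(seq_len(G), function(gr) 100 * sum(S[, gr]^2) / common, 0)
  list(loadings = L, omega_h_general = omega_h, omega_total = omega_t,
       omega_h_group = omega_h_group, ecv_general = ecv_gen,
       ecv_group = ecv_grp,
       low_general_items = colnames(R)[abs(g) <= load_cut],
       groups = groups, converged = fit$converged, n_persons = n_persons)
}

#' Monotonicity check via rest-score bins
#'
#' For each item, persons are binned by their rest score (total over the
#' other items, complete cases for the item's rest set) into `bins`
#' quantile groups; the item passes when its mean score never drops across
#' adjacent bins by more than `se_mult` pooled standard errors. Constant
#' items or items with too few complete cases are skipped with a warning.
#'
#' @param responses a [response_matrix()].
#' @param bins number of rest-score bins (default 10).
#' @param se_mult noise tolerance in pooled standard errors (default 2).
#' @return data frame: `label`, `status` (`"pass"`, `"fail"`, `"skipped"`),
#'   `worst_drop_se` (largest drop in SE units, `NA` when skipped).
#' @export
monotonicity_check <- function(responses, bins = 10L, se_mult = 2) {
  rm <- ensure_reversed(responses)
  X <- observed(rm)
  n <- nrow(X)
  if (n < 10L * bins) stop("need at least 10 persons per bin")
  out <- lapply(seq_len(ncol(X)), function(i) {
    x <- X[, i]
    rest <- rowMeans(X[, -i, drop = FALSE], na.rm = TRUE)
    ok <- !is.na(x) & is.finite(rest)
    if (sum(ok) < 3L * bins || stats::var(x[ok]) == 0) {
      warning("item ", colnames(X)[i], " skipped in monotonicity check")
      return(data.frame(label = colnames(X)[i], status = "skipped",
                        worst_drop_se = NA_real_))
    }
    br <- unique(stats::quantile(rest[ok], probs = seq(0, 1, length.out = bins + 1L)))
    bin <- cut(rest[ok], br, include.lowest = TRUE)
    mu <- tapply(x[ok], bin, mean)
    se <- tapply(x[ok], bin, function(v) stats::sd(v) / sqrt(length(v)))
    d <- diff(mu)
    pooled <- sqrt(se[-length(se)]^2 + se[-1L]^2)
    drop_se <- ifelse(d < 0, -d / pmax(pooled, 1e-9), 0)
    worst <- if (length(drop_se)) max(drop_se, na.rm = TRUE) else 0
    data.frame(label = colnames(X)[i],
               status = if (worst > se_mult) "fail" else "pass",
               worst_drop_se = worst)
  })
  do.call(rbind, out)
}

#' Collapse categories that are never modal
#'
#' After a provisional GPCM fit, any category whose probability curve is
#' never the most likely one anywhere on the trait grid is collapsed into
#' its lower neighbour (the lowest category merges upward). Returns the
#' recode map and the recoded matrix; items needing no recode map to
#' themselves.
#'
#' @param responses a [response_matrix()].
#' @param fit optional [calibrate()] result for the provisional fit;
#'   computed if missing.
#' @param grid trait grid on which modality is examined.
#' @return list: `map` (per item, named integer vector old -> new),
#'   `responses` (recoded [response_matrix()]), `n_items_recoded`.
#' @export
recode_categories <- function(responses, fit = NULL,
                              grid = quadrature_grid()) {
  rm <- ensure_reversed(responses)
  if (is.null(fit)) fit <- calibrate(rm, model = "GPCM", grid = grid)
  bank <- fit$bank
  X <- observed(rm)
  maps <- vector("list", length(bank$a))
  names(maps) <- bank$labels
  newX <- X
  new_m <- bank$m
  for (i in seq_along(bank$a)) {
    p <- category_probs(grid$nodes, bank$a[i], bank$b[[i]])
    modal <- apply(p, 1L, which.max)
    m <- bank$m[i]
    keep_modal <- seq_len(m) %in% unique(modal)
    # never-modal categories merge into their lower neighbour; a never-modal
    # lowest category merges upward into the first kept one
    map <- integer(m); nxt <- -1L
    for (c in seq_len(m)) {
      if (keep_modal[c]) nxt <- nxt + 1L
      map[c] <- max(nxt, 0L)
    }
    if (max(map) < 1L) {
      warning("item ", bank$labels[i],
              ": all but one category never modal; left unrecoded")
      map <- 0:(m - 1L)
    }
    maps[[i]] <- stats::setNames(map, 0:(m - 1L))
    newX[, i] <- map[X[, i] + 1L]
    new_m[i] <- max(map) + 1L
  }
  out <- response_matrix(newX, n_categories = new_m,
                         polarity = attr(rm, "polarity"),
                         labels = colnames(X), nap = attr(rm, "nap"))
  attr(out, "reversed") <- TRUE
  list(map = maps, responses = out,
       n_items_recoded = sum(vapply(maps, function(mp) any(mp != seq_along(mp) - 1L), TRUE)))
}
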