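#' Item bank under the generalized partial credit model
#'
#' A calibrated (or ground-truth) bank of polytomous items. Under the GPCM
#' the probability of response `x` in `0..m-1` at latent trait `theta` is
#' \deqn{P(X = x \mid \theta) = \frac{\exp \sum_{k=0}^{x} a(\theta - b_k)}
#'   {\sum_{c=0}^{m-1} \exp \sum_{k=0}^{c} a(\theta - b_k)}}
#' with the `k = 0` term defined as zero, discrimination `a > 0` and
#' category-boundary thresholds `b_1 .. b_{m-1}`. The partial credit model
#' (PCM) is the special case with a common `a` across items.
#'
#' @param a numeric vector of discriminations, one per item, all > 0.
#' @param b list of numeric threshold vectors, `m_i - 1` values per item.
#' @param labels item labels (unique); default `"DT1", "DT2", ...`.
#' @param polarity `"positive"`/`"negative"` per item (metadata only; the
#'   model always works on positively oriented codes).
#' @return an object of class `"item_bank"`.
#' @export
item_bank <- function(a, b, labels = paste0("DT", seq_along(a)),
                      polarity = rep("positive", length(a))) {
  if (!is.list(b)) b <- list(b)
  k <- length(a)
  if (length(b) != k) stop("'a' and 'b' must have one entry per item")
  if (any(a <= 0)) stop("discrimination parameters must be positive")
  if (anyDuplicated(labels)) stop("item labels must be unique")
  b <- lapply(b, as.numeric)
  structure(list(labels = as.character(labels), a = as.numeric(a), b = b,
                 m = vapply(b, length, 1L) + 1L,
                 polarity = rep_len(polarity, k)),
            class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank: %d items, a in [%.2f, %.2f], %d..%d categories>\n",
              length(x$a), min(x$a), max(x$a), min(x$m), max(x$m)))
  invisible(x)
}

#' @export
length.item_bank <- function(x) length(x$a)

#' @export
`[.item_bank` <- function(x, i) {
  item_bank(x$a[i], x$b[i], x$labels[i], x$polarity[i])
}

#' GPCM category response probabilities
#'
#' Evaluates the category probability vector at one or more trait values,
#' guarded against overflow by log-sum-exp.
#'
#' @param theta numeric vector of latent trait values.
#' @param a item discrimination (> 0).
#' @param b numeric vector of `m - 1` category-boundary thresholds.
#' @return a `length(theta) x m` matrix of probabilities; rows sum to 1.
#' @export
category_probs <- function(theta, a, b) {
  m <- length(b) + 1L
  x <- 0:(m - 1L)
  # eta_c(theta) = a * (c * theta - cumsum(b)_c), with the c = 0 term zero
  eta <- outer(theta, x) * a - rep(a * c(0, cumsum(b)), each = length(theta))
  mx <- .row_max(eta)
  p <- exp(eta - mx)
  p / rowSums(p)
}

.row_max <- function(M) M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]

# log-probability table for one item over a node vector: Q x m
gpcm_logprob <- function(nodes, a, b) {
  m <- length(b) + 1L
  eta <- outer(nodes, 0:(m - 1L)) * a -
    rep(a * c(0, cumsum(b)), each = length(nodes))
  mr <- .row_max(eta)
  eta - (mr + log(rowSums(exp(eta - mr))))
}

#' Gaussian quadrature grid for marginal likelihoods
#'
#' Equally spaced nodes with standard-normal prior weights, renormalized to
#' sum to one — the substrate for marginal maximum likelihood and EAP
#' estimation.
#'
#' @param n_nodes number of nodes (default 61).
#' @param range span of the grid on the theta axis (default `c(-4, 4)`).
#' @param prior_mean,prior_sd prior on the latent trait (default N(0,1)).
#' @return list with `nodes` and `weights` (summing to 1).
#' @export
quadrature_grid <- function(n_nodes = 61L, range = c(-4, 4),
                            prior_mean = 0, prior_sd = 1) {
  nodes <- seq(range[1L], range[2L], length.out = n_nodes)
  w <- stats::dnorm(nodes, prior_mean, prior_sd)
  list(nodes = nodes, weights = w / sum(w))
}

# person x node log-likelihood matrix for a response matrix (NA ignored)
pattern_loglik <- function(X, bank, grid) {
  n <- nrow(X)
  Q <- length(grid$nodes)
  ll <- matrix(0, n, Q)
  for (i in seq_along(bank$a)) {
    lp <- gpcm_logprob(grid$nodes, bank$a[i], bank$b[[i]])  # Q x m
    xi <- X[, i]
    obs <- which(!is.na(xi))
    if (length(obs)) ll[obs, ] <- ll[obs, ] + t(lp)[xi[obs] + 1L, , drop = FALSE]
  }
  ll
}

#' Expected-a-posteriori (EAP) trait scores
#'
#' Posterior mean and posterior SD of the latent trait under the bank and
#' the grid's normal prior. The posterior SD is the per-person standard
#' error of measurement (SEM) used throughout the CAT machinery. A person
#' with no observed responses receives the prior mean and prior SD.
#'
#' @param responses a [response_matrix()], plain integer matrix, or a
#'   single response pattern (vector) on the positive orientation; `NA`
#'   entries are ignored in the likelihood.
#' @param bank an [item_bank()].
#' @param grid a [quadrature_grid()].
#' @return data frame with columns `person_id`, `theta`, `sem`.
#' @export
eap_score <- function(responses, bank, grid = quadrature_grid()) {
  X <- if (inherits(responses, "response_matrix")) observed(ensure_reversed(responses))
       else if (is.matrix(responses)) responses
       else matrix(responses, nrow = 1L)
  if (ncol(X) != length(bank$a))
    stop("response pattern width does not match the bank")
  ll <- pattern_loglik(X, bank, grid)
  lw <- sweep(ll, 2L, log(grid$weights), `+`)
  mx <- .row_max(lw)
  post <- exp(lw - mx)
  post <- post / rowSums(post)
  theta <- as.vector(post %*% grid$nodes)
  ex2 <- as.vector(post %*% grid$nodes^2)
  sem <- sqrt(pmax(ex2 - theta^2, 0))
  data.frame(person_id = rownames(X) %||% seq_len(nrow(X)),
             theta = theta, sem = sem)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Item and test information curves
#'
#' GPCM item information from the variance identity
#' `I_i(theta) = a_i^2 * Var(X_i | theta)`; test information is the sum over
#' items. `information_fraction()` reports the share of the integrated test
#' information inside an interval, relative to the integral over `total_range`
#' (Gauss–Legendre quadrature).
#'
#' @param bank an [item_bank()].
#' @param theta numeric grid of trait values.
#' @return `information()`: list with `theta`, `item` (grid x items matrix)
#'   and `test` (vector).
#' @export
information <- function(bank, theta = seq(-4, 4, length.out = 161L)) {
  k <- length(bank$a)
  item <- matrix(0, length(theta), k, dimnames = list(NULL, bank$labels))
  for (i in seq_len(k)) {
    p <- category_probs(theta, bank$a[i], bank$b[[i]])
    x <- 0:(bank$m[i] - 1L)
    ex <- p %*% x
    vx <- p %*% x^2 - ex^2
    item[, i] <- bank$a[i]^2 * vx
  }
  list(theta = theta, item = item, test = rowSums(item))
}

#' @rdname information
#' @param interval interval whose information share is reported.
#' @param total_range support over which "total" information is integrated.
#' @param n_nodes Gauss–Legendre nodes per integral.
#' @return `information_fraction()`: scalar in `[0, 1]`.
#' @export
information_fraction <- function(bank, interval = c(-2, 2),
                                 total_range = c(-4, 4), n_nodes = 101L) {
  tinfo <- function(th) information(bank, th)$test
  gl_int <- function(lo, hi) {
    gl <- pracma::gaussLegendre(n_nodes, lo, hi)
    sum(gl$w * tinfo(gl$x))
  }
  gl_int(interval[1L], interval[2L]) / gl_int(total_range[1L], total_range[2L])
}

#' Linear 0-100 score transform
#'
#' Maps trait estimates onto an interpretable 0–100 scale (higher = better
#' experience) via `100 * (theta - lo) / (hi - lo)`, clipped to `[0, 100]`.
#' The default anchors are the EAP estimates of the all-minimum and
#' all-maximum response patterns on the bank, so that the most negative
#' possible pattern scores 0 and the most positive scores 100.
#'
#' @param theta numeric vector of trait values.
#' @param anchors length-2 numeric `c(theta_lo, theta_hi)`, `lo < hi`.
#' @return numeric vector in `[0, 100]`.
#' @export
transform_score <- function(theta, anchors) {
  if (anchors[1L] >= anchors[2L]) stop("degenerate anchors: need lo < hi")
  pmin(pmax(100 * (theta - anchors[1L]) / (anchors[2L] - anchors[1L]), 0), 100)
}

#' @rdname transform_score
#' @param bank an [item_bank()].
#' @param grid a [quadrature_grid()].
#' @export
default_anchors <- function(bank, grid = quadrature_grid()) {
  lo <- rep(0L, length(bank$a))
  hi <- bank$m - 1L
  c(eap_score(lo, bank, grid)$theta, eap_score(hi, bank, grid)$theta)
}

#' Score every person: EAP theta, SEM and 0-100 score
#'
#' @param responses a [response_matrix()].
#' @param bank an [item_bank()].
#' @param grid a [quadrature_grid()].
#' @param anchors 0-100 anchors; defaults to [default_anchors()].
#' @return data frame `person_id`, `theta`, `sem`, `score_0_100`.
#' @export
score_persons <- function(responses, bank, grid = quadrature_grid(),
                          anchors = default_anchors(bank, grid)) {
  sc <- eap_score(responses, bank, grid)
  sc$score_0_100 <- transform_score(sc$theta, anchors)
  sc
}

#' Serialize a bank to / from JSON
#'
#' One record per item: `{label, a, b: [...], m, polarity}`.
#'
#' @param bank an [item_bank()].
#' @param path file path.
#' @export
write_bank <- function(bank, path) {
  items <- lapply(seq_along(bank$a), function(i) {
    list(label = bank$labels[i], a = bank$a[i], b = bank$b[[i]],
         m = bank$m[i], polarity = bank$polarity[i])
  })
  jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bank
#' @export
read_bank <- function(path) {
  items <- jsonlite::read_json(path, simplifyVector = TRUE)
  item_bank(a = items$a, b = lapply(items$b, as.numeric),
            labels = items$label, polarity = items$polarity)
}
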