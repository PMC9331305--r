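#' Impute a complete response matrix from a calibrated bank
#'
#' Replaces every missing / not-applicable entry by a draw from the GPCM
#' category probabilities at the person's EAP trait estimate (computed from
#' that person's observed responses). A person with no observed responses
#' is imputed from the prior predictive (EAP falls back to the prior mean)
#' and flagged. Deterministic under a fixed seed.
#'
#' @param responses a [response_matrix()].
#' @param bank a calibrated [item_bank()].
#' @param grid a [quadrature_grid()].
#' @param seed optional integer seed.
#' @return list: `responses` (complete [response_matrix()]),
#'   `flagged_persons` (ids imputed from the prior alone).
#' @export
impute_complete <- function(responses, bank, grid = quadrature_grid(),
                            seed = NULL) {
  rm <- ensure_reversed(responses)
  X <- observed(rm)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  n_obs <- rowSums(!is.na(X))
  sc <- eap_score(rm, bank, grid)
  for (i in seq_len(ncol(X))) {
    mis <- which(is.na(X[, i]))
    if (!length(mis)) next
    p <- category_probs(sc$theta[mis], bank$a[i], bank$b[[i]])
    cp <- t(apply(p, 1L, cumsum))
    u <- stats::runif(length(mis))
    X[mis, i] <- as.integer(rowSums(u > cp))
  }
  out <- response_matrix(X, n_categories = n_categories(rm),
                         polarity = attr(rm, "polarity"),
                         labels = colnames(X))
  attr(out, "reversed") <- TRUE
  rownames(out) <- rownames(rm)
  list(responses = out,
       flagged_persons = rownames(X)[n_obs == 0L])
}

#' CAT stopping / selection configuration
#'
#' @param sem_stop stop once the EAP posterior SD (the per-person SEM)
#'   falls to or below this value; the conventional range 0.33–0.55 spans
#'   reliabilities 0.90–0.70 via `reliability = 1 - SEM^2`.
#' @param max_items administer at most this many items (default: whole
#'   bank).
#' @param selection item-selection rule; only maximum Fisher information
#'   (`"MFI"`) is provided.
#' @param estimator trait estimator; only `"EAP"` is provided.
#' @return list of class `"cat_config"`.
#' @export
cat_config <- function(sem_stop = 0.33, max_items = Inf,
                       selection = "MFI", estimator = "EAP") {
  if (sem_stop < 0) stop("'sem_stop' must be >= 0")
  selection <- match.arg(selection, "MFI")
  estimator <- match.arg(estimator, "EAP")
  structure(list(sem_stop = sem_stop, max_items = max_items,
                 selection = selection, estimator = estimator),
            class = "cat_config")
}

# item information at a single theta for chosen items
.item_info_at <- function(theta, bank, items) {
  vapply(items, function(i) {
    p <- category_probs(theta, bank$a[i], bank$b[[i]])
    x <- 0:(bank$m[i] - 1L)
    ex <- sum(p * x)
    bank$a[i]^2 * (sum(p * x^2) - ex^2)
  }, 0)
}

#' Run an adaptive test for one person
#'
#' Implements the CAT loop: the first item is the bank's most informative
#' item at the prior mean (theta = 0); after each response the trait and
#' its SEM are re-estimated by EAP over the administered items; the next
#' item is the unadministered item with maximum Fisher information at the
#' current estimate (ties broken by lowest item index); the test stops
#' when `SEM <= sem_stop` or the bank is exhausted. The procedure is fully
#' deterministic given the response pattern.
#'
#' @param pattern complete integer response vector over the bank
#'   (positively oriented codes `0..m-1`).
#' @param bank an [item_bank()].
#' @param config a [cat_config()].
#' @param grid a [quadrature_grid()].
#' @return list of class `"cat_result"`: `administered` (item indices in
#'   order), `theta_trajectory`, `sem_trajectory`, `final_theta`,
#'   `final_sem`, `n_items`, `stop_reason` (`"SEM_REACHED"` or
#'   `"BANK_EXHAUSTED"`).
#' @export
run_cat <- function(pattern, bank, config = cat_config(),
                    grid = quadrature_grid()) {
  k <- length(bank$a)
  if (length(pattern) != k) stop("pattern must cover the whole bank")
  if (anyNA(pattern)) stop("pattern must be complete (impute first)")
  administered <- integer(0)
  theta_traj <- numeric(0)
  sem_traj <- numeric(0)
  theta <- 0
  repeat {
    remaining <- setdiff(seq_len(k), administered)
    info <- .item_info_at(theta, bank, remaining)
    nxt <- remaining[which.max(info)]  # which.max takes the first: lowest index on ties
    administered <- c(administered, nxt)
    resp <- rep(NA_integer_, k)
    resp[administered] <- pattern[administered]
    sc <- eap_score(resp, bank, grid)
    theta <- sc$theta
    sem <- sc$sem
    theta_traj <- c(theta_traj, theta)
    sem_traj <- c(sem_traj, sem)
    if (sem <= config$sem_stop) {
      reason <- "SEM_REACHED"; break
    }
    if (length(administered) >= min(k, config$max_items)) {
      reason <- "BANK_EXHAUSTED"; break
    }
  }
  structure(list(administered = administered, theta_trajectory = theta_traj,
                 sem_trajectory = sem_traj, final_theta = theta,
                 final_sem = sem, n_items = length(administered),
                 stop_reason = reason),
            class = "cat_result")
}

#' CAT simulation study over a cohort
#'
#' Replays [run_cat()] for every person at each SEM stopping level and
#' summarizes accuracy and burden against the full-bank EAP estimate:
#' Pearson `r` between CAT and full-bank trait estimates, their RMSE, the
#' mean number of items administered, and the median (IQR) of the final
#' 0–100 scores. The conventional adequacy expectations are `r >= 0.90`
#' and `RMSE <= 0.30`.
#'
#' @param responses complete [response_matrix()] (see [impute_complete()]).
#' @param bank an [item_bank()].
#' @param sem_levels SEM stopping thresholds (default `c(0.33, 0.44,
#'   0.55)`).
#' @param grid a [quadrature_grid()].
#' @param anchors 0–100 anchors; defaults to [default_anchors()].
#' @return list of class `"cat_study"`: `metrics` (data frame per level:
#'   `sem_stop`, `r`, `rmse`, `mean_items`, `median_score`, `iqr_lo`,
#'   `iqr_hi`, `pct_bank_exhausted`), `full_theta`, `cat_theta` (matrix
#'   persons x levels).
#' @export
simulate_cat_study <- function(responses, bank,
                               sem_levels = c(0.33, 0.44, 0.55),
                               grid = quadrature_grid(),
                               anchors = default_anchors(bank, grid)) {
  rm <- ensure_reversed(responses)
  X <- observed(rm)
  if (anyNA(X)) stop("responses must be complete; run impute_complete() first")
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 persons")
  full <- eap_score(rm, bank, grid)$theta
  cat_theta <- matrix(NA_real_, n, length(sem_levels))
  metrics <- vector("list", length(sem_levels))
  for (j in seq_along(sem_levels)) {
    cfg <- cat_config(sem_stop = sem_levels[j])
    nit <- numeric(n)
    exhausted <- 0L
    for (p in seq_len(n)) {
      res <- run_cat(X[p, ], bank, cfg, grid)
      cat_theta[p, j] <- res$final_theta
      nit[p] <- res$n_items
      if (res$stop_reason == "BANK_EXHAUSTED") exhausted <- exhausted + 1L
    }
    sc <- transform_score(cat_theta[, j], anchors)
    qs <- stats::quantile(sc, c(0.25, 0.5, 0.75))
    metrics[[j]] <- data.frame(
      sem_stop = sem_levels[j],
      r = stats::cor(cat_theta[, j], full),
      rmse = sqrt(mean((cat_theta[, j] - full)^2)),
      mean_items = mean(nit),
      median_score = qs[2L], iqr_lo = qs[1L], iqr_hi = qs[3L],
      pct_bank_exhausted = 100 * exhausted / n)
  }
  structure(list(metrics = do.call(rbind, metrics), full_theta = full,
                 cat_theta = cat_theta, sem_levels = sem_levels),
            class = "cat_study")
}

#' @export
print.cat_study <- function(x, ...) {
  cat("<cat_study>\n")
  print(format(x$metrics, digits = 3), row.names = FALSE)
  invisible(x)
}
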