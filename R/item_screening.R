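#' Descriptive item statistics
#'
#' Per-item mean, SD, floor/ceiling percentages, missingness, sample-moment
#' skewness and the largest single-category share. Reverse-worded items are
#' reverse-scored first so that every statistic refers to the "higher =
#' better experience" orientation. Floor/ceiling and category shares are
#' computed over observed responses (missing and not-applicable excluded);
#' `missing_pct` counts both kinds of non-response over all persons.
#'
#' An item with no observed responses is flagged (`n_obs = 0`) and its
#' descriptives are set to `NA`, never silently dropped; a constant item
#' gets `sd = 0` and `NA` skewness.
#'
#' @param responses a [response_matrix()].
#' @return data frame with one row per item: `label`, `n_obs`, `mean`,
#'   `sd`, `floor_pct`, `ceiling_pct`, `missing_pct`, `skewness`,
#'   `max_category_pct`.
#' @export
describe_items <- function(responses) {
  rm <- ensure_reversed(responses)
  X <- observed(rm)
  m <- n_categories(rm)
  n <- nrow(X)
  out <- lapply(seq_len(ncol(X)), function(i) {
    x <- X[, i]
    obs <- x[!is.na(x)]
    miss <- 100 * (n - length(obs)) / n
    if (length(obs) == 0L)
      return(data.frame(label = colnames(X)[i], n_obs = 0L, mean = NA_real_,
                        sd = NA_real_, floor_pct = NA_real_,
                        ceiling_pct = NA_real_, missing_pct = miss,
                        skewness = NA_real_, max_category_pct = NA_real_))
    tab <- tabulate(obs + 1L, nbins = m[i])
    mu <- mean(obs)
    s <- stats::sd(obs)
    # sample-moment (biased) skewness: m3 / m2^(3/2)
    skw <- if (length(obs) > 2L && s > 0) {
      m2 <- mean((obs - mu)^2)
      mean((obs - mu)^3) / m2^1.5
    } else NA_real_
    data.frame(label = colnames(X)[i], n_obs = length(obs), mean = mu,
               sd = if (length(obs) > 1L) s else 0,
               floor_pct = 100 * tab[1L] / length(obs),
               ceiling_pct = 100 * tab[m[i]] / length(obs),
               missing_pct = miss, skewness = skw,
               max_category_pct = 100 * max(tab) / length(obs))
  })
  do.call(rbind, out)
}

#' Inter-item Pearson correlations on observed ordinal codes
#'
#' Pairwise-complete Pearson correlations of the reverse-scored response
#' codes — the classical-test-theory screening substrate (the polychoric
#' machinery comes later in the pipeline).
#'
#' @param responses a [response_matrix()].
#' @return symmetric correlation matrix.
#' @export
interitem_corr <- function(responses) {
  X <- observed(ensure_reversed(responses))
  suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
}

#' Screen items by missingness, skewness and inter-item correlation
#'
#' Applies the three published exclusion rules: (1) missing-value rate above
#' `missing_cut` (default 70%); (2) extreme skewness — more than
#' `onecat_cut` (default 95%) of observed responses in a single category or
#' |skewness| above `skew_cut` (default 4); (3) inter-item Pearson
#' correlation above `corr_cut` (default 0.70). For rule (3) the member of
#' each offending pair with the higher missing rate is dropped (ties go to
#' the higher item index), and the rule iterates until no remaining pair
#' exceeds the cut — a deterministic tie-break so screening is reproducible.
#'
#' @param responses a [response_matrix()].
#' @param missing_cut,onecat_cut percentages; `skew_cut`, `corr_cut` reals.
#' @return list of class `"screening_report"`: `excluded` (data frame
#'   `label`, `reason`), `retained` (labels), `descriptives`,
#'   `interitem_corr`, `alpha` (Cronbach's alpha over retained items).
#' @export
screen_items <- function(responses, missing_cut = 70, onecat_cut = 95,
                         skew_cut = 4, corr_cut = 0.70) {
  stopifnot(missing_cut > 0, onecat_cut > 0, skew_cut > 0, corr_cut > 0)
  des <- describe_items(responses)
  labs <- des$label
  excl <- data.frame(label = character(), reason = character())
  add_excl <- function(lab, reason)
    rbind(excl, data.frame(label = lab, reason = reason))

  r1 <- labs[des$missing_pct > missing_cut]
  if (length(r1)) excl <- add_excl(r1, "MISSING_GT_THRESHOLD")
  r2 <- labs[(!is.na(des$max_category_pct) & des$max_category_pct > onecat_cut) |
               (!is.na(des$skewness) & abs(des$skewness) > skew_cut)]
  r2 <- setdiff(r2, excl$label)
  if (length(r2)) excl <- add_excl(r2, "EXTREME_SKEW")

  rmat <- interitem_corr(responses)
  keep <- setdiff(labs, excl$label)
  repeat {
    sub <- rmat[keep, keep, drop = FALSE]
    diag(sub) <- 0
    hi <- which(abs(sub) > corr_cut & !is.na(sub), arr.ind = TRUE)
    if (nrow(hi) == 0L) break
    # worst pair first: drop the more-missing member, tie -> higher index
    ord <- order(-abs(sub[hi]))
    pr <- hi[ord[1L], ]
    li <- keep[pr[1L]]; lj <- keep[pr[2L]]
    mi <- des$missing_pct[des$label == li]
    mj <- des$missing_pct[des$label == lj]
    drop_lab <- if (mi > mj) li
      else if (mj > mi) lj
      else labs[max(match(li, labs), match(lj, labs))]
    excl <- add_excl(drop_lab, "HIGH_INTERITEM_CORR")
    keep <- setdiff(keep, drop_lab)
  }

  retained <- labs[labs %in% keep]
  alpha <- if (length(retained) >= 2L)
    cronbach_alpha(subset_items(responses, retained))
  else NA_real_
  structure(list(excluded = excl, retained = retained, descriptives = des,
                 interitem_corr = rmat, alpha = alpha),
            class = "screening_report")
}

# subset a response_matrix by item labels, preserving attributes
.subset_rm <- function(parent, labels) {
  idx <- match(labels, colnames(parent))
  out <- response_matrix(observed(parent)[, idx, drop = FALSE],
                         n_categories = n_categories(parent)[idx],
                         polarity = attr(parent, "polarity")[idx],
                         labels = labels,
                         nap = attr(parent, "nap")[, idx, drop = FALSE])
  attr(out, "reversed") <- attr(parent, "reversed")
  rownames(out) <- rownames(parent)
  out
}

#' Subset a response matrix by item label or index
#'
#' @param responses a [response_matrix()].
#' @param items labels or indices to keep.
#' @return a `response_matrix` over the selected items.
#' @export
subset_items <- function(responses, items) {
  labels <- if (is.character(items)) items else colnames(responses)[items]
  .subset_rm(responses, labels)
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report: %d retained, %d excluded, alpha = %.3f>\n",
              length(x$retained), nrow(x$excluded), x$alpha))
  if (nrow(x$excluded)) {
    for (r in split(x$excluded$label, x$excluded$reason))
      cat(" ", paste(r, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Collapse response categories with no observations
#'
#' Calibration requires every category of an item to be observed at least
#' once. This folds each empty category into its lower neighbour (leading
#' empty categories merge upward into the first observed one) and relabels
#' codes to stay contiguous, returning the same kind of map as
#' [recode_categories()].
#'
#' @param responses a [response_matrix()].
#' @return list: `map` (per item, named integer vector old -> new),
#'   `responses` (collapsed [response_matrix()]), `n_items_collapsed`.
#' @export
collapse_empty_categories <- function(responses) {
  rm <- ensure_reversed(responses)
  X <- observed(rm)
  m <- n_categories(rm)
  maps <- vector("list", ncol(X))
  names(maps) <- colnames(X)
  newX <- X
  new_m <- m
  for (i in seq_len(ncol(X))) {
    cnt <- tabulate(X[!is.na(X[, i]), i] + 1L, nbins = m[i])
    map <- integer(m[i]); nxt <- -1L
    for (c in seq_len(m[i])) {
      if (cnt[c] > 0L) nxt <- nxt + 1L
      map[c] <- max(nxt, 0L)
    }
    maps[[i]] <- stats::setNames(map, 0:(m[i] - 1L))
    newX[, i] <- map[X[, i] + 1L]
    new_m[i] <- max(map) + 1L
  }
  out <- response_matrix(newX, n_categories = new_m,
                         polarity = attr(rm, "polarity"),
                         labels = colnames(X), nap = attr(rm, "nap"))
  attr(out, "reversed") <- TRUE
  rownames(out) <- rownames(rm)
  list(map = maps, responses = out,
       n_items_collapsed = sum(vapply(maps, function(mp)
         max(mp) < length(mp) - 1L, TRUE)))
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`,
#' computed on complete cases by default (`use = "complete"`) or from the
#' pairwise-complete covariance matrix (`use = "pairwise"`). A zero
#' total-score variance yields `NA` with a warning.
#'
#' @param responses a [response_matrix()] (reverse-scored internally).
#' @param use `"complete"` or `"pairwise"`.
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(responses, use = c("complete", "pairwise")) {
  use <- match.arg(use)
  X <- observed(ensure_reversed(responses))
  if (ncol(X) < 2L) stop("alpha needs >= 2 items")
  k <- ncol(X)
  if (use == "complete") {
    X <- X[stats::complete.cases(X), , drop = FALSE]
    if (nrow(X) < 2L) stop("fewer than 2 complete cases")
    v_items <- apply(X, 2L, stats::var)
    v_total <- stats::var(rowSums(X))
  } else {
    S <- stats::cov(X, use = "pairwise.complete.obs")
    v_items <- diag(S)
    v_total <- sum(S)
  }
  if (v_total <= 0) {
    warning("total-score variance is zero; alpha undefined")
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(v_items) / v_total)
}

#' Write a screening report to disk
#'
#' JSON report (exclusions, retained set, alpha) plus a CSV of item
#' descriptives shaped like a published descriptive table.
#'
#' @param report a [screen_items()] result.
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @export
write_screening_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(list(excluded = report$excluded,
                              retained = report$retained,
                              alpha = report$alpha),
                         json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(report$descriptives, csv_path, row.names = FALSE)
  invisible(report)
}
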