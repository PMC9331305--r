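#' Differential item functioning test for one item
#'
#' Ordinal-logistic-regression DIF in the lordif tradition: three nested
#' proportional-odds models are fit by maximum likelihood —
#' M1: `item ~ theta`; M2: `item ~ theta + group`;
#' M3: `item ~ theta + group + theta:group` — with the model-based EAP
#' trait estimate as the matching criterion. Overall DIF is the M1-vs-M3
#' likelihood-ratio test; its magnitude is the pseudo-R2 change
#' `R2(M3) - R2(M1)` (McFadden by default, Nagelkerke by option),
#' classified as negligible (< 0.13), moderate (0.13 <= dR2 < 0.26) or
#' large (>= 0.26); boundary values go to the higher class. An item is
#' excluded only for large DIF with `p < alpha`.
#'
#' A group with fewer than two observed levels (or a constant item)
#' collapses all three models together: `dR2 = 0`, `p = 1`. Separation or
#' non-convergence is flagged in the result, never silent.
#'
#' @param item_responses ordinal response vector (codes `0..m-1`, `NA`
#'   allowed).
#' @param theta latent trait estimates (matching criterion).
#' @param group grouping factor.
#' @param alpha overall-DIF detection level (default 0.01).
#' @param r2 `"mcfadden"` or `"nagelkerke"`.
#' @param min_group_n minimum observations per group (default 25).
#' @return one-row data frame: `item`, `group_variable`, `n`, `p_overall`,
#'   `delta_r2`, `magnitude`, `decision`, `flagged`.
#' @export
dif_test <- function(item_responses, theta, group, alpha = 0.01,
                     r2 = c("mcfadden", "nagelkerke"), min_group_n = 25L,
                     item = "item", group_variable = "group") {
  r2 <- match.arg(r2)
  group <- droplevels(factor(group))
  ok <- !is.na(item_responses) & !is.na(theta) & !is.na(group)
  y <- droplevels(factor(item_responses[ok], ordered = TRUE))
  th <- theta[ok]
  g <- droplevels(group[ok])
  base <- data.frame(item = item, group_variable = group_variable,
                     n = sum(ok), p_overall = NA_real_,
                     delta_r2 = NA_real_, magnitude = NA_character_,
                     decision = NA_character_, flagged = FALSE)
  if (nlevels(y) < 2L || nlevels(g) < 2L) {
    base$p_overall <- 1; base$delta_r2 <- 0
    base$magnitude <- "negligible"; base$decision <- "keep"
    return(base)
  }
  if (min(table(g)) < min_group_n) {
    base$flagged <- TRUE
    warning("group '", group_variable, "' has a level with fewer than ",
            min_group_n, " observations")
  }
  dat <- data.frame(y = y, th = th, g = g)
  fits <- tryCatch({
    suppressWarnings({
      m0 <- MASS::polr(y ~ 1, data = dat, method = "logistic")
      m1 <- MASS::polr(y ~ th, data = dat, method = "logistic")
      m2 <- MASS::polr(y ~ th + g, data = dat, method = "logistic")
      m3 <- MASS::polr(y ~ th * g, data = dat, method = "logistic")
    })
    list(l0 = stats::logLik(m0), l1 = stats::logLik(m1),
         l2 = stats::logLik(m2), l3 = stats::logLik(m3))
  }, error = function(e) NULL)
  if (is.null(fits)) {
    base$flagged <- TRUE
    warning("ordinal model did not converge for item ", item,
            " x ", group_variable)
    return(base)
  }
  df13 <- attr(fits$l3, "df") - attr(fits$l1, "df")
  stat <- max(2 * (as.numeric(fits$l3) - as.numeric(fits$l1)), 0)
  p <- stats::pchisq(stat, df13, lower.tail = FALSE)
  n <- nrow(dat)
  pseudo <- function(lm_, l0_) {
    if (r2 == "mcfadden") 1 - as.numeric(lm_) / as.numeric(l0_)
    else {
      cs <- 1 - exp(2 * (as.numeric(l0_) - as.numeric(lm_)) / n)
      cs / (1 - exp(2 * as.numeric(l0_) / n))
    }
  }
  dr2 <- max(pseudo(fits$l3, fits$l0) - pseudo(fits$l1, fits$l0), 0)
  magnitude <- dif_magnitude(dr2)
  base$p_overall <- p
  base$delta_r2 <- dr2
  base$magnitude <- magnitude
  base$decision <- if (magnitude == "large" && p < alpha) "exclude" else "keep"
  base
}

#' Zumbo magnitude class for a pseudo-R2 change
#'
#' Deterministic half-open classification: negligible below 0.13, moderate
#' from 0.13 up to (but excluding) 0.26, large at 0.26 and above. Boundary
#' values belong to the higher class.
#'
#' @param delta_r2 pseudo-R2 change(s).
#' @return character vector in `{negligible, moderate, large}`.
#' @export
dif_magnitude <- function(delta_r2) {
  ifelse(delta_r2 < 0.13, "negligible",
         ifelse(delta_r2 < 0.26, "moderate", "large"))
}

#' DIF sweep over all items and grouping variables
#'
#' Runs [dif_test()] for every item against each grouping variable. The
#' default variables mirror the published screen: sex, age (median split),
#' care setting and diagnosis — one row per item x variable (26 items x 4
#' variables = 104 tests at the published bank size). A numeric age column
#' is split at the sample median automatically; a missing variable is
#' skipped with a warning.
#'
#' @param responses a [response_matrix()].
#' @param scores [eap_score()]/[score_persons()] data frame aligned with
#'   the responses.
#' @param covariates per-person data frame holding the grouping variables.
#' @param variables character vector of covariate columns to test.
#' @param alpha,r2 forwarded to [dif_test()].
#' @return list of class `"dif_table"`: `table` (stacked [dif_test()]
#'   rows), `excluded` (labels with an exclude decision), `n_tests`,
#'   `n_overall_dif` (tests with `p < alpha`).
#' @export
dif_sweep <- function(responses, scores, covariates,
                      variables = c("sex", "age", "care_setting", "diagnosis"),
                      alpha = 0.01, r2 = "mcfadden") {
  rm <- ensure_reversed(responses)
  X <- observed(rm)
  theta <- scores$theta
  rows <- list()
  for (v in variables) {
    if (is.null(covariates[[v]])) {
      warning("grouping variable '", v, "' not found; skipped")
      next
    }
    g <- covariates[[v]]
    if (is.numeric(g)) {
      med <- stats::median(g, na.rm = TRUE)
      g <- factor(ifelse(g <= med, "low", "high"), levels = c("low", "high"))
    }
    for (i in seq_len(ncol(X))) {
      rows[[length(rows) + 1L]] <-
        dif_test(X[, i], theta, g, alpha = alpha, r2 = r2,
                 item = colnames(X)[i], group_variable = v)
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 excluded = unique(tab$item[tab$decision == "exclude" &
                                              !is.na(tab$decision)]),
                 n_tests = nrow(tab),
                 n_overall_dif = sum(tab$p_overall < alpha, na.rm = TRUE)),
            class = "dif_table")
}

#' @export
print.dif_table <- function(x, ...) {
  cat(sprintf("<dif_table: %d tests, %d with overall DIF, %d item(s) excluded>\n",
              x$n_tests, x$n_overall_dif, length(x$excluded)))
  invisible(x)
}

#' Write a DIF table as CSV
#'
#' @param dif a [dif_sweep()] result.
#' @param path output path.
#' @export
write_dif_table <- function(dif, path) {
  utils::write.csv(dif$table, path, row.names = FALSE)
  invisible(path)
}
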