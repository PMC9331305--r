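#' External-validity comparison table
#'
#' Compares the 0–100 experience score against person covariates the way
#' classical known-groups validation reports do: a two-group factor gets a
#' classic Student's t-test (equal variances, two-sided), a factor with
#' three or more levels gets a one-way ANOVA, and a continuous covariate
#' gets a Pearson correlation test. Subgroup means ± SD and Ns are
#' reported per row; an empty subgroup drops the row with a warning.
#' Normality is a reader's diagnostic here, never a gate: see
#' [score_qq_data()].
#'
#' @param scores a [score_persons()] data frame (uses `score_0_100`).
#' @param covariates per-person data frame, aligned by row.
#' @param variables covariate columns to test (default: all except
#'   `person_id`).
#' @return data frame of class `"validity_table"`: `variable`, `test`
#'   (`"t"`, `"ANOVA"` or `"correlation"`), `subgroups` (collapsed
#'   `level: mean +/- sd (n)` text), `r`, `statistic`, `p_value`.
#' @export
build_validity_table <- function(scores, covariates,
                                 variables = setdiff(names(covariates),
                                                     "person_id")) {
  y <- scores$score_0_100
  rows <- list()
  for (v in variables) {
    x <- covariates[[v]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) { warning("variable '", v, "' skipped: too few data"); next }
    if (is.numeric(x) && length(unique(x[ok])) > 10L) {
      ct <- stats::cor.test(x[ok], y[ok])
      rows[[v]] <- data.frame(variable = v, test = "correlation",
                              subgroups = sprintf("n = %d", sum(ok)),
                              r = unname(ct$estimate),
                              statistic = unname(ct$statistic),
                              p_value = ct$p.value)
      next
    }
    g <- droplevels(factor(x[ok]))
    tab <- table(g)
    if (any(tab < 2L)) {
      warning("variable '", v, "' skipped: subgroup with fewer than 2 persons")
      next
    }
    mu <- tapply(y[ok], g, mean)
    sdv <- tapply(y[ok], g, stats::sd)
    sub <- paste(sprintf("%s: %.2f +/- %.2f (n=%d)", names(tab), mu, sdv,
                         as.integer(tab)), collapse = "; ")
    if (nlevels(g) == 2L) {
      tt <- stats::t.test(y[ok] ~ g, var.equal = TRUE)
      rows[[v]] <- data.frame(variable = v, test = "t", subgroups = sub,
                              r = NA_real_, statistic = unname(tt$statistic),
                              p_value = tt$p.value)
    } else {
      an <- stats::anova(stats::aov(y[ok] ~ g))
      rows[[v]] <- data.frame(variable = v, test = "ANOVA", subgroups = sub,
                              r = NA_real_, statistic = an$`F value`[1L],
                              p_value = an$`Pr(>F)`[1L])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(variable = character(), test = character(),
                    subgroups = character(), r = numeric(),
                    statistic = numeric(), p_value = numeric())
  rownames(out) <- NULL
  class(out) <- c("validity_table", class(out))
  out
}

#' Normal Q-Q diagnostic data for the score distribution
#'
#' Theoretical vs. sample quantiles of the 0–100 scores, for a reader's
#' Q-Q plot. Reported as data, never used to gate any test.
#'
#' @param scores a [score_persons()] data frame.
#' @return data frame `theoretical`, `sample`.
#' @export
score_qq_data <- function(scores) {
  s <- sort(scores$score_0_100)
  n <- length(s)
  data.frame(theoretical = stats::qnorm(stats::ppoints(n),
                                        mean = mean(s), sd = stats::sd(s)),
             sample = s)
}

#' Write a validity table as CSV plus a text report
#'
#' @param vt a [build_validity_table()] result.
#' @param csv_path,txt_path output paths (either may be `NULL`).
#' @export
write_validity_report <- function(vt, csv_path = NULL, txt_path = NULL) {
  if (!is.null(csv_path)) utils::write.csv(vt, csv_path, row.names = FALSE)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    writeLines("External validity of the 0-100 experience score", con)
    writeLines(strrep("-", 48), con)
    for (i in seq_len(nrow(vt))) {
      writeLines(sprintf("%s [%s]  p = %.4g%s", vt$variable[i], vt$test[i],
                         vt$p_value[i],
                         if (!is.na(vt$r[i])) sprintf("  r = %.3f", vt$r[i])
                         else ""), con)
      writeLines(paste0("  ", vt$subgroups[i]), con)
    }
  }
  invisible(vt)
}
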