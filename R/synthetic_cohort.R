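#' Published descriptive profile of the 37-item drug-therapy item pool
#'
#' Per-item floor/ceiling/missing percentages, skewness and wording polarity
#' of the 37-item PREMIUM-DT pool, as published for the 541-patient
#' calibration sample. Used as the default target profile of the synthetic
#' cohort generator (in particular its per-item missingness rates, which
#' range from 0.4% to 49.7%) and as a reference shape for descriptive
#' reports.
#'
#' @return data frame with columns `label`, `floor_pct`, `ceiling_pct`,
#'   `missing_pct`, `skewness`, `polarity`.
#' @export
premium_dt_items <- function() {
  flo <- c(7.4, 5.0, 4.8, 5.4, 5.0, 5.2, 4.8, 3.9, 5.2, 10.4, 13.5, 1.8,
           13.7, 11.3, 16.3, 10.4, 8.9, 2.4, 4.8, 7.2, 6.8, 1.5, 9.2, 13.7,
           5.0, 6.5, 27.9, 16.8, 25.7, 18.7, 11.8, 5.7, 16.1, 23.1, 21.6,
           9.2, 8.1)
  cei <- c(20.1, 26.2, 29.8, 22.9, 28.8, 29.2, 27.4, 28.8, 21.3, 20.0, 12.6,
           35.5, 13.3, 15.3, 11.8, 16.6, 18.5, 29.6, 29.2, 25.9, 19.4, 12.2,
           14.4, 10.7, 22.9, 22.7, 8.5, 6.8, 9.4, 12.2, 17.2, 23.5, 13.1,
           9.4, 9.8, 10.9, 14.4)
  mis <- c(4.1, 2.2, 1.7, 1.5, 2.6, 4.4, 8.5, 2.8, 5.2, 3.5, 4.1, 3.5, 2.8,
           2.8, 5.5, 2.0, 3.0, 1.8, 0.9, 0.7, 0.7, 48.4, 1.1, 1.8, 0.6, 0.4,
           4.4, 49.7, 1.5, 1.7, 1.8, 2.8, 1.7, 1.7, 9.4, 6.5, 4.3)
  skw <- c(-0.56, -0.77, -0.90, -0.57, -1.05, -1.08, -1.06, -1.06, -0.76,
           -0.24, 0.08, -1.45, -0.06, -0.27, 0.07, -0.38, -0.46, -1.07,
           -1.02, -0.84, -0.63, -0.90, -0.34, -0.12, -0.81, -0.78, 2.04,
           1.59, 1.65, 1.30, 1.08, 1.32, 1.37, 1.62, 1.55, -0.20, 1.85)
  neg <- c(27, 28, 29, 30, 31, 32, 33, 34, 35, 37)
  data.frame(label = paste0("DT", 1:37),
             floor_pct = flo, ceiling_pct = cei, missing_pct = mis,
             skewness = skw,
             polarity = ifelse(1:37 %in% neg, "negative", "positive"))
}

#' Generate a ground-truth item bank
#'
#' Discriminations are drawn uniformly in `a_range` and each item's
#' `n_categories - 1` thresholds are drawn uniformly in `b_range`, then
#' sorted ascending within the item. The default ranges reproduce the
#' published calibration: discriminations 0.48–2.70 and thresholds
#' −1.96–3.25. Setting `disorder = TRUE` skips the sort, producing banks
#' with reversed (disordered) thresholds so category-collapse logic can be
#' exercised.
#'
#' @param n_items number of items (>= 1).
#' @param a_range discrimination range, lower bound > 0.
#' @param b_range threshold range.
#' @param n_categories ordered categories per item (>= 2).
#' @param seed integer seed; the same seed reproduces the bank exactly.
#' @param labels item labels.
#' @param disorder keep thresholds in draw order instead of sorting.
#' @return an [item_bank()].
#' @export
generate_bank <- function(n_items = 26L, a_range = c(0.48, 2.70),
                          b_range = c(-1.96, 3.25), n_categories = 5L,
                          seed = 1L, labels = paste0("DT", seq_len(n_items)),
                          disorder = FALSE) {
  if (n_items < 1L) stop("'n_items' must be >= 1")
  if (a_range[1L] <= 0) stop("invalid parameter: a_range lower bound must be positive")
  if (n_categories < 2L) stop("'n_categories' must be >= 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  a <- stats::runif(n_items, a_range[1L], a_range[2L])
  b <- replicate(n_items, {
    bi <- stats::runif(n_categories - 1L, b_range[1L], b_range[2L])
    if (disorder) bi else sort(bi)
  }, simplify = FALSE)
  item_bank(a, b, labels = labels)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Specification of a synthetic cohort
#'
#' Describes the population from which [simulate_cohort()] draws: latent
#' trait distribution, per-item missing / not-applicable rates, optional
#' injected differential item functioning, and the covariate model linking
#' the trait to adherence, quality-of-life and satisfaction proxies. The
#' defaults emulate the published calibration sample: 541 respondents,
#' trait ~ N(0,1), group base rates 54.7% men, 93.2% outpatient, diagnosis
#' mix 61.9/19.6/18.5%, and age centred on the median of 36 years.
#'
#' @param n_persons cohort size.
#' @param theta_mean,theta_sd latent trait distribution.
#' @param missing_rate scalar or per-item missing-completely-at-random rate
#'   in `[0, 1]`.
#' @param nap_rate scalar or per-item "not applicable" rate in `[0, 1]`.
#' @param dif_effects list of DIF injections, each a list with fields
#'   `item` (label or index), `group` (covariate name), `uniform_shift`
#'   (added to every threshold for the focal group) and `slope_factor`
#'   (multiplies the discrimination for the focal group). The focal group
#'   is the last level of the covariate.
#' @param covariate_link correlation in `[0, 1)` between the trait and the
#'   continuous proxies (adherence, quality-of-life subscores); default 0.3,
#'   matching the weak published correlations (~0.2–0.3).
#' @param satisfaction_link correlation between trait and the satisfaction
#'   proxy; default 0.65 (published r with overall satisfaction).
#' @param theta_dependent_missing if `TRUE`, missingness probability rises
#'   for lower-trait persons (off by default; the default mechanism is MCAR).
#' @param group_probs base rates for `sex` (P(men)), `care_setting`
#'   (P(outpatient)) and `diagnosis` (3 probabilities).
#' @param seed integer seed; fixed seed gives bit-identical cohorts.
#' @return a list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_persons = 541L, theta_mean = 0, theta_sd = 1,
                        missing_rate = 0, nap_rate = 0,
                        dif_effects = list(),
                        covariate_link = 0.3, satisfaction_link = 0.65,
                        theta_dependent_missing = FALSE,
                        group_probs = list(sex = 0.547,
                                           care_setting = 0.932,
                                           diagnosis = c(0.619, 0.196, 0.185)),
                        seed = 1L) {
  stopifnot(n_persons >= 1, theta_sd > 0,
            all(missing_rate >= 0 & missing_rate <= 1),
            all(nap_rate >= 0 & nap_rate <= 1))
  structure(list(n_persons = as.integer(n_persons), theta_mean = theta_mean,
                 theta_sd = theta_sd, missing_rate = missing_rate,
                 nap_rate = nap_rate, dif_effects = dif_effects,
                 covariate_link = covariate_link,
                 satisfaction_link = satisfaction_link,
                 theta_dependent_missing = theta_dependent_missing,
                 group_probs = group_probs, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a GPCM-governed cohort with known ground truth
#'
#' Draws each person's trait from the spec's normal distribution, samples
#' every response from the GPCM category probabilities of the bank (after
#' applying any injected DIF shift/slope change for focal-group members),
#' then masks entries to missing / not-applicable at the specified rates.
#' Covariates are generated so that a higher trait goes with better
#' adherence, quality of life and satisfaction at the configured
#' correlations. Items with negative polarity in the bank are emitted in
#' their raw (reverse-worded) coding, so the cohort exercises
#' [reverse_score()] downstream.
#'
#' @param bank an [item_bank()] (the ground truth).
#' @param spec a [cohort_spec()].
#' @return list of class `"synthetic_cohort"` with elements `responses`
#'   (a [response_matrix()]), `true_theta`, `bank`, `covariates` (data
#'   frame: `person_id`, `sex`, `age`, `age_group`, `care_setting`,
#'   `diagnosis`, `adherence`, `qol_pcs`, `qol_mcs`, `satisfaction`), and
#'   `spec`.
#' @export
simulate_cohort <- function(bank, spec = cohort_spec()) {
  k <- length(bank$a)
  n <- spec$n_persons
  miss <- rep_len(spec$missing_rate, k)
  napr <- rep_len(spec$nap_rate, k)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  theta <- stats::rnorm(n, spec$theta_mean, spec$theta_sd)

  covariates <- .simulate_covariates(theta, spec)

  # resolve DIF injections to (item index, focal person mask, shift, factor)
  dif <- lapply(spec$dif_effects, function(e) {
    idx <- if (is.character(e$item)) match(e$item, bank$labels) else as.integer(e$item)
    if (is.na(idx) || idx < 1L || idx > k)
      stop("dif_effects references unknown item: ", e$item)
    g <- covariates[[e$group]]
    if (is.null(g)) stop("dif_effects references unknown group variable: ", e$group)
    g <- as.factor(g)
    list(item = idx, focal = g == levels(g)[nlevels(g)],
         shift = e$uniform_shift %||% 0, factor = e$slope_factor %||% 1)
  })

  X <- matrix(NA_integer_, n, k)
  for (i in seq_len(k)) {
    a_p <- rep(bank$a[i], n)
    bmat <- matrix(bank$b[[i]], n, bank$m[i] - 1L, byrow = TRUE)
    for (e in dif) {
      if (e$item == i) {
        bmat[e$focal, ] <- bmat[e$focal, , drop = FALSE] + e$shift
        a_p[e$focal] <- a_p[e$focal] * e$factor
      }
    }
    X[, i] <- .draw_gpcm(theta, a_p, bmat)
  }
  # negative-polarity items emitted in raw (reverse-worded) coding
  for (i in which(bank$polarity == "negative"))
    X[, i] <- (bank$m[i] - 1L) - X[, i]

  # masking: MCAR by default, optionally trait-dependent
  nap <- matrix(FALSE, n, k)
  for (i in seq_len(k)) {
    pm <- rep(miss[i], n)
    if (spec$theta_dependent_missing && miss[i] > 0) {
      pm <- stats::plogis(stats::qlogis(pmin(pmax(miss[i], 1e-6), 1 - 1e-6)) - 0.5 * theta)
    }
    drop_miss <- stats::runif(n) < pm
    drop_nap <- stats::runif(n) < napr[i]
    nap[, i] <- drop_nap & !drop_miss
    X[drop_miss | drop_nap, i] <- NA_integer_
  }

  rm <- response_matrix(X, n_categories = bank$m, polarity = bank$polarity,
                        labels = bank$labels, nap = nap)
  structure(list(responses = rm, true_theta = theta, bank = bank,
                 covariates = covariates, spec = spec),
            class = "synthetic_cohort")
}

# vectorized GPCM draw with per-person parameters (n x (m-1) threshold matrix)
.draw_gpcm <- function(theta, a, bmat) {
  n <- length(theta)
  m <- ncol(bmat) + 1L
  csb <- cbind(0, t(apply(bmat, 1L, cumsum)))
  if (m == 2L) csb <- cbind(0, bmat)  # apply() drops dims for one column
  eta <- (theta * a) %o% (0:(m - 1L)) - a * csb
  eta <- eta - apply(eta, 1L, max)
  p <- exp(eta)
  p <- p / rowSums(p)
  cp <- t(apply(p, 1L, cumsum))
  u <- stats::runif(n)
  as.integer(rowSums(u > cp))
}

.simulate_covariates <- function(theta, spec) {
  n <- length(theta)
  r <- spec$covariate_link
  rs <- spec$satisfaction_link
  noisy <- function(rho) rho * theta + sqrt(1 - rho^2) * stats::rnorm(n)
  gp <- spec$group_probs
  sex <- factor(ifelse(stats::runif(n) < gp$sex, "men", "women"),
                levels = c("men", "women"))
  care <- factor(ifelse(stats::runif(n) < gp$care_setting, "outpatient", "inpatient"),
                 levels = c("outpatient", "inpatient"))
  dx <- factor(sample(c("schizophrenia", "bipolar", "depression"), n,
                      replace = TRUE, prob = gp$diagnosis),
               levels = c("schizophrenia", "bipolar", "depression"))
  age <- round(pmin(pmax(stats::rnorm(n, 37, 12), 18), 65))
  adherence <- pmin(pmax(round(6 + 2 * noisy(r)), 0), 10)    # MARS-like 0-10
  qol_pcs <- 43.5 + 9.8 * noisy(r)                           # SF-12-like
  qol_mcs <- 39.0 + 9.9 * noisy(r)
  satisfaction <- pmin(pmax(round(5 + 2.5 * noisy(rs)), 0), 10)
  data.frame(person_id = paste0("P", seq_len(n)), sex = sex, age = age,
             age_group = factor(ifelse(age <= stats::median(age), "younger", "older"),
                                levels = c("younger", "older")),
             care_setting = care, diagnosis = dx, adherence = adherence,
             qol_pcs = qol_pcs, qol_mcs = qol_mcs, satisfaction = satisfaction)
}

#' Write a synthetic cohort to disk
#'
#' Emits the response matrix and covariates as CSV plus a JSON ground-truth
#' file holding the bank parameters, true trait values and DIF spec.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_responses(cohort$responses, file.path(dir, "responses.csv"))
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- list(bank = lapply(seq_along(cohort$bank$a), function(i) {
    list(label = cohort$bank$labels[i], a = cohort$bank$a[i],
         b = cohort$bank$b[[i]], m = cohort$bank$m[i],
         polarity = cohort$bank$polarity[i])
  }), true_theta = cohort$true_theta, dif_effects = cohort$spec$dif_effects,
  seed = cohort$spec$seed)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
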