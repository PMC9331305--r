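test_that("generated banks respect parameter ranges and sorted thresholds", {
  b <- generate_bank(26, a_range = c(0.48, 2.70), b_range = c(-1.96, 3.25),
                     n_categories = 5, seed = 1)
  expect_length(b$a, 26)
  expect_true(all(b$a >= 0.48 & b$a <= 2.70))
  expect_true(all(unlist(b$b) >= -1.96 & unlist(b$b) <= 3.25))
  expect_true(all(vapply(b$b, function(x) !is.unsorted(x), TRUE)))
  expect_error(generate_bank(3, a_range = c(-1, 2)), "positive")
})

test_that("degenerate ranges and seed determinism behave exactly", {
  b <- generate_bank(1, a_range = c(1, 1), b_range = c(0, 0),
                     n_categories = 2, seed = 0)
  expect_equal(b$a, 1)
  expect_equal(b$b[[1]], 0)
  expect_identical(generate_bank(5, seed = 7), generate_bank(5, seed = 7))
  d <- generate_bank(6, seed = 3, disorder = TRUE)
  expect_false(all(vapply(d$b, function(x) !is.unsorted(x), TRUE)))
})

test_that("cohorts are reproducible and complete when no masking is requested", {
  b <- fx_bank(5)
  sp <- cohort_spec(n_persons = 50, missing_rate = 0, nap_rate = 0, seed = 9)
  c1 <- simulate_cohort(b, sp)
  c2 <- simulate_cohort(b, sp)
  expect_identical(observed(c1$responses), observed(c2$responses))
  expect_identical(c1$true_theta, c2$true_theta)
  expect_identical(c1$covariates, c2$covariates)
  expect_false(anyNA(observed(c1$responses)))
  expect_false(any(attr(c1$responses, "nap")))
})

test_that("observed missing and NAP proportions track the requested rates", {
  b <- fx_bank(6)
  rates <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
  co <- simulate_cohort(b, cohort_spec(n_persons = 4000, missing_rate = rates,
                                       nap_rate = 0.05, seed = 17))
  X <- unclass(co$responses)
  nap <- attr(co$responses, "nap")
  miss_obs <- colMeans(is.na(X) & !nap)
  # Monte-Carlo tolerance: 3 binomial SEs
  tol <- 3 * sqrt(rates * (1 - rates) / 4000)
  expect_true(all(abs(miss_obs - rates) < tol + 0.01))
  expect_true(all(abs(colMeans(nap) - 0.05 * (1 - rates)) < 0.02))
})

test_that("category frequencies match GPCM marginals integrated over the prior", {
  b <- item_bank(a = 2, b = list(c(-1, 0, 1, 2)), labels = "X1")
  co <- simulate_cohort(b, cohort_spec(n_persons = 20000, seed = 5))
  obs_freq <- tabulate(observed(co$responses)[, 1] + 1L, 5) / 20000
  # oracle: brute-force integration of category probabilities over a fine grid
  th <- seq(-6, 6, length.out = 4001)
  w <- dnorm(th); w <- w / sum(w)
  marg <- colSums(category_probs(th, 2, c(-1, 0, 1, 2)) * w)
  expect_lt(max(abs(obs_freq - marg)), 0.01)
})

test_that("injected uniform DIF shifts the focal group's expected score", {
  b <- fx_bank(4)
  eff <- list(list(item = "DT2", group = "sex", uniform_shift = 1.5,
                   slope_factor = 1))
  co <- simulate_cohort(b, cohort_spec(n_persons = 4000, seed = 33,
                                       dif_effects = eff))
  X <- observed(co$responses)
  focal <- co$covariates$sex == "women"
  # positive threshold shift makes high categories harder for the focal group
  expect_lt(mean(X[focal, 2]), mean(X[!focal, 2]) - 0.1)
  expect_lt(abs(mean(X[focal, 1]) - mean(X[!focal, 1])), 0.15)
  expect_error(
    simulate_cohort(b, cohort_spec(n_persons = 20, dif_effects =
      list(list(item = "nope", group = "sex", uniform_shift = 1)))),
    "unknown item")
  expect_error(
    simulate_cohort(b, cohort_spec(n_persons = 20, dif_effects =
      list(list(item = "DT1", group = "nope", uniform_shift = 1)))),
    "unknown group")
})

test_that("covariates associate with the trait in the configured direction", {
  co <- fx_cohort()
  expect_gt(cor(co$true_theta, co$covariates$adherence), 0.15)
  expect_gt(cor(co$true_theta, co$covariates$satisfaction), 0.5)
  expect_gt(cor(co$true_theta, co$covariates$qol_pcs), 0.15)
})

test_that("cohorts serialize to responses/covariates CSV plus ground-truth JSON", {
  b <- fx_bank(3)
  co <- simulate_cohort(b, cohort_spec(n_persons = 25, missing_rate = 0.2,
                                       nap_rate = 0.1, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_setequal(list.files(dir),
                  c("responses.csv", "covariates.csv", "ground_truth.json"))
  back <- read_responses(file.path(dir, "responses.csv"),
                         n_categories = b$m, polarity = b$polarity)
  expect_identical(observed(back), observed(co$responses))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$bank$a, b$a)
  expect_equal(truth$true_theta, co$true_theta, tolerance = 1e-12)
})
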