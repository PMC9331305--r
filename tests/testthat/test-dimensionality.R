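test_that("polychoric estimates recover the latent correlation of discretized normals", {
  set.seed(61)
  n <- 5000
  rho <- 0.6
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cuts <- qnorm(c(0.2, 0.4, 0.6, 0.8))
  x1 <- findInterval(z1, cuts)
  x2 <- findInterval(z2, cuts)
  rm <- response_matrix(cbind(x1, x2), labels = c("u", "v"))
  pc <- polychoric_corr(rm)
  expect_lt(abs(pc$rho[1, 2] - rho), 0.05)
  # an item against itself is a unit correlation
  self <- polychoric_corr(response_matrix(cbind(x1, x1), labels = c("a", "b")))
  expect_gt(self$rho[1, 2], 0.99)
  # independent items estimate near zero
  ind <- polychoric_corr(response_matrix(
    cbind(x1, findInterval(rnorm(n), cuts)), labels = c("a", "b")))
  expect_lt(abs(ind$rho[1, 2]), 0.05)
})

test_that("polychoric matrices have unit diagonal and admissible eigenvalues", {
  pc <- polychoric_corr(fx_cohort()$responses)
  expect_equal(diag(pc$rho), setNames(rep(1, 8), colnames(pc$rho)))
  expect_equal(pc$rho, t(pc$rho))
  expect_gt(min(eigen(pc$rho, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_error(polychoric_corr(response_matrix(matrix(c(1L, 1L, 0L, 1L), 2),
                                               labels = c("flat", "ok"))),
               "flat")
})

test_that("eigenvalue sum equals the item count and known ratios reproduce", {
  pc <- polychoric_corr(fx_cohort()$responses)
  ep <- eigen_and_parallel(pc, n_persons = 600, reps = 100, seed = 3)
  expect_equal(sum(ep$eigenvalues), 8, tolerance = 1e-8)
  # published design arithmetic: first two eigenvalues 11.4 and 3.3 give 3.5
  expect_equal(round(11.4 / 3.3, 1), 3.5)
  # identity matrix: all eigenvalues 1, ratio 1
  ident <- eigen_and_parallel(diag(6), n_persons = 500, reps = 100, seed = 1)
  expect_equal(ident$eigenvalues, rep(1, 6))
  expect_equal(ident$ratio_1_2, 1)
  # parallel-analysis thresholds decrease across factor index
  expect_true(all(diff(ep$pa_thresholds) < 0))
  expect_error(eigen_and_parallel(pc, 600, reps = 10), "100")
})

test_that("an equicorrelated one-factor population matrix has the closed-form eigenvalue", {
  k <- 26
  R <- pop_corr(matrix(0.7, k, 1))
  ev <- eigen_and_parallel(R, n_persons = 1000, reps = 100, seed = 2)
  expect_equal(ev$eigenvalues[1], 1 + (k - 1) * 0.49, tolerance = 1e-10)
  expect_equal(ev$n_factors_kaiser, 1)
})

test_that("a perfect one-factor population matrix fits exactly", {
  R <- pop_corr(matrix(0.7, 12, 1))
  dimnames(R) <- list(paste0("I", 1:12), paste0("I", 1:12))
  f <- fit_one_factor(R, n_persons = 541)
  expect_equal(f$chi_square, 0, tolerance = 1e-6)
  expect_equal(f$rmsea, 0)
  expect_equal(f$cfi, 1)
  expect_equal(f$tli, 1, tolerance = 1e-8)
  expect_equal(unname(f$loadings), rep(0.7, 12), tolerance = 1e-5)
  expect_true(all(abs(f$residuals) < 0.25))
  expect_equal(nrow(f$flagged_pairs), 0)
})

test_that("a two-factor population forced into one factor misfits clearly", {
  L <- matrix(0, 12, 2)
  L[1:6, 1] <- 0.8
  L[7:12, 2] <- 0.8
  R <- pop_corr(L) + 0.1 * (tcrossprod(c(rep(1, 6), rep(0, 6)),
                                       c(rep(0, 6), rep(1, 6))) +
                            tcrossprod(c(rep(0, 6), rep(1, 6)),
                                       c(rep(1, 6), rep(0, 6))))
  dimnames(R) <- list(paste0("I", 1:12), paste0("I", 1:12))
  f <- fit_one_factor(R, n_persons = 541)
  expect_gt(f$rmsea, 0.10)
  expect_lt(f$rmsea_ci["lower"], f$rmsea)
  expect_gt(f$rmsea_ci["upper"], f$rmsea)
})

test_that("bifactor indices satisfy their identities and recover truth", {
  # ECV percentages always sum to 100
  pc <- polychoric_corr(fx_cohort()$responses)
  bf <- bifactor(pc, 600)
  expect_equal(bf$ecv_general + sum(bf$ecv_group), 100, tolerance = 1e-9)
  expect_lte(bf$omega_h_general, bf$omega_total + 1e-12)
  # general-only population: omega_h equals omega_total, ECV_general = 100
  Rg <- pop_corr(matrix(0.7, 12, 1))
  dimnames(Rg) <- list(paste0("I", 1:12), paste0("I", 1:12))
  bfg <- bifactor(Rg, 500, groups = rep(1:2, each = 6))
  expect_equal(bfg$ecv_general, 100, tolerance = 0.5)
  expect_equal(bfg$omega_h_general, bfg$omega_total, tolerance = 5e-3)
  # true bifactor population with three group factors (two group factors
  # leave the general/group split unidentified, so three are used, as in
  # the instrument's published structure): fitted indices match the
  # closed-form formulas evaluated on the true loadings
  g <- rep(0.6, 12)
  s <- rep(0.4, 12)
  grp <- rep(1:3, each = 4)
  Lt <- cbind(g, sapply(1:3, function(j) ifelse(grp == j, s, 0)))
  Rt <- pop_corr(Lt)
  dimnames(Rt) <- list(paste0("I", 1:12), paste0("I", 1:12))
  bft <- bifactor(Rt, 500, groups = grp)
  psi <- 1 - g^2 - s^2
  omega_h_true <- sum(g)^2 / (sum(g)^2 + 3 * sum(s[1:4])^2 + sum(psi))
  ecv_true <- 100 * sum(g^2) / (sum(g^2) + sum(s^2))
  expect_equal(bft$omega_h_general, omega_h_true, tolerance = 1e-3)
  expect_equal(bft$ecv_general, ecv_true, tolerance = 0.2)
})

test_that("monotone data pass and an inverted item fails the rest-score check", {
  co <- fx_cohort()
  mono <- monotonicity_check(co$responses)
  expect_true(all(mono$status == "pass"))
  X <- observed(co$responses)
  X[, 2] <- 4L - X[, 2]  # invert without flagging it reverse-worded
  rm <- response_matrix(X, labels = colnames(X))
  mono2 <- monotonicity_check(rm)
  expect_equal(mono2$status[2], "fail")
  # a constant item is skipped with a warning
  X[, 5] <- 2L
  expect_warning(mono3 <- monotonicity_check(
    response_matrix(X, labels = colnames(X))), "skipped")
  expect_equal(mono3$status[5], "skipped")
})

test_that("never-modal categories are collapsed with a consistent recode map", {
  # disordered thresholds guarantee categories that are never modal; the
  # extra well-behaved items anchor the provisional calibration
  b <- item_bank(a = c(1.5, 2, 1.6, 1.8, 1.4, 1.7),
                 b = c(list(c(0.6, -0.6, 1.8, 1.0), c(-2, -0.7, 0.6, 2)),
                       lapply(c(-1, -0.5, 0, 0.5), function(o) o + c(-1.2, -0.4, 0.4, 1.2))),
                 labels = c("disordered", "spread", paste0("A", 1:4)))
  co <- simulate_cohort(b, cohort_spec(n_persons = 1500, seed = 91))
  rc <- recode_categories(co$responses)
  expect_true(all(vapply(rc$map, function(m) all(diff(m) %in% c(0L, 1L)), TRUE)))
  expect_true(all(vapply(rc$map, function(m) m[1] == 0L, TRUE)))
  # the spread item with well-separated thresholds keeps all its categories
  expect_equal(unname(rc$map$spread), 0:4)
  expect_gte(rc$n_items_recoded, 1)
  # recoded matrix is consistent with the map
  Xo <- observed(co$responses)
  Xn <- observed(rc$responses)
  expect_true(all(Xn[, 1] == rc$map$disordered[Xo[, 1] + 1L], na.rm = TRUE))
})
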