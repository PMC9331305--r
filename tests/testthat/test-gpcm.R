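test_that("category probabilities normalize and match the direct formula", {
  # dichotomous boundary: theta at the threshold splits 50/50
  expect_equal(as.vector(category_probs(0.5, a = 1, b = 0.5)), c(0.5, 0.5))
  # frozen oracle: direct evaluation of the cumulative-sum exponent formula
  p <- as.vector(category_probs(0, a = 1.5, b = c(-1, 0, 1, 2)))
  expect_equal(p, c(0.090800417593, 0.406939239108, 0.406939239108,
                    0.090800417593, 0.004520686599), tolerance = 1e-10)
  # normalization everywhere, including extreme traits
  for (th in c(-30, -3, 0, 2.5, 30)) {
    pr <- category_probs(th, a = 2.2, b = c(-1.5, 0.2, 0.9, 3))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr >= 0))
  }
})

test_that("a dichotomous GPCM item reproduces the two-parameter logistic", {
  th <- seq(-4, 4, length.out = 41)
  a <- 1.7; b <- -0.3
  p <- category_probs(th, a, b)[, 2]
  expect_equal(p, plogis(a * (th - b)), tolerance = 1e-12)
})

test_that("EAP falls back to the prior and agrees with a fine-grid oracle", {
  bank <- fx_bank(6)
  grid <- quadrature_grid(61)
  allmiss <- eap_score(rep(NA_integer_, 6), bank, grid)
  expect_equal(allmiss$theta, 0, tolerance = 1e-9)
  expect_equal(allmiss$sem, 1, tolerance = 5e-3)
  fine <- quadrature_grid(2001)
  set.seed(21)
  for (r in 1:20) {
    pat <- vapply(seq_len(6), function(i) sample(0:(bank$m[i] - 1L), 1), 0L)
    expect_lt(abs(eap_score(pat, bank, grid)$theta -
                    eap_score(pat, bank, fine)$theta), 1e-3)
  }
})

test_that("raising one response never lowers the EAP estimate", {
  bank <- fx_bank(5)
  set.seed(31)
  for (r in 1:10) {
    pat <- vapply(seq_len(5), function(i) sample(0:(bank$m[i] - 1L), 1), 0L)
    i <- sample(5, 1)
    if (pat[i] == bank$m[i] - 1L) pat[i] <- pat[i] - 1L
    up <- pat
    up[i] <- up[i] + 1L
    expect_gte(eap_score(up, bank)$theta, eap_score(pat, bank)$theta)
  }
})

test_that("test information is the sum of item informations and scales as a^2", {
  bank <- fx_bank(7)
  info <- information(bank)
  expect_equal(info$test, rowSums(info$item), tolerance = 1e-12)
  expect_true(all(info$item >= 0))
  # doubling a on a dichotomous item quadruples peak information
  i1 <- information(item_bank(1, list(0)), theta = seq(-3, 3, 0.01))
  i2 <- information(item_bank(2, list(0)), theta = seq(-3, 3, 0.01))
  expect_equal(max(i2$test), 4 * max(i1$test), tolerance = 1e-9)
})

test_that("information share in an interval matches a trapezoidal oracle", {
  bank <- fx_bank(10)
  frac <- information_fraction(bank, c(-2, 2), total_range = c(-4, 4))
  trap <- function(lo, hi) {
    th <- seq(lo, hi, length.out = 20001)
    pracma::trapz(th, information(bank, th)$test)
  }
  oracle <- trap(-2, 2) / trap(-4, 4)
  expect_equal(frac, oracle, tolerance = 1e-6)
  expect_true(frac > 0 && frac < 1)
})

test_that("the 0-100 transform maps anchors to the endpoints linearly", {
  anchors <- c(-2.3, 1.9)
  expect_equal(transform_score(anchors[1], anchors), 0)
  expect_equal(transform_score(anchors[2], anchors), 100)
  expect_equal(transform_score(mean(anchors), anchors), 50)
  th <- seq(anchors[1], anchors[2], length.out = 50)
  expect_true(all(diff(transform_score(th, anchors)) > 0))
  expect_equal(transform_score(-10, anchors), 0)  # clipped outside
  expect_error(transform_score(0, c(1, 1)), "degenerate")
})

test_that("default anchors bracket every observable pattern's EAP", {
  bank <- fx_bank()
  an <- default_anchors(bank)
  expect_lt(an[1], an[2])
  sc <- score_persons(fx_cohort()$responses, bank)
  expect_true(all(sc$score_0_100 >= 0 & sc$score_0_100 <= 100))
  # all-minimum and all-maximum patterns hit the endpoints exactly
  expect_equal(transform_score(eap_score(rep(0L, 8), bank)$theta, an), 0)
  expect_equal(transform_score(eap_score(bank$m - 1L, bank)$theta, an), 100)
})

test_that("banks roundtrip through JSON exactly", {
  bank <- fx_bank(5)
  path <- withr::local_tempfile(fileext = ".json")
  write_bank(bank, path)
  back <- read_bank(path)
  expect_equal(back$a, bank$a, tolerance = 1e-12)
  expect_equal(back$b, bank$b, tolerance = 1e-12)
  expect_identical(back$labels, bank$labels)
})
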