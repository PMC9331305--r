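test_that("descriptives match hand-computed moments on a tiny item", {
  x <- matrix(c(0L, 0L, 1L, 4L), 4, 1)
  d <- describe_items(response_matrix(x, labels = "A"))
  expect_equal(d$floor_pct, 50)
  expect_equal(d$ceiling_pct, 25)
  expect_equal(d$mean, 1.25)
  # third standardized moment of {0,0,1,4}, frozen from the moment formula
  expect_equal(d$skewness, 0.957549162553564, tolerance = 1e-12)
})

test_that("degenerate items are flagged, never silently dropped", {
  x <- matrix(c(2L, 2L, 2L, NA, NA, NA), 3, 2)
  d <- describe_items(response_matrix(x, labels = c("const", "empty")))
  expect_equal(nrow(d), 2)
  expect_equal(d$sd[1], 0)
  expect_true(is.na(d$skewness[1]))
  expect_equal(d$max_category_pct[1], 100)
  expect_equal(d$n_obs[2], 0)
  expect_true(is.na(d$mean[2]))
  expect_equal(d$missing_pct[2], 100)
})

test_that("floor plus ceiling never exceeds 100 percent", {
  co <- fx_cohort()
  d <- describe_items(co$responses)
  expect_true(all(d$floor_pct + d$ceiling_pct <= 100 + 1e-9))
  expect_true(all(d$missing_pct >= 0 & d$missing_pct <= 100))
})

test_that("each screening rule fires on its own construction", {
  set.seed(1)
  n <- 300
  base <- replicate(4, sample(0:4, n, replace = TRUE))
  # items 3 and 4 duplicates plus noise; item 5 mostly missing
  dup <- pmin(pmax(base[, 3] + sample(c(0L, 0L, 1L, -1L), n, replace = TRUE), 0L), 4L)
  x5 <- sample(0:4, n, replace = TRUE)
  x5[seq_len(0.8 * n)] <- NA
  rm <- response_matrix(cbind(base[, 1:3], dup, x5),
                        labels = paste0("I", 1:5))
  expect_gt(abs(cor(base[, 3], dup)), 0.70)  # the pair really is collinear
  rep <- screen_items(rm)
  hic <- rep$excluded$label[rep$excluded$reason == "HIGH_INTERITEM_CORR"]
  expect_length(intersect(c("I3", "I4"), hic), 1)
  expect_true("I5" %in%
                rep$excluded$label[rep$excluded$reason == "MISSING_GT_THRESHOLD"])
  expect_setequal(c(rep$excluded$label, rep$retained), paste0("I", 1:5))
  expect_length(intersect(rep$excluded$label, rep$retained), 0)
})

test_that("extreme one-category concentration triggers the skew rule", {
  x <- matrix(sample(0:4, 200, replace = TRUE), 100, 2)
  x[, 2] <- c(rep(0L, 97), 1L, 2L, 3L)
  rm <- response_matrix(x, labels = c("ok", "spike"))
  rep <- screen_items(rm)
  expect_equal(rep$excluded$reason[rep$excluded$label == "spike"],
               "EXTREME_SKEW")
})

test_that("independent complete items are all retained and screening is idempotent", {
  set.seed(4)
  rm <- response_matrix(replicate(6, sample(0:4, 400, replace = TRUE)),
                        labels = paste0("I", 1:6))
  rep <- screen_items(rm)
  expect_equal(nrow(rep$excluded), 0)
  again <- screen_items(subset_items(rm, rep$retained))
  expect_equal(nrow(again$excluded), 0)
  expect_setequal(again$retained, rep$retained)
})

test_that("the more-missing member of a collinear pair is the one dropped", {
  set.seed(8)
  z <- sample(0:4, 500, replace = TRUE)
  x1 <- z
  x2 <- z
  x2[1:50] <- NA  # same construct, more missingness
  rm <- response_matrix(cbind(x1, x2, sample(0:4, 500, TRUE)),
                        labels = c("lean", "leaky", "other"))
  rep <- screen_items(rm)
  expect_equal(rep$excluded$label, "leaky")
})

test_that("Cronbach's alpha matches its closed form and limiting cases", {
  # frozen oracle: alpha of a fixed 6x3 matrix from the variance identity
  X <- matrix(c(0, 1, 2, 3, 4, 2, 1, 1, 2, 4, 3, 2, 0, 2, 3, 3, 4, 1), 6, 3)
  rm <- response_matrix(X, labels = c("a", "b", "c"))
  expect_equal(cronbach_alpha(rm), 0.918224299065421, tolerance = 1e-12)
  # parallel duplicate items -> alpha exactly 1
  dup <- response_matrix(cbind(X[, 1], X[, 1]), labels = c("a", "b"))
  expect_equal(cronbach_alpha(dup), 1)
  # many independent items -> alpha near 0
  set.seed(11)
  ind <- response_matrix(replicate(10, sample(0:4, 3000, replace = TRUE)),
                         labels = paste0("I", 1:10))
  expect_lt(abs(cronbach_alpha(ind)), 0.1)
  # zero-variance total
  cst <- response_matrix(matrix(1L, 4, 2), labels = c("a", "b"))
  expect_warning(a0 <- cronbach_alpha(cst), "zero")
  expect_true(is.na(a0))
})

test_that("pairwise alpha agrees with complete-case alpha on complete data", {
  co <- fx_cohort()
  expect_equal(cronbach_alpha(co$responses, "complete"),
               cronbach_alpha(co$responses, "pairwise"), tolerance = 1e-10)
})

test_that("empty categories collapse into their lower neighbour before calibration", {
  x <- matrix(c(0L, 0L, 2L, 2L, 4L, 4L,   # categories 1 and 3 unobserved
                0L, 1L, 2L, 3L, 4L, 0L), 6, 2)
  rm <- response_matrix(x, labels = c("gappy", "full"))
  cl <- collapse_empty_categories(rm)
  expect_equal(unname(cl$map$gappy), c(0L, 0L, 1L, 1L, 2L))
  expect_equal(unname(cl$map$full), 0:4)
  expect_equal(cl$n_items_collapsed, 1)
  expect_equal(n_categories(cl$responses), c(3L, 5L))
  expect_identical(observed(cl$responses)[, 2], observed(rm)[, 2])
  # calibration accepts the collapsed matrix
  set.seed(99)
  big <- matrix(c(sample(c(0L, 2L, 4L), 300, TRUE), sample(0:4, 300, TRUE)), 300, 2)
  rm2 <- response_matrix(big, labels = c("gappy", "full"))
  expect_error(calibrate(rm2), "category")
  expect_s3_class(calibrate(collapse_empty_categories(rm2)$responses), "calibration")
})
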