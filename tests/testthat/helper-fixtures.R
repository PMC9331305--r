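# Shared fixtures, built once per test run.

# small ground-truth bank with the published parameter ranges
fx_bank <- function(n_items = 8L, seed = 101L)
  generate_bank(n_items, seed = seed)

# moderate cohort used by several suites (complete responses)
fx_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(fx_bank(), cohort_spec(n_persons = 600, seed = 202L))
    cache
  }
})

# a quick GPCM fit on the shared cohort
fx_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate(fx_cohort()$responses, "GPCM")
    cache
  }
})

# draw GPCM responses for one item at given trait values (test-side sampler,
# independent of the package generator)
draw_item <- function(theta, a, b) {
  p <- category_probs(theta, a, b)
  cp <- t(apply(p, 1L, cumsum))
  as.integer(rowSums(stats::runif(length(theta)) > cp))
}

# population correlation matrix implied by orthogonal-factor loadings
pop_corr <- function(L) {
  R <- tcrossprod(L)
  diag(R) <- 1
  R
}
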