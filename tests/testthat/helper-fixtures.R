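# Shared fixtures, built in code. Pools and cohorts are cached per session
# so several test files can reuse the same medium-sized objects.

tiny_patch <- function(value = 0, dim = 10L, spacing = 1,
                       mask = matrix(TRUE, dim, dim), ...) {
  image_patch(matrix(value, dim, dim), mask, spacing, ...)
}

local({
  cache <- new.env(parent = emptyenv())
  assign("fixture_cache", cache, envir = topenv())
})

fixture_pool <- function() {
  if (is.null(fixture_cache$pool))
    fixture_cache$pool <- generate_synthetic_pool(
      n_patches = 600L, seed = 424L)
  fixture_cache$pool
}

fixture_cohort <- function() {
  if (is.null(fixture_cache$cohort))
    fixture_cache$cohort <- sample_cohort(400L, scm_params(), seed = 77L)
  fixture_cache$cohort
}

# a very small matched setup for fast training-path tests
fixture_matched <- function() {
  if (is.null(fixture_cache$matched)) {
    pool <- fixture_pool()
    co_tr <- sample_cohort(120L, scm_params(), seed = 91L)
    co_va <- sample_cohort(60L, scm_params(), seed = 92L)
    fixture_cache$matched <- list(
      pool = pool,
      train = match_images(co_tr, pool, "train"),
      val = match_images(co_va, pool, "validation"))
  }
  fixture_cache$matched
}
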