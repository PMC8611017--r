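#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats dbinom rbinom rpois runif median setNames binom.test
#'   pbinom kmeans rgeom quantile
#' @importFrom utils head tail
NULL

# run `code` under a local RNG state seeded with `seed`
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# derive a child seed from a master seed; keeps results < 2^31
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "mrclone_error")
}

assert_count <- function(x, name, min = 1) {
  assert_that(
    is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min && x == floor(x),
    sprintf("`%s` must be a single integer >= %d", name, min)
  )
}

assert_prob <- function(x, name) {
  assert_that(
    is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1,
    sprintf("`%s` must be a single value in [0, 1]", name)
  )
}
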