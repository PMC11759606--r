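#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rbeta rnorm runif rexp rpois plogis quantile cor
#'   sd predict glm binomial pchisq
#' @importFrom utils read.csv write.csv
NULL

# Derive a per-stage seed from one root seed so stages can be re-run in
# isolation yet the whole pipeline flows from a single integer.
stage_seed <- function(root_seed, stage) {
  offsets <- c(
    synth = 101L, split = 211L, tiling = 223L, train = 307L,
    fusion = 331L, metastasis = 401L, survival = 503L, report = 601L
  )
  if (!stage %in% names(offsets)) {
    stop("unknown pipeline stage: ", stage)
  }
  as.integer((as.numeric(root_seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Population (divide-by-n) standard deviation; used wherever a pinned
# numeric contract depends on it (Z-scoring, Reinhard statistics).
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
  invisible(TRUE)
}
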