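#' @importFrom rlang %||% abort warn
#' @importFrom stats var sd cor rnorm runif setNames complete.cases
#' @importFrom utils head tail
NULL

# flatten k x 3 configuration row-wise -> (x1,y1,z1,x2,...)
flatten_config <- function(x) as.vector(t(x))

unflatten_config <- function(v, ndim = 3L) {
  matrix(v, ncol = ndim, byrow = TRUE)
}

# deterministic substream seeds; stage ids are fixed small integers so the
# same base seed gives decoupled, reproducible streams per pipeline stage
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((as.double(seed) %% 1e6) * 1021 + stage) %% .Machine$integer.max
}

stage_ids <- c(
  simulate = 11L, expectation = 23L, disparity = 37L, rates_groups = 41L,
  rates_regions = 43L, allometry = 53L, correlations = 59L
)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

perm_pvalue <- function(null_stats, observed) {
  (sum(null_stats >= observed) + 1) / (length(null_stats) + 1)
}
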