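# Internal helpers: classed error conditions, rounding, rescaling.

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("skr_input_error", "skr_error", "error")))
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("skr_config_error", "skr_error", "error")))
}

stop_numeric <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("skr_numeric_error", "skr_error", "error")))
}

#' Round half away from zero
#'
#' Base [round()] rounds half to even; reported tables use conventional
#' half-up rounding, so reporting code goes through this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Min-max rescale to [0, 1]; constant vectors map to all zeros.
rescale01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] < .Machine$double.eps * max(1, abs(rng[2]))) {
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# Population (divide-by-N) standard deviation, one variance convention
# throughout the package.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Stratified fold assignment: every class is spread across folds as evenly
# as possible. Returns an integer vector of fold ids in 1..k.
stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  folds <- integer(length(y))
  rs <- local_rng(seed)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[rs$sample_int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Small self-contained RNG wrapper: evaluates seeded draws without touching
# the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    if (!is.null(env$state)) {
      assign(".Random.seed", env$state, envir = globalenv())
    } else {
      set.seed(seed)
    }
    res <- expr_fun()
    env$state <- get(".Random.seed", globalenv())
    res
  }
  list(
    sample_int = function(n, size = n) run(function() sample.int(n, size)),
    rnorm = function(n, mean = 0, sd = 1) run(function() stats::rnorm(n, mean, sd)),
    runif = function(n, min = 0, max = 1) run(function() stats::runif(n, min, max))
  )
}

# Derive a distinct 32-bit sub-seed from a base seed and a stage label.
sub_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000000L) * 1009L %% 2147480000L + h %% 104729L
}
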