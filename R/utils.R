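# internal helpers shared across modules

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so simulators never perturb
#' the global RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Lognormal multiplicative noise with unit mean
#'
#' Parameterized by the coefficient of variation; cv = 0 returns exactly 1 so
#' the noiseless limit is bit-exact, not merely approximate.
#' @noRd
rlnorm_unit <- function(n, cv) {
  if (cv < 0) stop("coefficient of variation must be >= 0", call. = FALSE)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Deterministic per-stage substreams: adding a stage never perturbs the draws
# of earlier stages because each stage reseeds from its own offset.
.stage_offsets <- c(
  plate = 101L, blots = 211L, surface = 307L, msa = 401L,
  images = 503L, treatments = 601L, fixtures = 701L
)

#' @noRd
stage_seed <- function(seed, stage) {
  off <- .stage_offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

#' @noRd
is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= min
}

#' @noRd
is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x < 1
}

#' Sample mean and SD with the n-1 denominator
#'
#' Replicate summary used throughout reporting (mean +/- 1 SD of independent
#' experiments).
#'
#' @param values numeric vector of per-experiment values (n >= 2).
#' @return list with `mean`, `sd` (sample SD) and `n`.
#' @examples
#' aggregate_replicates(c(66, 92, 79, 83))
#' @export
aggregate_replicates <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("replicate values must not contain NA", call. = FALSE)
  n <- length(values)
  if (n < 2L) {
    stop("insufficient replicates: need at least 2 independent experiments",
         call. = FALSE)
  }
  list(mean = mean(values), sd = stats::sd(values), n = n)
}
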