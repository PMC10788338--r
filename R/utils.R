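#' Round half away from zero
#'
#' Rounds to a fixed number of decimals with ties going up (half-up), the
#' convention used when reproducing printed percentage tables. Base [round()]
#' rounds half to even, which disagrees with printed clinical tables on exact
#' halves such as 27.85.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage rate from counts
#'
#' @param numerator,denominator nonnegative counts.
#' @param digits decimals kept (default one, matching printed rate tables).
#' @return `100 * numerator / denominator`, rounded half-up; `NA` when the
#'   denominator is zero.
#' @export
rate_pct <- function(numerator, denominator, digits = 1) {
  out <- ifelse(denominator > 0, 100 * numerator / denominator, NA_real_)
  round_half_up(out, digits)
}

# Derive a per-stage / per-replicate seed from a base seed.  Stage offsets are
# multiples of 1000 so replicate seeds (consecutive integers) never collide
# with another stage's block.  Kept below 2^31 - 1.
derive_seed <- function(base_seed, stage, index = 0L) {
  (as.integer(base_seed) %% 1000000L) + 1000L * as.integer(stage) +
    as.integer(index)
}

# logit and inverse logit without clamping (callers control the range)
logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a binary indicator matrix; returns it as a numeric matrix.
check_binary_matrix <- function(x, arg = "x") {
  x <- as.matrix(x)
  if (anyNA(x))
    stop(sprintf("`%s` contains missing values; the latent class model does not support missing indicators -- resolve them during cohort construction", arg))
  if (!all(x %in% c(0, 1)))
    stop(sprintf("`%s` must contain only 0/1 entries", arg))
  storage.mode(x) <- "double"
  x
}
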