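#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves going up (0.005 -> 0.01),
#' the convention used in clinical metric tables, unlike [base::round()]'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is restored afterwards so seeded generators are isolated.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-item seed from a master seed; stays below 2^31 - 1.
derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 10007 + 7919 * as.numeric(index)) %% 2147483647)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_dim <- function(msg) stop(msg, call. = FALSE)

check_matrix <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_dim(sprintf("%s must be a numeric matrix", what))
  if (any(!is.finite(x))) stop_dim(sprintf("%s contains non-finite values", what))
  invisible(x)
}
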