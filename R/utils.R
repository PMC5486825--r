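# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded generation
#' (phantom cases, reader masks, labels) never perturbs the global stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a stable per-case / per-reader seed from a master seed
#'
#' Mixing is a simple multiplicative congruence kept below 2^31 - 1 so the
#' result is always a valid R integer seed. The derivation depends only on
#' (master_seed, index), so case k is reproducible regardless of how many
#' cases are generated around it.
#' @noRd
derive_seed <- function(master_seed, index) {
  m <- 2147483629
  s <- (as.numeric(master_seed) %% m)
  as.integer((s * 48271 + as.numeric(index) * 9973) %% m + 1)
}

#' Dice overlap between two logical masks
#' @param a,b logical arrays of identical shape.
#' @return Dice coefficient in [0, 1]; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

# stop() with a consistent prefix for user input problems
input_error <- function(...) stop(..., call. = FALSE)
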