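## Internal helpers: deterministic seed derivation and RNG hygiene.

.seed_mod <- 2147483647  # 2^31 - 1; keeps every derived seed a valid R integer

## Named RNG streams so stimulus synthesis, reference choices and observer
## choices are reproducible in isolation.
.stream <- c(stimuli = 1, reference = 2, observer = 3, fixture = 4, grid = 5)

#' Derive a reproducible sub-seed
#'
#' Hashes `(seed, stream, index)` into a positive 32-bit integer with a
#' Lehmer-style multiplicative step. Used to give every trial, reference
#' simulation and observer run its own deterministic RNG seed, so that e.g.
#' trial `t` of a 10-trial stimulus set equals trial `t` of a 1000-trial set
#' built from the same master seed (prefix stability).
#'
#' @param seed master seed (single finite number).
#' @param stream small integer separating independent consumers.
#' @param index vector of indices (e.g. trial numbers); vectorised.
#' @return integer vector of seeds in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, stream, index = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- abs(seed) %% .seed_mod
  h <- (s * 48271 + stream) %% .seed_mod
  h <- (h * 48271 + index) %% .seed_mod
  as.integer(h %% (.seed_mod - 1) + 1)
}

## Set the RNG seed for the calling function's lifetime, restoring the caller's
## RNG state afterwards; a NULL seed leaves the global RNG stream untouched.
local_seed <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(seed, .local_envir = envir)
  invisible(seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
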