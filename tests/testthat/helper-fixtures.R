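# Shared fixtures: everything is generated in code at test time.

# Small basis/stimulus sets reused across files (built once per test run).
tiny_basis <- function() {
  if (is.null(.fixture_env$basis64)) .fixture_env$basis64 <- noise_basis(64)
  .fixture_env$basis64
}

tiny_stimuli <- function(n_trials = 30, master_seed = 7) {
  key <- paste0("stim_", n_trials, "_", master_seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- stimulus_set(n_trials, tiny_basis(), master_seed)
  }
  .fixture_env[[key]]
}

.fixture_env <- new.env(parent = emptyenv())

# Brute-force oracle: count sinusoid layers by enumerating the patch grids.
enumerate_layers <- function(n_levels = 5, n_orientations = 6, n_phases = 2) {
  n <- 0
  for (k in seq_len(n_levels) - 1) {
    m <- 2^k
    for (pr in seq_len(m)) for (pc in seq_len(m)) {
      n <- n + n_orientations * n_phases
    }
  }
  n
}

# Brute-force MAD: median of absolute deviations from the median.
brute_mad <- function(x) {
  med <- sort(x)[ceiling(length(x) / 2)]
  if (length(x) %% 2 == 0) {
    s <- sort(x)
    med <- (s[length(x) / 2] + s[length(x) / 2 + 1]) / 2
  }
  dev <- sort(abs(x - med))
  if (length(dev) %% 2 == 1) dev[ceiling(length(dev) / 2)]
  else (dev[length(dev) / 2] + dev[length(dev) / 2 + 1]) / 2
}

# Toy stimulus sets with hand-specified 4-pixel patterns, bypassing the
# sinusoid model, for arithmetic oracles.
toy_stimuli <- function(patterns) {
  # patterns: list of equal-length numeric vectors (perfect squares)
  P <- do.call(cbind, lapply(patterns, as.numeric))
  res <- as.integer(sqrt(nrow(P)))
  stopifnot(res^2 == nrow(P))
  basis <- list(resolution = res, n_levels = 1L, n_layers = nrow(P))
  class(basis) <- "noise_basis"
  x <- infoval:::new_stimulus_set(basis, seeds = seq_len(ncol(P)),
                                  master_seed = 0, patterns = P)
  x
}
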