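## Sinusoid stimulus-noise model for 2IFC reverse correlation.
##
## A noise pattern is a weighted sum of 4092 sinusoid layers: the image is
## partitioned at 5 patch-grid levels (4^0 .. 4^4 equal square patches); every
## patch carries 12 sinusoid variants (6 orientations x 2 phases, 2 cycles per
## patch side); each layer has an independent contrast weight drawn uniformly
## from [-1, 1]. The pattern is the sum of all layers divided by the number of
## levels. The two stimuli of a 2IFC trial are a pattern and its negative.

#' Construct a sinusoid noise basis
#'
#' Defines the fixed geometry of the stimulus noise: patch grids, sinusoid
#' orientations, phases and cycles per patch. With the default parameters the
#' basis has \eqn{(1+4+16+64+256) \times 6 \times 2 = 4092} layers, one
#' contrast weight each.
#'
#' @param resolution image side length in pixels; must be divisible by the
#'   deepest patch grid (16) and large enough that the smallest patches can
#'   carry the sinusoid (at least 2 pixels per cycle, i.e. `resolution >= 64`
#'   with the defaults).
#' @param n_levels number of patch-grid levels; level `k` (0-based) partitions
#'   the image into `4^k` equal square patches.
#' @param orientations sinusoid orientations in degrees.
#' @param phases phase offsets in radians.
#' @param cycles sinusoid cycles spanning one patch side.
#' @return an object of class `noise_basis`.
#' @examples
#' b <- noise_basis(64)
#' b$n_layers  # 4092
#' @export
noise_basis <- function(resolution, n_levels = 5L,
                        orientations = c(0, 30, 60, 90, 120, 150),
                        phases = c(0, pi / 2), cycles = 2) {
  if (length(resolution) != 1L || !is.finite(resolution) ||
      resolution != round(resolution)) {
    stop("`resolution` must be a single whole number of pixels")
  }
  resolution <- as.integer(resolution)
  n_levels <- as.integer(n_levels)
  m_max <- as.integer(2^(n_levels - 1L))
  if (resolution < m_max || resolution %% m_max != 0L) {
    stop(sprintf(
      "resolution %d is not divisible by %d, the deepest patch grid (%d x %d patches)",
      resolution, m_max, m_max, m_max))
  }
  s_min <- resolution %/% m_max
  if (s_min < 2 * cycles) {
    stop(sprintf(paste0(
      "resolution %d gives deepest-level patches of %d x %d pixels, smaller than ",
      "the %g sinusoid cycles they must carry (need >= %g pixels per patch side)"),
      resolution, s_min, s_min, cycles, 2 * cycles))
  }
  n_var <- length(orientations) * length(phases)
  levels <- vector("list", n_levels)
  offset <- 0L
  for (k in seq_len(n_levels) - 1L) {
    m <- as.integer(2^k)
    s <- resolution %/% m
    idx <- vector("list", m * m)
    p <- 0L
    for (pr in 0:(m - 1L)) {
      for (pc in 0:(m - 1L)) {
        p <- p + 1L
        ## pixel indices of patch (pr, pc), local order column-major
        ## (row fastest) to match the template rows
        idx[[p]] <- as.vector(outer(pr * s + seq_len(s),
                                    (pc * s + seq_len(s) - 1L) * resolution, "+"))
      }
    }
    levels[[k + 1L]] <- list(
      k = k, m = m, patch_side = s, n_patches = m * m,
      template = sinusoid_templates(s, orientations, phases, cycles),
      patch_pixels = idx,
      weight_offset = offset)
    offset <- offset + m * m * n_var
  }
  structure(
    list(resolution = resolution, n_levels = n_levels,
         orientations = orientations, phases = phases, cycles = cycles,
         n_variants = n_var, n_layers = offset, levels = levels),
    class = "noise_basis")
}

## One patch worth of sinusoid layers: an s^2 x (orientations x phases) matrix.
## Pixel centers sit at integer coordinates (r, c) in 0..s-1 measured from the
## patch's top-left corner; phase is measured from that corner. The cycles
## span the patch inclusive of both edge pixel centers (grid spacing
## 1/(s - 1), as in the reference noise generator's meshgrid). The inclusive
## grid matters: with spacing 1/s every layer would sum to *exactly* zero
## over its patch (at these orientations one factor of the separable
## geometric sum always completes full periods), leaving a mean-brightness
## observer with no signal at all; with the inclusive grid patch sums are
## genuinely nonzero, of order 1/s.
sinusoid_templates <- function(s, orientations, phases, cycles) {
  rr <- rep(0:(s - 1L), times = s)
  cc <- rep(0:(s - 1L), each = s)
  out <- matrix(0, s * s, length(orientations) * length(phases))
  v <- 0L
  for (o in orientations) {
    th <- o * pi / 180
    proj <- cc * cos(th) + rr * sin(th)
    for (ph in phases) {
      v <- v + 1L
      out[, v] <- sin(2 * pi * cycles * proj / (s - 1) + ph)
    }
  }
  out
}

#' @export
print.noise_basis <- function(x, ...) {
  cat(sprintf("Sinusoid noise basis: %d x %d pixels\n", x$resolution, x$resolution))
  cat(sprintf("  %d patch-grid levels (patch sides: %s)\n", x$n_levels,
              paste(vapply(x$levels, function(l) l$patch_side, integer(1)),
                    collapse = ", ")))
  cat(sprintf("  %d orientations x %d phases, %g cycles per patch\n",
              length(x$orientations), length(x$phases), x$cycles))
  cat(sprintf("  %d layers (contrast weights)\n", x$n_layers))
  invisible(x)
}

#' Draw a random contrast-weight vector
#'
#' One independent uniform `[-1, 1]` draw per sinusoid layer, from the current
#' RNG state (seed beforehand with [set.seed()] for reproducibility).
#'
#' @param basis a [noise_basis()].
#' @return numeric vector of length `basis$n_layers`.
#' @export
sample_weights <- function(basis) {
  stopifnot(inherits(basis, "noise_basis"))
  stats::runif(basis$n_layers, -1, 1)
}

#' Synthesize a noise pattern from contrast weights
#'
#' The pattern is the sum over all patch-restricted sinusoid layers, each
#' multiplied by its weight, divided by the number of patch-grid levels.
#' Synthesis is linear in the weights: `synthesize(b, a * w)` equals
#' `a * synthesize(b, w)`.
#'
#' @param basis a [noise_basis()].
#' @param weights numeric vector of length `basis$n_layers`, ordered
#'   level-major, then patch (row-major grid), then orientation, then phase.
#' @return a `resolution x resolution` numeric matrix of class `noise_pattern`.
#' @export
synthesize <- function(basis, weights) {
  stopifnot(inherits(basis, "noise_basis"))
  if (length(weights) != basis$n_layers) {
    stop(sprintf("weight count %d does not match basis layer count %d",
                 length(weights), basis$n_layers))
  }
  v <- synthesize_matrix(basis, matrix(as.numeric(weights), ncol = 1L))
  structure(matrix(v, basis$resolution, basis$resolution),
            class = c("noise_pattern", "matrix"))
}

#' Invert a noise pattern
#'
#' The second stimulus of a 2IFC trial: the exact pixel-wise negative.
#'
#' @param pattern a noise pattern (numeric matrix).
#' @return the negated pattern.
#' @export
invert <- function(pattern) -pattern

## Batch synthesis: W is n_layers x T; returns the I x T pattern matrix.
## Works patch-by-patch so every level contributes one dense GEMM per patch,
## which keeps full-scale synthesis (512 x 512, T = 1000) to a few seconds.
## Columns are processed in chunks to bound transient memory.
synthesize_matrix <- function(basis, W, chunk = NULL) {
  I <- basis$resolution^2
  nT <- ncol(W)
  if (nrow(W) != basis$n_layers) {
    stop(sprintf("weight count %d does not match basis layer count %d",
                 nrow(W), basis$n_layers))
  }
  if (is.null(chunk)) chunk <- max(1L, min(nT, as.integer(2^25 %/% I)))
  out <- matrix(0, I, nT)
  start <- 1L
  nv <- basis$n_variants
  while (start <= nT) {
    J <- start:min(nT, start + chunk - 1L)
    acc <- matrix(0, I, length(J))
    for (lev in basis$levels) {
      tm <- lev$template
      for (p in seq_len(lev$n_patches)) {
        rows <- lev$weight_offset + (p - 1L) * nv + seq_len(nv)
        blk <- tm %*% W[rows, J, drop = FALSE]
        if (lev$n_patches == 1L) {
          acc <- acc + blk
        } else {
          ii <- lev$patch_pixels[[p]]
          acc[ii, ] <- acc[ii, ] + blk
        }
      }
    }
    out[, J] <- acc / basis$n_levels
    start <- start + length(J)
  }
  out
}

## Weight matrix (n_layers x T) regenerated from per-trial seeds.
trial_weight_matrix <- function(basis, seeds) {
  W <- matrix(0, basis$n_layers, length(seeds))
  for (t in seq_along(seeds)) {
    withr::with_seed(seeds[t], W[, t] <- stats::runif(basis$n_layers, -1, 1))
  }
  W
}

#' Generate a 2IFC stimulus set
#'
#' Generates `n_trials` noise patterns, one per trial; trial `t` presents
#' pattern `t` and its inverse. Each trial's weights are drawn from a per-trial
#' seed derived deterministically from `master_seed`, so the set is bit-exact
#' reproducible and prefix-stable: the first `n` trials of a longer set equal
#' an `n`-trial set built from the same master seed (the property the
#' cumulative-trials analysis relies on).
#'
#' @param n_trials number of trials (>= 1).
#' @param basis a [noise_basis()].
#' @param master_seed seed from which all per-trial seeds are derived.
#' @param keep_patterns keep the realized `I x n_trials` pattern matrix in the
#'   returned object (default). With `FALSE` the patterns are regenerated on
#'   demand, trading time for memory.
#' @return an object of class `stimulus_set`.
#' @export
stimulus_set <- function(n_trials, basis, master_seed, keep_patterns = TRUE) {
  stopifnot(inherits(basis, "noise_basis"))
  if (length(n_trials) != 1L || !is.finite(n_trials) || n_trials < 1) {
    stop("`n_trials` must be a single number >= 1")
  }
  n_trials <- as.integer(n_trials)
  seeds <- derive_seed(master_seed, .stream[["stimuli"]], seq_len(n_trials))
  patterns <- NULL
  if (keep_patterns) {
    patterns <- synthesize_matrix(basis, trial_weight_matrix(basis, seeds))
  }
  new_stimulus_set(basis, seeds, master_seed, patterns)
}

new_stimulus_set <- function(basis, seeds, master_seed, patterns = NULL) {
  structure(
    list(basis = basis, n_trials = length(seeds), master_seed = master_seed,
         trial_seeds = seeds, patterns = patterns,
         cache = new.env(parent = emptyenv())),
    class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("2IFC stimulus set: %d trials, %d x %d pixels (master seed %s)\n",
              x$n_trials, x$basis$resolution, x$basis$resolution,
              format(x$master_seed)))
  cat(sprintf("  patterns %s in memory; Gram matrix %s\n",
              if (is.null(x$patterns)) "not held" else "held",
              if (is.null(x$cache$gram)) "not cached" else "cached"))
  invisible(x)
}

#' Pattern matrix of a stimulus set
#'
#' The `I x n_trials` matrix of realized noise patterns (pixels in column-major
#' image order), regenerated from the per-trial seeds if the set was built or
#' compacted without them.
#'
#' @param x a `stimulus_set`.
#' @return numeric matrix.
#' @export
stimulus_patterns <- function(x) {
  stopifnot(inherits(x, "stimulus_set"))
  if (!is.null(x$patterns)) return(x$patterns)
  synthesize_matrix(x$basis, trial_weight_matrix(x$basis, x$trial_seeds))
}

#' Extract one trial's noise pattern
#' @param x a `stimulus_set`.
#' @param t trial index.
#' @return a `noise_pattern` matrix.
#' @export
get_pattern <- function(x, t) {
  stopifnot(inherits(x, "stimulus_set"), t >= 1, t <= x$n_trials)
  if (!is.null(x$patterns)) {
    v <- x$patterns[, t]
  } else {
    v <- synthesize_matrix(
      x$basis, trial_weight_matrix(x$basis, x$trial_seeds[t]))[, 1L]
  }
  structure(matrix(v, x$basis$resolution, x$basis$resolution),
            class = c("noise_pattern", "matrix"))
}

#' Drop the realized patterns from a stimulus set
#'
#' Frees the pattern matrix while keeping the seeds and any cached Gram matrix
#' or region means; patterns are regenerated from the seeds when next needed.
#'
#' @param x a `stimulus_set`.
#' @return the compacted `stimulus_set`.
#' @export
drop_patterns <- function(x) {
  stopifnot(inherits(x, "stimulus_set"))
  x$patterns <- NULL
  x
}

#' Subset trials of a stimulus set
#'
#' Keeps the indexed trials (typically a prefix `1:n` for cumulative-trials
#' analyses). Cached Gram matrices and region means are subset accordingly.
#'
#' @param x a `stimulus_set`.
#' @param i trial indices.
#' @param ... ignored.
#' @export
`[.stimulus_set` <- function(x, i, ...) {
  i <- seq_len(x$n_trials)[i]
  if (anyNA(i) || length(i) < 1L) stop("trial indices out of range")
  out <- new_stimulus_set(x$basis, x$trial_seeds[i], x$master_seed,
                          if (!is.null(x$patterns)) x$patterns[, i, drop = FALSE])
  if (!is.null(x$cache$gram)) out$cache$gram <- x$cache$gram[i, i, drop = FALSE]
  if (!is.null(x$cache$region_means)) {
    out$cache$region_means <- lapply(x$cache$region_means, function(m) m[i])
  }
  out
}

#' Gram matrix of a stimulus set
#'
#' The `T x T` matrix of pixel-space inner products between noise patterns,
#' `G[s, t] = sum_i n_s[i] n_t[i]`. Because a classification image is a signed
#' average of patterns, its squared vector length is the quadratic form
#' `c' G c / T^2`, so once `G` is computed every simulated vector length costs
#' `O(T^2)` instead of `O(T I)`. The result is cached on the set.
#'
#' @param x a `stimulus_set`.
#' @return symmetric positive semi-definite numeric matrix.
#' @export
gram_matrix <- function(x) {
  stopifnot(inherits(x, "stimulus_set"))
  if (is.null(x$cache$gram)) x$cache$gram <- crossprod(stimulus_patterns(x))
  x$cache$gram
}

## Vector lengths of the CIs produced by the +-1 choice columns of C,
## via the Gram quadratic form: |P c| / T = sqrt(c' G c) / T.
lengths_from_gram <- function(G, C) {
  S <- G %*% C
  sqrt(pmax(colSums(C * S), 0)) / nrow(C)
}

## Naive path kept for oracle testing: explicit pattern averages.
lengths_naive <- function(P, C) {
  M <- P %*% C
  sqrt(colSums(M^2)) / nrow(C)
}

#' Resolve a signal-mask specification to pixel indices
#'
#' Masks describe the image region an observer's brightness judgment uses.
#' Accepted forms: `"full"`; `"centerN"` (centered `N x N` square, e.g.
#' `"center256"`, `"center32"`); a single number (centered square side); or
#' `c(r1, r2, c1, c2)` (1-based inclusive rectangle).
#'
#' @param mask mask specification.
#' @param resolution image side length in pixels.
#' @return integer vector of column-major pixel indices.
#' @export
resolve_mask <- function(mask, resolution) {
  if (is.character(mask) && length(mask) == 1L) {
    if (mask == "full") {
      return(seq_len(resolution^2))
    }
    if (grepl("^center[0-9]+$", mask)) {
      mask <- as.numeric(sub("^center", "", mask))
    } else {
      stop(sprintf("unknown mask specification '%s'", mask))
    }
  }
  mask <- as.numeric(mask)
  if (length(mask) == 1L) {
    side <- as.integer(mask)
    if (side < 1L || side > resolution) {
      stop(sprintf("mask side %d outside image of %d pixels", side, resolution))
    }
    o <- (resolution - side) %/% 2L
    mask <- c(o + 1L, o + side, o + 1L, o + side)
  }
  if (length(mask) != 4L) stop("mask must be 'full', 'centerN', a side length, or c(r1, r2, c1, c2)")
  r <- as.integer(mask[1:2]); cl <- as.integer(mask[3:4])
  if (r[1] < 1L || r[2] > resolution || cl[1] < 1L || cl[2] > resolution ||
      r[1] > r[2] || cl[1] > cl[2]) {
    stop("mask rectangle is empty or outside the image bounds")
  }
  as.integer(outer(r[1]:r[2], (cl[1]:cl[2] - 1L) * as.integer(resolution), "+"))
}

mask_key <- function(mask) paste(as.character(mask), collapse = "_")

#' Per-trial mean intensity over a mask region
#'
#' For every pattern in the set, the mean pixel value over the mask region.
#' An ideal observer prefers the pair member whose region mean is positive
#' (the original pattern if the mean exceeds 0, the inverse otherwise).
#' Results are cached on the set per mask.
#'
#' @param x a `stimulus_set`.
#' @param mask a mask specification (see [resolve_mask()]).
#' @return numeric vector of length `n_trials`.
#' @export
region_means <- function(x, mask = "full") {
  stopifnot(inherits(x, "stimulus_set"))
  key <- mask_key(mask)
  if (is.null(x$cache$region_means)) x$cache$region_means <- list()
  hit <- x$cache$region_means[[key]]
  if (!is.null(hit)) return(hit)
  idx <- resolve_mask(mask, x$basis$resolution)
  P <- stimulus_patterns(x)
  m <- if (length(idx) == nrow(P)) colMeans(P) else colMeans(P[idx, , drop = FALSE])
  x$cache$region_means[[key]] <- m
  m
}
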