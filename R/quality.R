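## Data-quality metrics that accompany infoVal: objective discriminability
## ratio, pixel-wise test-retest correlation, classical MDS of CI distances,
## and cumulative-trials infoVal curves. All metrics operate on the unscaled
## mean-noise images.

ci_pixels <- function(x) {
  if (inherits(x, "classification_image")) as.numeric(x$mean_noise)
  else as.numeric(x)
}

#' Euclidean distance between two classification images
#'
#' The L2 norm of the pixel-wise difference of the (unscaled) mean-noise
#' images; smaller distance means more similar CIs.
#'
#' @param ci_a,ci_b `classification_image` objects (or numeric matrices) of
#'   equal resolution.
#' @return non-negative scalar.
#' @export
ci_distance <- function(ci_a, ci_b) {
  a <- ci_pixels(ci_a)
  b <- ci_pixels(ci_b)
  if (length(a) != length(b)) {
    stop(sprintf("classification images differ in size (%d vs %d pixels)",
                 length(a), length(b)))
  }
  sqrt(sum((a - b)^2))
}

#' Objective discriminability ratio (ODR)
#'
#' For a target CI within a labeled set, the ratio of its mean Euclidean
#' distance to CIs of the *other* category over its mean distance to the
#' *other* CIs of its own category:
#' \deqn{ODR = \bar d_{across} / \bar d_{within}.}
#' A ratio above 1 means the CI sits closer to its own category than to the
#' opposite one, i.e. the categories are objectively discriminable.
#'
#' @param cis list of `classification_image` objects (equal resolution).
#' @param labels category label per CI.
#' @param target index of the CI to score.
#' @return an object of class `odr_result` with `d_within`, `d_across`,
#'   `ratio`.
#' @export
odr <- function(cis, labels, target) {
  if (!is.list(cis) || length(cis) != length(labels)) {
    stop("`cis` must be a list with one label per classification image")
  }
  if (length(target) != 1L || target < 1 || target > length(cis)) {
    stop("`target` must index one CI in `cis`")
  }
  same <- setdiff(which(labels == labels[target]), target)
  other <- which(labels != labels[target])
  if (length(same) < 1L || length(other) < 1L) {
    stop(sprintf(paste0(
      "ODR needs at least one other same-category CI and one other-category ",
      "CI; category '%s' has %d other member(s), other categories %d"),
      labels[target], length(same), length(other)))
  }
  d_within <- mean(vapply(same, function(j) ci_distance(cis[[target]], cis[[j]]),
                          numeric(1)))
  d_across <- mean(vapply(other, function(j) ci_distance(cis[[target]], cis[[j]]),
                          numeric(1)))
  if (d_within == 0) {
    stop("d_within = 0 (target coincides with every same-category CI); ODR undefined")
  }
  structure(list(target = target, label = labels[target],
                 d_within = d_within, d_across = d_across,
                 ratio = d_across / d_within),
            class = "odr_result")
}

#' @export
print.odr_result <- function(x, ...) {
  cat(sprintf(
    "ODR for CI %d ('%s'): d_across = %.6g / d_within = %.6g = %.4f\n",
    x$target, x$label, x$d_across, x$d_within, x$ratio))
  invisible(x)
}

#' ODR for every CI in a labeled set
#'
#' @inheritParams odr
#' @return data frame with one row per CI: `target`, `label`, `d_within`,
#'   `d_across`, `ratio`.
#' @export
odr_all <- function(cis, labels) {
  do.call(rbind, lapply(seq_along(cis), function(i) {
    r <- odr(cis, labels, i)
    data.frame(target = i, label = r$label, d_within = r$d_within,
               d_across = r$d_across, ratio = r$ratio,
               stringsAsFactors = FALSE)
  }))
}

#' Pixel-wise correlation between two classification images
#'
#' Pearson correlation over pixels of the unscaled mean-noise images; the
#' test-retest reliability measure when the two CIs come from two sessions of
#' the same participant.
#'
#' @param ci_a,ci_b `classification_image` objects (or numeric matrices) of
#'   equal resolution.
#' @return correlation in `[-1, 1]`.
#' @export
pixelwise_correlation <- function(ci_a, ci_b) {
  a <- ci_pixels(ci_a)
  b <- ci_pixels(ci_b)
  if (length(a) != length(b)) {
    stop(sprintf("classification images differ in size (%d vs %d pixels)",
                 length(a), length(b)))
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("pixel-wise correlation is undefined for a constant image")
  }
  stats::cor(a, b)
}

#' Euclidean distance matrix of a set of classification images
#'
#' @param cis list of `classification_image` objects of equal resolution.
#' @return symmetric matrix of pairwise distances with zero diagonal.
#' @export
ci_distance_matrix <- function(cis) {
  n <- length(cis)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      D[i, j] <- D[j, i] <- ci_distance(cis[[i]], cis[[j]])
    }
  }
  D
}

#' Classical MDS embedding of a CI distance matrix
#'
#' Classical (metric) multidimensional scaling — the eigendecomposition of
#' the doubly centered squared-distance matrix — so that pairwise embedded
#' distances approximate the input distances. Deterministic up to rotation
#' and reflection. Used to visualise how CIs of different categories separate.
#'
#' @param distance_matrix square symmetric non-negative matrix with zero
#'   diagonal.
#' @param dims embedding dimension (default 2).
#' @return numeric matrix of coordinates, one row per CI.
#' @export
mds_embedding <- function(distance_matrix, dims = 2) {
  D <- as.matrix(distance_matrix)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (any(D < 0)) stop("distance matrix must be non-negative")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D)))) {
    stop("distance matrix must be symmetric")
  }
  stats::cmdscale(D, k = dims)
}

#' Cumulative-trials infoVal curve
#'
#' Scores the first `c` trials of a session for each checkpoint `c`, against
#' a reference distribution built on the first `c` stimuli. Because stimulus
#' sets are prefix-stable, "the first `c` stimuli" is exactly the set a
#' `c`-trial session would have used, so the curve shows how the evidence for
#' signal accumulates with task length.
#'
#' @param stimuli a [stimulus_set()].
#' @param responses `+1` / `-1` choices for the full session.
#' @param checkpoints increasing trial counts, each `<= n_trials`.
#' @param n_iter reference iterations per checkpoint.
#' @param seed optional master seed (one derived seed per checkpoint).
#' @param critical critical value for the per-checkpoint decision.
#' @return data frame with one row per checkpoint: `checkpoint`,
#'   `observed_length`, `score`, `reject`.
#' @export
cumulative_infoval <- function(stimuli, responses, checkpoints,
                               n_iter = 10000, seed = NULL, critical = 1.96) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  responses <- response_vector(responses)
  if (length(responses) != stimuli$n_trials) {
    stop(sprintf("got %d responses for a stimulus set of %d trials",
                 length(responses), stimuli$n_trials))
  }
  checkpoints <- as.integer(checkpoints)
  if (length(checkpoints) < 1L || any(checkpoints < 1L)) {
    stop("`checkpoints` must contain positive trial counts")
  }
  if (any(diff(checkpoints) <= 0)) stop("`checkpoints` must be strictly increasing")
  if (max(checkpoints) > stimuli$n_trials) {
    stop(sprintf("checkpoint %d exceeds the %d available trials",
                 max(checkpoints), stimuli$n_trials))
  }
  rows <- lapply(seq_along(checkpoints), function(ci) {
    cp <- checkpoints[ci]
    sub <- if (cp == stimuli$n_trials) stimuli else stimuli[seq_len(cp)]
    sd_i <- if (is.null(seed)) NULL else derive_seed(seed, .stream[["reference"]], ci)
    iv <- infoval(sub, responses[seq_len(cp)], n_iter = n_iter, seed = sd_i,
                  critical = critical)
    data.frame(checkpoint = cp, observed_length = iv$observed_length,
               score = iv$score, reject = iv$reject_h0)
  })
  do.call(rbind, rows)
}
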