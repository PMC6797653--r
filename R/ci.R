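## Classification images: signed averages of the selected noise patterns.

#' Validate a 2IFC response vector
#'
#' Responses are encoded `+1` (chose the original noise pattern) or `-1`
#' (chose its inverse). Because the unchosen stimulus is always the chosen
#' one's negative, this signed encoding is all the classification image needs.
#'
#' @param choices vector of `+1` / `-1` values.
#' @param response_times optional per-trial durations in ms (same length).
#' @return integer vector of `+1` / `-1`, with `response_times` attached as an
#'   attribute when given.
#' @export
response_vector <- function(choices, response_times = NULL) {
  ch <- suppressWarnings(as.numeric(choices))
  bad <- which(is.na(ch) | !(ch %in% c(-1, 1)))
  if (length(bad) > 0L) {
    stop(sprintf("responses must be +1 or -1; offending positions: %s",
                 paste(utils::head(bad, 10L), collapse = ", ")))
  }
  out <- as.integer(ch)
  if (!is.null(response_times)) {
    if (length(response_times) != length(out)) {
      stop(sprintf("got %d response times for %d choices",
                   length(response_times), length(out)))
    }
    attr(out, "response_times") <- as.numeric(response_times)
  }
  out
}

#' Compute a classification image
#'
#' Averages the selected noise patterns: pixel `i` of the CI is
#' \eqn{\bar p_i = (1/T) \sum_t c_t n_{t,i}} with choices \eqn{c_t = \pm 1},
#' since the unchosen stimulus is the chosen one's negative. The CI's vector
#' length — the Euclidean norm \eqn{x = \sqrt{\sum_i \bar p_i^2}} — grows with
#' response consistency and is the statistic the infoVal metric tests.
#'
#' @param stimuli a [stimulus_set()].
#' @param responses `+1` / `-1` choices, one per trial (see
#'   [response_vector()]).
#' @return an object of class `classification_image` with fields `mean_noise`
#'   (matrix), `vector_length` and `n_trials`.
#' @export
classification_image <- function(stimuli, responses) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  responses <- response_vector(responses)
  if (length(responses) != stimuli$n_trials) {
    stop(sprintf("got %d responses for a stimulus set of %d trials",
                 length(responses), stimuli$n_trials))
  }
  P <- stimulus_patterns(stimuli)
  mn <- as.vector(P %*% responses) / stimuli$n_trials
  res <- stimuli$basis$resolution
  new_classification_image(matrix(mn, res, res), n_trials = stimuli$n_trials)
}

new_classification_image <- function(mean_noise, n_trials = NA_integer_) {
  structure(
    list(mean_noise = mean_noise,
         vector_length = sqrt(sum(mean_noise^2)),
         n_trials = n_trials,
         resolution = nrow(mean_noise)),
    class = "classification_image")
}

#' Wrap a pixel matrix as a classification image
#'
#' Convenience constructor for CIs that come from outside the package (e.g.
#' read back from a numeric dump, or toy examples).
#'
#' @param mean_noise square numeric matrix of average noise values.
#' @param n_trials number of trials behind the average, if known.
#' @return a `classification_image`.
#' @export
as_classification_image <- function(mean_noise, n_trials = NA_integer_) {
  mean_noise <- as.matrix(mean_noise)
  if (nrow(mean_noise) != ncol(mean_noise)) {
    stop("`mean_noise` must be a square matrix")
  }
  new_classification_image(mean_noise, n_trials)
}

#' Vector length of a classification image
#'
#' The Euclidean norm over all pixels, \eqn{x = \sqrt{\sum_i \bar p_i^2}};
#' zero exactly when every pixel is zero.
#'
#' @param ci a `classification_image`, or a numeric matrix/vector of pixel
#'   values.
#' @return non-negative scalar.
#' @export
vector_length <- function(ci) {
  v <- if (inherits(ci, "classification_image")) ci$mean_noise else ci
  sqrt(sum(as.numeric(v)^2))
}

#' @export
print.classification_image <- function(x, ...) {
  cat(sprintf("Classification image: %d x %d pixels%s\n", x$resolution,
              x$resolution,
              if (is.na(x$n_trials)) "" else sprintf(" (%d trials)", x$n_trials)))
  cat(sprintf("  vector length: %.6g\n", x$vector_length))
  invisible(x)
}

#' Group-level classification image
#'
#' Pixel-wise mean of the (unscaled) individual mean-noise images; the vector
#' length is recomputed on the average.
#'
#' @param cis non-empty list of `classification_image` objects with equal
#'   resolution.
#' @return a `classification_image`.
#' @export
group_ci <- function(cis) {
  if (!is.list(cis) || length(cis) < 1L ||
      !all(vapply(cis, inherits, logical(1), "classification_image"))) {
    stop("`cis` must be a non-empty list of classification images")
  }
  res <- vapply(cis, function(ci) ci$resolution, integer(1))
  if (length(unique(res)) != 1L) {
    stop(sprintf("classification images differ in resolution: %s",
                 paste(unique(res), collapse = ", ")))
  }
  mn <- Reduce(`+`, lapply(cis, function(ci) ci$mean_noise)) / length(cis)
  out <- new_classification_image(mn)
  attr(out, "n_images") <- length(cis)
  out
}

#' Render a classification image over a base image
#'
#' Display-only: the unscaled mean noise is mapped symmetrically about zero
#' onto the base image's intensity range (autoscaling), added to the base, and
#' clipped into `[0, 255]`. All statistics in this package operate on the
#' unscaled mean noise; rendering never feeds back into any metric.
#'
#' @param ci a `classification_image`.
#' @param base numeric matrix of grayscale intensities in `[0, 255]`, same
#'   resolution as the CI.
#' @return numeric matrix in `[0, 255]`.
#' @export
render_ci <- function(ci, base) {
  stopifnot(inherits(ci, "classification_image"))
  base <- as.matrix(base)
  if (!all(dim(base) == dim(ci$mean_noise))) {
    stop(sprintf("base image is %d x %d but the CI is %d x %d",
                 nrow(base), ncol(base), nrow(ci$mean_noise), ncol(ci$mean_noise)))
  }
  amp <- max(abs(ci$mean_noise))
  if (amp == 0) return(base)
  scale <- (max(base) - min(base)) / 2 / amp
  pmin(pmax(base + ci$mean_noise * scale, 0), 255)
}
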