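## The infoVal metric: a modified z-score relating an observed CI vector
## length to a Monte-Carlo reference distribution of vector lengths obtained
## by fully random responding on the identical stimulus set.

#' Scaled median absolute deviation
#'
#' `k * median(|x - median(x)|)`. With the standard `k = 1.4826` the result
#' approximates the standard deviation for distributions close to normal,
#' which is what makes the modified z-score comparable to an ordinary z-score
#' while staying robust to the slight skew of the reference distribution.
#'
#' @param x numeric vector (non-empty).
#' @param k scaling constant; `k = 1` gives the raw MAD.
#' @return non-negative scalar.
#' @export
scaled_mad <- function(x, k = 1.4826) {
  if (length(x) < 1L) stop("`x` must contain at least one value")
  stats::mad(x, constant = k)
}

#' Simulate the reference distribution of vector lengths
#'
#' Simulates a participant who picks one of the two stimuli at random
#' (probability .5) on every trial of the *same* stimulus set, records the
#' resulting CI's vector length, and repeats `n_iter` times. The distribution
#' is summarised by its median and by `sigma_sim = 1.4826 * MAD`, the robust
#' spread estimate the infoVal score divides by.
#'
#' By default lengths are computed through the Gram quadratic form
#' (see [gram_matrix()]); `method = "naive"` averages explicit patterns and is
#' retained as an independent check of the fast path.
#'
#' @param stimuli a [stimulus_set()].
#' @param n_iter number of simulated random responders (>= 2; default 10000).
#'   Below 2000 the Monte-Carlo error of the median and MAD becomes
#'   non-negligible and a warning is issued.
#' @param seed optional seed; when given, the caller's RNG state is left
#'   untouched.
#' @param method `"gram"` (default) or `"naive"`.
#' @param chunk iterations per internal block.
#' @return an object of class `infoval_reference` with fields `lengths`,
#'   `median_length`, `mad`, `sigma_sim`, `k`, `n_iter`.
#' @export
infoval_reference <- function(stimuli, n_iter = 10000, seed = NULL,
                              method = c("gram", "naive"), chunk = 2000L) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  method <- match.arg(method)
  if (length(n_iter) != 1L || !is.finite(n_iter) || n_iter < 2) {
    stop("`n_iter` must be at least 2 to define a spread")
  }
  n_iter <- as.integer(n_iter)
  if (n_iter < 2000L) {
    warning(sprintf(paste0(
      "n_iter = %d gives a noticeably noisy reference distribution; ",
      "10000 iterations are recommended"), n_iter))
  }
  local_seed(seed)
  T <- stimuli$n_trials
  src <- if (method == "gram") gram_matrix(stimuli) else stimulus_patterns(stimuli)
  lens <- numeric(n_iter)
  done <- 0L
  while (done < n_iter) {
    m <- min(chunk, n_iter - done)
    C <- matrix(sample(c(-1, 1), T * m, replace = TRUE), nrow = T)
    lens[done + seq_len(m)] <- if (method == "gram") {
      lengths_from_gram(src, C)
    } else {
      lengths_naive(src, C)
    }
    done <- done + m
  }
  k <- 1.4826
  mad0 <- scaled_mad(lens, k = 1)
  structure(
    list(lengths = lens,
         median_length = stats::median(lens),
         mad = mad0,
         sigma_sim = k * mad0,
         k = k,
         n_iter = n_iter,
         n_trials = T,
         method = method,
         seed = seed,
         master_seed = stimuli$master_seed),
    class = "infoval_reference")
}

#' @export
print.infoval_reference <- function(x, ...) {
  cat(sprintf("Reference distribution of CI vector lengths under random responding\n"))
  cat(sprintf("  %d iterations on a %d-trial stimulus set (%s path)\n",
              x$n_iter, x$n_trials, x$method))
  cat(sprintf("  median = %.6g, MAD = %.6g, sigma_sim = k * MAD = %.6g (k = %.4f)\n",
              x$median_length, x$mad, x$sigma_sim, x$k))
  invisible(x)
}

#' Score an observed vector length against a reference distribution
#'
#' The infoVal score is the modified z-score
#' \deqn{\mathrm{infoVal} = (x_{obs} - \tilde x_{sim}) / \sigma_{sim},}
#' with \eqn{\tilde x_{sim}} the median of the simulated lengths and
#' \eqn{\sigma_{sim} = 1.4826 \cdot MAD}. The null hypothesis that the CI was
#' generated by a random process is rejected when the score exceeds the
#' critical value (one-sided; default 1.96 for alpha = .05).
#'
#' @param observed_length vector length of the observed CI.
#' @param reference an [infoval_reference()].
#' @param critical critical value for the rejection decision.
#' @return an object of class `infoval`.
#' @export
infoval_score <- function(observed_length, reference, critical = 1.96) {
  stopifnot(inherits(reference, "infoval_reference"))
  if (!is.finite(observed_length) || observed_length < 0) {
    stop("`observed_length` must be a non-negative number")
  }
  if (reference$sigma_sim <= 0) {
    stop(paste0("degenerate reference distribution: sigma_sim = 0 ",
                "(all simulated vector lengths coincide); ",
                "the infoVal score is undefined for this stimulus set"))
  }
  score <- (observed_length - reference$median_length) / reference$sigma_sim
  structure(
    list(score = score,
         observed_length = observed_length,
         critical = critical,
         reject_h0 = score > critical,
         reference = reference),
    class = "infoval")
}

#' Informational value of a classification image
#'
#' The main entry point: computes the observed CI's vector length from the
#' responses, simulates (or reuses) the reference distribution of vector
#' lengths under fully random responding on the same stimulus set, and returns
#' the infoVal score — a modified z-score that is positive and large when the
#' responses were consistent enough that the CI cannot plausibly have arisen
#' from random responding.
#'
#' The reference distribution is cached on the stimulus set keyed by
#' `(n_iter, seed, method)`, so scoring many participants who performed the
#' same task reuses one reference.
#'
#' @param stimuli a [stimulus_set()].
#' @param responses `+1` / `-1` choices, one per trial.
#' @param n_iter reference iterations (default 10000).
#' @param seed optional seed for the reference simulation.
#' @param critical critical value (default 1.96).
#' @param reference optional precomputed [infoval_reference()] (overrides
#'   `n_iter` and `seed`).
#' @param method `"gram"` (default) or `"naive"` vector-length path.
#' @return an object of class `infoval` with fields `score`,
#'   `observed_length`, `reject_h0`, `critical` and the embedded `reference`.
#' @examples
#' b <- noise_basis(64)
#' stim <- stimulus_set(40, b, master_seed = 11)
#' resp <- sign(region_means(stim, "full"))  # a perfectly consistent observer
#' iv <- infoval(stim, resp, n_iter = 2000, seed = 1)
#' iv$score
#' @export
infoval <- function(stimuli, responses, n_iter = 10000, seed = NULL,
                    critical = 1.96, reference = NULL,
                    method = c("gram", "naive")) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  method <- match.arg(method)
  responses <- response_vector(responses)
  if (length(responses) != stimuli$n_trials) {
    stop(sprintf("got %d responses for a stimulus set of %d trials",
                 length(responses), stimuli$n_trials))
  }
  x_obs <- if (method == "gram") {
    lengths_from_gram(gram_matrix(stimuli), matrix(responses, ncol = 1L))
  } else {
    vector_length(classification_image(stimuli, responses))
  }
  if (is.null(reference)) {
    key <- paste("ref", n_iter, seed %||% "none", method, sep = "_")
    reference <- stimuli$cache[[key]]
    if (is.null(reference)) {
      reference <- infoval_reference(stimuli, n_iter = n_iter, seed = seed,
                                     method = method)
      stimuli$cache[[key]] <- reference
    }
  } else {
    stopifnot(inherits(reference, "infoval_reference"))
    if (reference$n_trials != stimuli$n_trials) {
      stop(sprintf("reference was built on %d trials but the stimulus set has %d",
                   reference$n_trials, stimuli$n_trials))
    }
  }
  infoval_score(as.numeric(x_obs), reference, critical = critical)
}

#' @export
print.infoval <- function(x, ...) {
  cat("\tInformational value of a classification image\n\n")
  cat(sprintf("infoVal = %.4f (modified z), critical value = %g\n",
              x$score, x$critical))
  cat(sprintf("observed vector length = %.6g\n", x$observed_length))
  r <- x$reference
  cat(sprintf("reference: median = %.6g, sigma_sim = %.6g (%d random-response iterations)\n",
              r$median_length, r$sigma_sim, r$n_iter))
  cat(if (x$reject_h0) {
    "decision: reject H0 of random responding (signal present)\n"
  } else {
    "decision: do not reject H0 of random responding\n"
  })
  invisible(x)
}

#' @export
summary.infoval <- function(object, ...) {
  r <- object$reference
  out <- list(
    score = object$score,
    observed_length = object$observed_length,
    critical = object$critical,
    reject_h0 = object$reject_h0,
    reference_median = r$median_length,
    reference_mad = r$mad,
    reference_sigma = r$sigma_sim,
    reference_quantiles = stats::quantile(r$lengths, c(.01, .05, .5, .95, .99)),
    n_iter = r$n_iter,
    n_trials = r$n_trials)
  class(out) <- "summary.infoval"
  out
}

#' @export
print.summary.infoval <- function(x, ...) {
  cat("Informational value (infoVal) summary\n")
  cat(sprintf("  score: %.4f  (critical %g; reject H0: %s)\n",
              x$score, x$critical, x$reject_h0))
  cat(sprintf("  observed vector length: %.6g over %d trials\n",
              x$observed_length, x$n_trials))
  cat(sprintf("  reference (n_iter = %d): median %.6g, MAD %.6g, sigma_sim %.6g\n",
              x$n_iter, x$reference_median, x$reference_mad, x$reference_sigma))
  cat("  reference length quantiles:\n")
  print(x$reference_quantiles)
  invisible(x)
}

#' Plot an infoVal result
#'
#' Histogram of the reference distribution of simulated vector lengths, with
#' the reference median (dashed), the rejection threshold
#' `median + critical * sigma_sim` (dotted) and the observed vector length
#' (point) marked.
#'
#' @param x an `infoval` object.
#' @param ... passed to [graphics::hist()].
#' @export
plot.infoval <- function(x, ...) {
  r <- x$reference
  thr <- r$median_length + x$critical * r$sigma_sim
  xlim <- range(r$lengths, x$observed_length, thr)
  h <- graphics::hist(r$lengths, breaks = 50, plot = FALSE)
  graphics::plot(h, freq = TRUE, xlim = xlim,
                 main = "Reference distribution of simulated vector lengths",
                 xlab = "CI vector length", ...)
  graphics::abline(v = r$median_length, lty = 2)
  graphics::abline(v = thr, lty = 3)
  graphics::points(x$observed_length, 0, pch = 19, col = "red", cex = 1.3)
  invisible(x)
}
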