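## Ideal-observer / partial-random simulation harness used to establish the
## Type-I error rate and power of the infoVal metric.

#' Configure a simulated observer
#'
#' The simulated participant's task is to pick, from a noise pattern and its
#' inverse, the stimulus that appears brightest over a signal region. With
#' probability `p_random` a trial is answered at chance; otherwise the
#' observer picks the pair member with the higher mean intensity over the
#' mask (the original pattern when its region mean is positive).
#'
#' @param p_random probability of random responding per trial, in `[0, 1]`.
#' @param mask signal region used for the brightness judgment (see
#'   [resolve_mask()]); `"full"`, `"centerN"`, a side length, or a rectangle.
#' @param tie behavior when a region mean is exactly zero: `"random"`
#'   (default, unbiased coin flip), `"original"` or `"inverse"`.
#' @return an object of class `observer_config`.
#' @export
ideal_observer <- function(p_random = 0, mask = "full",
                           tie = c("random", "original", "inverse")) {
  tie <- match.arg(tie)
  if (length(p_random) != 1L || !is.finite(p_random) ||
      p_random < 0 || p_random > 1) {
    stop("`p_random` must be a single probability in [0, 1]")
  }
  structure(list(p_random = p_random, mask = mask, tie = tie),
            class = "observer_config")
}

#' @export
print.observer_config <- function(x, ...) {
  cat(sprintf("Simulated observer: P[random] = %g, mask = %s, tie rule = %s\n",
              x$p_random, paste(as.character(x$mask), collapse = ":"), x$tie))
  invisible(x)
}

## Deterministic part of the observer's choices: +1 / -1 per trial from the
## sign of the region mean; zeros resolved by the tie rule.
ideal_choices <- function(stimuli, observer) {
  m <- region_means(stimuli, observer$mask)
  ch <- sign(m)
  zero <- which(ch == 0)
  if (length(zero) > 0L) {
    ch[zero] <- switch(observer$tie,
                       random = sample(c(-1, 1), length(zero), replace = TRUE),
                       original = 1,
                       inverse = -1)
  }
  as.integer(ch)
}

#' Simulate one observer's choices
#'
#' One `+1` / `-1` choice per trial from the current RNG state: each trial is
#' random with probability `p_random`, otherwise the brightness rule decides.
#'
#' @param stimuli a [stimulus_set()].
#' @param observer an [ideal_observer()] configuration.
#' @return integer vector of `+1` / `-1` choices.
#' @export
observer_choices <- function(stimuli, observer) {
  stopifnot(inherits(stimuli, "stimulus_set"),
            inherits(observer, "observer_config"))
  ch <- ideal_choices(stimuli, observer)
  if (observer$p_random > 0) {
    r <- stats::runif(stimuli$n_trials) < observer$p_random
    n_r <- sum(r)
    if (n_r > 0L) ch[r] <- sample(c(-1L, 1L), n_r, replace = TRUE)
  }
  ch
}

#' Run one simulated participant and score the resulting CI
#'
#' Generates a full response vector via [observer_choices()], then scores the
#' implied classification image against the supplied reference distribution.
#' With `p_random = 0` the observer is deterministic, so repeated runs on the
#' same stimulus set give the identical score — the upper bound attainable
#' given the task parameters.
#'
#' @param stimuli a [stimulus_set()].
#' @param observer an [ideal_observer()].
#' @param reference an [infoval_reference()] built on the same stimulus set.
#' @param critical critical value for the decision.
#' @return an `infoval` object.
#' @export
simulate_run <- function(stimuli, observer, reference, critical = 1.96) {
  ch <- observer_choices(stimuli, observer)
  x <- lengths_from_gram(gram_matrix(stimuli), matrix(ch, ncol = 1L))
  infoval_score(as.numeric(x), reference, critical = critical)
}

#' Run one simulation cell
#'
#' `n_runs` independent simulated participants with the same observer
#' configuration on the same stimulus set; reports the proportion of runs
#' whose infoVal score exceeds the critical value (Type-I error rate when
#' `p_random = 1`, statistical power otherwise).
#'
#' @param stimuli a [stimulus_set()].
#' @param observer an [ideal_observer()].
#' @param n_runs number of simulated participants (>= 1).
#' @param reference an [infoval_reference()] built on the same stimulus set;
#'   built on the fly (with `n_iter` iterations) when omitted.
#' @param critical critical value(s); the first is the cell's headline value,
#'   rejection proportions are reported for all.
#' @param seed optional seed for the observer choices.
#' @param n_iter reference iterations when `reference` is omitted.
#' @return an object of class `simulation_cell` with per-run `scores`,
#'   `rejection_proportion` (named by critical value) and the cell settings.
#' @export
run_cell <- function(stimuli, observer, n_runs, reference = NULL,
                     critical = 1.96, seed = NULL, n_iter = 10000) {
  stopifnot(inherits(stimuli, "stimulus_set"),
            inherits(observer, "observer_config"))
  if (n_runs < 1) stop("`n_runs` must be at least 1")
  n_runs <- as.integer(n_runs)
  if (is.null(reference)) {
    reference <- infoval_reference(stimuli, n_iter = n_iter,
                                   seed = if (is.null(seed)) NULL else
                                     derive_seed(seed, .stream[["reference"]]))
  }
  if (reference$n_trials != stimuli$n_trials) {
    stop(sprintf("reference was built on %d trials but the stimulus set has %d",
                 reference$n_trials, stimuli$n_trials))
  }
  local_seed(if (is.null(seed)) NULL else derive_seed(seed, .stream[["observer"]]))
  T <- stimuli$n_trials
  base <- ideal_choices(stimuli, observer)
  C <- matrix(base, nrow = T, ncol = n_runs)
  if (observer$p_random > 0) {
    r <- matrix(stats::runif(T * n_runs) < observer$p_random, nrow = T)
    n_r <- sum(r)
    if (n_r > 0L) C[r] <- sample(c(-1, 1), n_r, replace = TRUE)
  }
  lens <- lengths_from_gram(gram_matrix(stimuli), C)
  scores <- (lens - reference$median_length) / reference$sigma_sim
  rej <- vapply(critical, function(cv) mean(scores > cv), numeric(1))
  names(rej) <- format(critical)
  structure(
    list(p_random = observer$p_random,
         mask = observer$mask,
         n_trials = T,
         n_runs = n_runs,
         critical_value = critical,
         scores = scores,
         rejection_proportion = rej,
         seed = seed),
    class = "simulation_cell")
}

#' @export
print.simulation_cell <- function(x, ...) {
  cat(sprintf(
    "Simulation cell: P[random] = %g, mask = %s, %d trials, %d runs\n",
    x$p_random, paste(as.character(x$mask), collapse = ":"), x$n_trials,
    x$n_runs))
  for (i in seq_along(x$critical_value)) {
    cat(sprintf("  P(infoVal > %g) = %.3f\n", x$critical_value[i],
                x$rejection_proportion[i]))
  }
  invisible(x)
}

#' Run a grid of simulation cells (a power table)
#'
#' Crosses `p_random` levels, signal masks and trial counts, running
#' `n_runs` simulated participants per cell. All cells with the same trial
#' count share one stimulus set — the first `n` trials of `stimuli`, which is
#' well-defined because stimulus sets are prefix-stable — and one reference
#' distribution, mirroring how the metric is used in practice.
#'
#' @param stimuli a [stimulus_set()] with at least `max(n_trials)` trials.
#' @param p_random vector of random-responding probabilities.
#' @param masks list (or vector) of mask specifications.
#' @param n_trials vector of trial counts (default: the full set only).
#' @param n_runs simulated participants per cell.
#' @param n_iter iterations per reference distribution.
#' @param critical critical value(s) reported for every cell.
#' @param seed master seed; every reference and cell derives its own stream.
#' @return an object of class `power_table`: `cells` (data frame with one
#'   rejection-proportion column per critical value), per-cell `scores`, and
#'   the shared `references`.
#' @export
run_grid <- function(stimuli, p_random = c(0, .125, .25, .5, .75, 1),
                     masks = list("full"), n_trials = NULL, n_runs = 1000,
                     n_iter = 10000, critical = c(1.96, 3), seed = NULL) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  if (is.null(n_trials)) n_trials <- stimuli$n_trials
  if (max(n_trials) > stimuli$n_trials) {
    stop(sprintf("grid asks for %d trials but the stimulus set has %d",
                 max(n_trials), stimuli$n_trials))
  }
  if (!is.list(masks)) masks <- as.list(masks)
  refs <- list()
  cells <- list()
  scores <- list()
  row <- 0L
  for (ti in seq_along(n_trials)) {
    Tn <- n_trials[ti]
    sub <- if (Tn == stimuli$n_trials) stimuli else stimuli[seq_len(Tn)]
    gram_matrix(sub)  # computed once, shared by the reference and all cells
    ref_seed <- if (is.null(seed)) NULL else
      derive_seed(seed, .stream[["reference"]], ti)
    ref <- infoval_reference(sub, n_iter = n_iter, seed = ref_seed)
    refs[[as.character(Tn)]] <- ref
    for (mi in seq_along(masks)) {
      for (pi in seq_along(p_random)) {
        row <- row + 1L
        obs <- ideal_observer(p_random = p_random[pi], mask = masks[[mi]])
        cell_seed <- if (is.null(seed)) NULL else
          derive_seed(seed, .stream[["grid"]], row)
        cell <- run_cell(sub, obs, n_runs = n_runs, reference = ref,
                         critical = critical, seed = cell_seed)
        rec <- data.frame(
          mask = paste(as.character(masks[[mi]]), collapse = ":"),
          p_random = p_random[pi],
          n_trials = Tn,
          n_runs = n_runs,
          stringsAsFactors = FALSE)
        for (ci in seq_along(critical)) {
          rec[[paste0("reject_", critical[ci])]] <-
            cell$rejection_proportion[ci]
        }
        cells[[row]] <- rec
        scores[[row]] <- cell$scores
      }
    }
  }
  structure(
    list(cells = do.call(rbind, cells), scores = scores, references = refs,
         critical = critical, n_iter = n_iter, seed = seed),
    class = "power_table")
}

#' @export
print.power_table <- function(x, ...) {
  cat(sprintf("Power table: %d cells, %d reference iterations each\n",
              nrow(x$cells), x$n_iter))
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.power_table <- function(x, ...) x$cells

#' Dose-response summary of a simulation grid
#'
#' Pools every run of a power table and summarises how the infoVal score
#' responds to the probability of random responding: the Pearson correlation
#' between `p_random` and score across all runs, and the variance explained
#' by linear and quadratic least-squares fits.
#'
#' @param table a [run_grid()] result with at least 3 distinct `p_random`
#'   levels.
#' @return list with `r`, `r_squared_linear`, `r_squared_quadratic`,
#'   `n_runs_total` and the fitted `lm` objects.
#' @export
dose_response_summary <- function(table) {
  stopifnot(inherits(table, "power_table"))
  p <- rep(table$cells$p_random, lengths(table$scores))
  s <- unlist(table$scores, use.names = FALSE)
  if (length(unique(table$cells$p_random)) < 3L) {
    stop("need at least 3 distinct p_random levels to summarise the dose-response relation")
  }
  fit1 <- stats::lm(s ~ p)
  fit2 <- stats::lm(s ~ p + I(p^2))
  list(r = stats::cor(p, s),
       r_squared_linear = summary(fit1)$r.squared,
       r_squared_quadratic = summary(fit2)$r.squared,
       n_runs_total = length(s),
       fit_linear = fit1,
       fit_quadratic = fit2)
}
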