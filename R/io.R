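## File formats: response CSVs, result JSON/CSV, stimulus archives, and the
## synthetic-experiment fixture generator.

#' Read 2IFC responses from a CSV file
#'
#' Expected columns: `participant_id`, `trial_index` (1-based, contiguous per
#' participant), `choice`, and optionally `rt_ms`. Choices are `+1` / `-1`,
#' or arbitrary labels (e.g. `L` / `R`) mapped via `choice_map` or via a
#' comment header line in the file of the form `# choice_map: L=1,R=-1`.
#'
#' @param path CSV file path.
#' @param choice_map optional named vector mapping choice labels to `+1` /
#'   `-1`; overrides any map found in the file header.
#' @return named list with one `+1` / `-1` response vector per participant
#'   (trial order), with response times attached when present.
#' @export
read_responses <- function(path, choice_map = NULL) {
  if (!file.exists(path)) stop(sprintf("response file '%s' does not exist", path))
  if (is.null(choice_map)) {
    head_lines <- readLines(path, n = 10L)
    ml <- grep("^#\\s*choice_map\\s*:", head_lines, value = TRUE)
    if (length(ml) > 0L) {
      spec <- sub("^#\\s*choice_map\\s*:\\s*", "", ml[1L])
      parts <- strsplit(strsplit(spec, ",")[[1]], "=")
      choice_map <- stats::setNames(
        as.numeric(trimws(vapply(parts, `[`, "", 2L))),
        trimws(vapply(parts, `[`, "", 1L)))
    }
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("participant_id", "trial_index", "choice")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("response file is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(choice_map)) {
    mapped <- choice_map[as.character(df$choice)]
    un <- which(is.na(mapped) & !is.na(df$choice))
    if (length(un) > 0L) {
      stop(sprintf("choice value(s) not covered by the choice map at row(s): %s",
                   paste(utils::head(un, 10L), collapse = ", ")))
    }
    df$choice <- as.numeric(mapped)
  }
  dup <- which(duplicated(df[, c("participant_id", "trial_index")]))
  if (length(dup) > 0L) {
    stop(sprintf("duplicate (participant, trial) row(s): %s",
                 paste(utils::head(dup, 10L), collapse = ", ")))
  }
  out <- list()
  for (pid in unique(df$participant_id)) {
    sub <- df[df$participant_id == pid, , drop = FALSE]
    sub <- sub[order(sub$trial_index), , drop = FALSE]
    if (!identical(as.integer(sub$trial_index), seq_len(nrow(sub)))) {
      stop(sprintf(
        "participant '%s': trial indices must be contiguous from 1 (got %s...)",
        pid, paste(utils::head(sub$trial_index, 5L), collapse = ", ")))
    }
    out[[as.character(pid)]] <- response_vector(
      sub$choice, response_times = if ("rt_ms" %in% names(df)) sub$rt_ms)
  }
  out
}

#' Write an infoVal result as JSON
#'
#' Keys: `score`, `observed_length`, `median`, `mad`, `sigma`, `n_iter`,
#' `reject`.
#'
#' @param result an `infoval` object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_infoval <- function(result, path) {
  stopifnot(inherits(result, "infoval"))
  r <- result$reference
  obj <- list(score = result$score,
              observed_length = result$observed_length,
              median = r$median_length,
              mad = r$mad,
              sigma = r$sigma_sim,
              n_iter = r$n_iter,
              reject = result$reject_h0)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read back an infoVal result JSON
#' @param path file written by [write_infoval()].
#' @return named list.
#' @export
read_infoval <- function(path) {
  jsonlite::fromJSON(path)
}

#' Write a power table as CSV
#'
#' Long format: one row per cell and critical value, with columns
#' `p_random`, `n_trials`, `mask`, `crit`, `n_runs`, `rejections`,
#' `proportion`.
#'
#' @param table a [run_grid()] result.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_power_table <- function(table, path) {
  stopifnot(inherits(table, "power_table"))
  rows <- list()
  for (i in seq_len(nrow(table$cells))) {
    cell <- table$cells[i, ]
    for (cv in table$critical) {
      prop <- cell[[paste0("reject_", cv)]]
      rows[[length(rows) + 1L]] <- data.frame(
        p_random = cell$p_random, n_trials = cell$n_trials, mask = cell$mask,
        crit = cv, n_runs = cell$n_runs,
        rejections = as.integer(round(prop * cell$n_runs)),
        proportion = prop, stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a stimulus archive
#'
#' A gzip-compressed JSON container holding the basis parameters, the master
#' seed and the per-trial seeds — everything needed to regenerate the
#' stimulus set bit-exactly, without storing any pixels.
#'
#' @param stimuli a [stimulus_set()].
#' @param path output path (conventionally `.json.gz`).
#' @return the path, invisibly.
#' @export
write_stimulus_archive <- function(stimuli, path) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  b <- stimuli$basis
  obj <- list(format = "infoval_stimulus_archive", version = 1L,
              resolution = b$resolution, n_levels = b$n_levels,
              orientations = b$orientations, phases = b$phases,
              cycles = b$cycles,
              master_seed = stimuli$master_seed,
              n_trials = stimuli$n_trials,
              trial_seeds = stimuli$trial_seeds)
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), con)
  invisible(path)
}

#' Read a stimulus archive
#'
#' Regenerates the stimulus set recorded by [write_stimulus_archive()].
#'
#' @param path archive path.
#' @param keep_patterns synthesize and hold the pattern matrix now (default);
#'   with `FALSE`, patterns are regenerated lazily.
#' @return a `stimulus_set`.
#' @export
read_stimulus_archive <- function(path, keep_patterns = TRUE) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  obj <- jsonlite::fromJSON(paste(readLines(con), collapse = "\n"))
  if (!identical(obj$format, "infoval_stimulus_archive")) {
    stop(sprintf("'%s' is not an infoval stimulus archive", path))
  }
  basis <- noise_basis(obj$resolution, n_levels = obj$n_levels,
                       orientations = obj$orientations, phases = obj$phases,
                       cycles = obj$cycles)
  x <- new_stimulus_set(basis, as.integer(obj$trial_seeds), obj$master_seed)
  if (keep_patterns) x$patterns <- stimulus_patterns(x)
  x
}

#' Export an image matrix as 8-bit grayscale PNG
#'
#' Display-only: values are affinely mapped from `[lo, hi]` into `[0, 255]`.
#' Requires the `png` package.
#'
#' @param img numeric matrix.
#' @param path output path.
#' @param range intensity range mapped to black..white; defaults to the
#'   image's own range.
#' @return the path, invisibly.
#' @export
write_image_png <- function(img, path, range = NULL) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("PNG export requires the 'png' package")
  }
  img <- as.matrix(img)
  if (is.null(range)) range <- base::range(img)
  if (diff(range) == 0) range <- range + c(-0.5, 0.5)
  z <- (img - range[1]) / diff(range)
  png::writePNG(pmin(pmax(z, 0), 1), path)
  invisible(path)
}

#' Generate a complete synthetic 2IFC experiment on disk
#'
#' Stands in for empirical data: simulated participants in two categories
#' perform the same task on a shared stimulus set, each category attending to
#' its own signal region (so the two categories develop distinct CIs), with a
#' per-participant probability of random responding. Emits a stimulus archive
#' plus per-session response CSVs and a labels CSV, so every downstream
#' metric (infoVal, ODR, test-retest, MDS) can run with no external data.
#'
#' @param dir output directory (created if needed).
#' @param n_per_category simulated participants per category.
#' @param p_random per-trial probability of random responding (single value
#'   or one per category).
#' @param n_trials trials per session.
#' @param resolution stimulus side length in pixels.
#' @param n_sessions sessions per participant (2 enables test-retest).
#' @param masks named list of one mask per category; defaults to the left and
#'   right image halves.
#' @param labels the two category labels.
#' @param seed master seed.
#' @return list with file `paths`, the `stimuli`, the per-session response
#'   lists and the label data frame.
#' @export
generate_fixture <- function(dir, n_per_category = 10, p_random = 0.3,
                             n_trials = 200, resolution = 64, n_sessions = 1,
                             masks = NULL, labels = c("A", "B"), seed = 1) {
  if (length(labels) != 2L) stop("`labels` must name exactly two categories")
  if (is.null(masks)) {
    half <- resolution %/% 2L
    masks <- list(c(1, resolution, 1, half),
                  c(1, resolution, half + 1L, resolution))
  }
  if (length(masks) != 2L) stop("`masks` must supply one mask per category")
  p_random <- rep_len(p_random, 2L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  basis <- noise_basis(resolution)
  stim <- stimulus_set(n_trials, basis,
                       master_seed = derive_seed(seed, .stream[["stimuli"]]))
  archive <- file.path(dir, "stimuli.json.gz")
  write_stimulus_archive(stim, archive)
  lab_df <- data.frame(
    participant_id = sprintf("p%02d", seq_len(2L * n_per_category)),
    category = rep(labels, each = n_per_category),
    stringsAsFactors = FALSE)
  responses <- vector("list", n_sessions)
  session_paths <- character(n_sessions)
  run <- 0L
  for (s in seq_len(n_sessions)) {
    rows <- list()
    responses[[s]] <- list()
    for (i in seq_len(nrow(lab_df))) {
      run <- run + 1L
      cat_i <- match(lab_df$category[i], labels)
      obs <- ideal_observer(p_random = p_random[cat_i], mask = masks[[cat_i]])
      local({
        local_seed(derive_seed(seed, .stream[["fixture"]], run))
        ch <- observer_choices(stim, obs)
        responses[[s]][[lab_df$participant_id[i]]] <<- ch
        rows[[i]] <<- data.frame(
          participant_id = lab_df$participant_id[i],
          trial_index = seq_len(n_trials),
          choice = ch, stringsAsFactors = FALSE)
      })
    }
    session_paths[s] <- file.path(dir, sprintf("responses_session%d.csv", s))
    utils::write.csv(do.call(rbind, rows), session_paths[s], row.names = FALSE)
  }
  labels_path <- file.path(dir, "labels.csv")
  utils::write.csv(lab_df, labels_path, row.names = FALSE)
  list(paths = list(archive = archive, responses = session_paths,
                    labels = labels_path),
       stimuli = stim, responses = responses, labels = lab_df)
}
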