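test_that("observer configuration is validated", {
  expect_error(ideal_observer(p_random = 1.2), "\\[0, 1\\]")
  expect_error(ideal_observer(p_random = -0.1), "\\[0, 1\\]")
  obs <- ideal_observer(0.5, mask = "center32")
  expect_s3_class(obs, "observer_config")
  stim <- tiny_stimuli()
  expect_error(observer_choices(stim, ideal_observer(mask = "center128")),
               "outside")
})

test_that("the brightness rule picks the brighter pair member", {
  stim <- tiny_stimuli()
  m <- region_means(stim, "full")
  ch <- observer_choices(stim, ideal_observer(p_random = 0, mask = "full"))
  expect_identical(ch, as.integer(sign(m)))  # +1 where original brighter
  # choosing the inverse when the original's region mean is negative
  expect_true(all(ch[m < 0] == -1L))
  # a fully random observer is a fair coin
  set.seed(40)
  draws <- observer_choices(
    tiny_stimuli(30)[rep(1, 1)], ideal_observer(p_random = 1))
  big <- replicate(10000, observer_choices(stim[1], ideal_observer(1)))
  expect_lt(abs(mean(big == 1L) - 0.5), 0.02)
})

test_that("exact region-mean ties follow the tie rule", {
  stim <- toy_stimuli(list(c(1, -1, 2, -2), c(1, 2, 3, 4)))
  expect_identical(
    observer_choices(stim, ideal_observer(0, mask = "full", tie = "original")),
    c(1L, 1L))
  expect_identical(
    observer_choices(stim, ideal_observer(0, mask = "full", tie = "inverse")),
    c(-1L, 1L))
  set.seed(2)
  flips <- replicate(500, observer_choices(
    stim, ideal_observer(0, mask = "full", tie = "random"))[1])
  expect_lt(abs(mean(flips == 1L) - 0.5), 0.12)
})

test_that("p_random = 0 runs are deterministic and give the ceiling score", {
  stim <- tiny_stimuli()
  suppressWarnings(ref <- infoval_reference(stim, n_iter = 1000, seed = 20))
  obs <- ideal_observer(0, mask = "full")
  r1 <- simulate_run(stim, obs, ref)
  r2 <- simulate_run(stim, obs, ref)
  expect_identical(r1$score, r2$score)
  cell <- run_cell(stim, obs, n_runs = 5, reference = ref, seed = 1)
  expect_equal(length(unique(cell$scores)), 1L)
  expect_true(cell$rejection_proportion[[1]] %in% c(0, 1))
})

test_that("a fully random observer is indistinguishable from reference draws", {
  stim <- tiny_stimuli()
  suppressWarnings(ref <- infoval_reference(stim, n_iter = 1500, seed = 21))
  cell <- run_cell(stim, ideal_observer(1), n_runs = 500, reference = ref,
                   seed = 22)
  lens <- cell$scores * ref$sigma_sim + ref$median_length
  wt <- stats::wilcox.test(lens, ref$lengths)
  expect_gt(wt$p.value, 0.01)
})

test_that("simulation cells report seeded, reproducible rejection proportions", {
  stim <- tiny_stimuli()
  suppressWarnings(ref <- infoval_reference(stim, n_iter = 1000, seed = 23))
  cell <- run_cell(stim, ideal_observer(0.5), n_runs = 40, reference = ref,
                   critical = c(1.96, 3), seed = 24)
  again <- run_cell(stim, ideal_observer(0.5), n_runs = 40, reference = ref,
                    critical = c(1.96, 3), seed = 24)
  expect_identical(cell$scores, again$scores)
  expect_equal(cell$rejection_proportion[[1]], mean(cell$scores > 1.96))
  expect_equal(cell$rejection_proportion[[2]], mean(cell$scores > 3))
  expect_error(run_cell(stim, ideal_observer(1), n_runs = 0), "at least 1")
  # reference must match the stimulus set
  sub <- stim[1:10]
  expect_error(run_cell(sub, ideal_observer(1), n_runs = 2, reference = ref),
               "30")
})

test_that("a toy grid has the advertised layout and is seed-deterministic", {
  stim <- tiny_stimuli()
  suppressWarnings(
    pt <- run_grid(stim, p_random = c(0.25, 1), masks = list("full"),
                   n_trials = c(10, 30), n_runs = 3, n_iter = 300,
                   critical = 1.96, seed = 30))
  expect_equal(nrow(pt$cells), 4L)
  expect_equal(length(unlist(pt$scores)), 12L)
  expect_named(pt$references, c("10", "30"))
  suppressWarnings(
    pt2 <- run_grid(stim, p_random = c(0.25, 1), masks = list("full"),
                    n_trials = c(10, 30), n_runs = 3, n_iter = 300,
                    critical = 1.96, seed = 30))
  expect_identical(pt$cells, pt2$cells)
  expect_identical(unlist(pt$scores), unlist(pt2$scores))
})

test_that("power rises with trials and falls with random responding (small grid)", {
  stim <- stimulus_set(60, tiny_basis(), master_seed = 55)
  suppressWarnings(
    pt <- run_grid(stim, p_random = c(0, 0.5, 1), masks = list("center32"),
                   n_trials = c(20, 60), n_runs = 150, n_iter = 1500,
                   critical = 1.96, seed = 31))
  cells <- pt$cells
  for (Tn in unique(cells$n_trials)) {
    prop <- cells$reject_1.96[cells$n_trials == Tn]
    expect_true(all(diff(prop) <= 0.08))  # anti-monotone in p_random
  }
  mean_score_by_T <- tapply(
    vapply(pt$scores, mean, numeric(1))[cells$p_random == 0.5],
    cells$n_trials[cells$p_random == 0.5], mean)
  expect_gt(mean_score_by_T["60"], mean_score_by_T["20"] - 0.25)
})

test_that("dose-response summary matches a normal-equations oracle", {
  # hand-built 5-point dataset, fitted by explicitly solving X'X b = X'y
  p <- c(0, 0.25, 0.5, 0.75, 1)
  s <- c(9.1, 7.2, 4.8, 2.4, 0.3)
  pt <- structure(list(
    cells = data.frame(p_random = p, n_trials = 5, mask = "full", n_runs = 1,
                       reject_1.96 = NA),
    scores = as.list(s), references = list(), critical = 1.96,
    n_iter = 0, seed = NULL), class = "power_table")
  dr <- suppressWarnings(dose_response_summary(pt))  # perfect-fit warnings
  X1 <- cbind(1, p)
  b1 <- solve(t(X1) %*% X1, t(X1) %*% s)
  rss1 <- sum((s - X1 %*% b1)^2)
  X2 <- cbind(1, p, p^2)
  b2 <- solve(t(X2) %*% X2, t(X2) %*% s)
  rss2 <- sum((s - X2 %*% b2)^2)
  tss <- sum((s - mean(s))^2)
  expect_equal(dr$r, sum((p - mean(p)) * (s - mean(s))) /
                 sqrt(sum((p - mean(p))^2) * sum((s - mean(s))^2)))
  expect_equal(dr$r_squared_linear, 1 - rss1 / tss)
  expect_equal(dr$r_squared_quadratic, 1 - rss2 / tss)
  expect_equal(unname(coef(dr$fit_quadratic)), as.numeric(b2), tolerance = 1e-9)

  # scores exactly linear in p_random: |r| = 1 and both fits are perfect
  pt$scores <- as.list(10 - 8 * p)
  dr_lin <- suppressWarnings(dose_response_summary(pt))
  expect_equal(dr_lin$r, -1)
  expect_equal(dr_lin$r_squared_linear, 1)
  expect_equal(dr_lin$r_squared_quadratic, 1)
  pt$cells <- pt$cells[1:2, ]; pt$scores <- pt$scores[1:2]
  expect_error(dose_response_summary(pt), "3 distinct")
})
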