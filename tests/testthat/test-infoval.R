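test_that("scaled MAD matches the brute-force definition", {
  expect_equal(scaled_mad(rep(4.2, 10)), 0)
  expect_equal(scaled_mad(c(1, 2, 3, 4, 5), k = 1), 1)
  expect_equal(scaled_mad(c(1, 1, 2, 2, 4, 6, 9), k = 1), 1)
  expect_equal(scaled_mad(c(1, 1, 2, 2, 4, 6, 9), k = 1),
               brute_mad(c(1, 1, 2, 2, 4, 6, 9)))
  set.seed(31)
  for (n in c(4, 7, 12, 101)) {
    x <- stats::rnorm(n)
    expect_equal(scaled_mad(x, k = 1), brute_mad(x))
    expect_equal(scaled_mad(x), 1.4826 * brute_mad(x))
  }
  expect_error(scaled_mad(numeric(0)), "at least one")
})

test_that("Gram quadratic form reproduces brute-force norms over all sign vectors", {
  pats <- list(c(0.3, -1, 2, 0.5), c(1, 1, -1, 0), c(0.2, 0.4, -0.6, 1.5))
  stim <- toy_stimuli(pats)
  G <- gram_matrix(stim)
  expect_equal(diag(G), vapply(pats, function(p) sum(p^2), numeric(1)))
  expect_equal(G, t(G))
  expect_gte(min(eigen(G, only.values = TRUE)$values), -1e-12)
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  for (i in seq_len(nrow(signs))) {
    cc <- signs[i, ]
    brute <- sqrt(sum((cc[1] * pats[[1]] + cc[2] * pats[[2]] + cc[3] * pats[[3]])^2)) / 3
    expect_equal(as.numeric(infoval:::lengths_from_gram(G, matrix(cc, ncol = 1))),
                 brute, tolerance = 1e-12)
  }
})

test_that("Gram fast path and naive pattern path agree to 1e-9 relative", {
  stim <- tiny_stimuli(16)
  G <- gram_matrix(stim)
  P <- stimulus_patterns(stim)
  # exhaustive over a 16-trial toy would be 65536 sign vectors; sample the
  # cube densely and include the exhaustive enumeration of the first 8 trials
  sub <- stim[1:8]
  C8 <- t(as.matrix(expand.grid(rep(list(c(-1, 1)), 8))))
  expect_equal(infoval:::lengths_from_gram(gram_matrix(sub), C8),
               infoval:::lengths_naive(stimulus_patterns(sub), C8),
               tolerance = 1e-9)
  set.seed(13)
  C <- matrix(sample(c(-1, 1), 16 * 500, replace = TRUE), 16)
  lg <- infoval:::lengths_from_gram(G, C)
  ln <- infoval:::lengths_naive(P, C)
  expect_lt(max(abs(lg - ln) / ln), 1e-9)
})

test_that("reference distributions behave at degenerate and tiny trial counts", {
  one <- tiny_stimuli()[1]
  suppressWarnings(ref1 <- infoval_reference(one, n_iter = 50, seed = 1))
  # T = 1: every random CI is +-the single pattern, so all lengths coincide
  expect_equal(ref1$mad, 0)
  expect_error(infoval_score(ref1$median_length + 1, ref1), "degenerate")
  expect_error(infoval_reference(one, n_iter = 1), "at least 2")

  two <- tiny_stimuli()[1:2]
  P <- stimulus_patterns(two)
  lens_expected <- sort(c(sqrt(sum((P[, 1] + P[, 2])^2)),
                          sqrt(sum((P[, 1] - P[, 2])^2))) / 2)
  suppressWarnings(ref2 <- infoval_reference(two, n_iter = 400, seed = 2))
  expect_true(all(sapply(ref2$lengths, function(l)
    min(abs(l - lens_expected)) < 1e-12)))
  frac <- mean(abs(ref2$lengths - lens_expected[1]) < 1e-12)
  expect_gt(frac, 0.5 - 0.13)  # each of the 4 sign sequences has p = 1/4
  expect_lt(frac, 0.5 + 0.13)
})

test_that("sigma_sim is k * MAD with the standard k = 1.4826", {
  stim <- tiny_stimuli()
  suppressWarnings(ref <- infoval_reference(stim, n_iter = 500, seed = 3))
  expect_equal(ref$k, 1.4826)
  expect_equal(ref$sigma_sim, 1.4826 * ref$mad)
  expect_equal(ref$mad, brute_mad(ref$lengths))
  expect_equal(ref$median_length, stats::median(ref$lengths))
})

test_that("infoVal scores follow the modified z-score identity", {
  stim <- tiny_stimuli()
  suppressWarnings(ref <- infoval_reference(stim, n_iter = 500, seed = 4))
  expect_equal(infoval_score(ref$median_length, ref)$score, 0)
  at_crit <- infoval_score(ref$median_length + 1.96 * ref$sigma_sim, ref)
  expect_equal(at_crit$score, 1.96)
  expect_false(at_crit$reject_h0)  # one-sided, strict inequality
  above <- infoval_score(ref$median_length + 2 * ref$sigma_sim, ref)
  expect_true(above$reject_h0)
  below <- infoval_score(max(ref$median_length - 3 * ref$sigma_sim, 0), ref)
  expect_false(below$reject_h0)  # negative scores never reject
})

test_that("infoVal is invariant to global rescaling of the noise", {
  stim <- tiny_stimuli(12)
  scaled <- toy_stimuli(asplit(stimulus_patterns(stim) * 7.3, 2))
  set.seed(17)
  resp <- sample(c(-1L, 1L), 12, replace = TRUE)
  suppressWarnings(iv1 <- infoval(stim, resp, n_iter = 300, seed = 5))
  suppressWarnings(iv2 <- infoval(scaled, resp, n_iter = 300, seed = 5))
  expect_equal(iv1$score, iv2$score, tolerance = 1e-12)
  expect_equal(iv2$observed_length, 7.3 * iv1$observed_length,
               tolerance = 1e-12)
})

test_that("end-to-end scoring separates consistent from random responders", {
  b <- tiny_basis()
  stim <- stimulus_set(20, b, master_seed = 77)
  # a responder who always chooses the pair member aligned with one fixed
  # pattern direction (the first trial's pattern)
  P <- stimulus_patterns(stim)
  consistent <- as.integer(sign(crossprod(P, P[, 1])))
  suppressWarnings(iv <- infoval(stim, consistent, n_iter = 1000, seed = 6))
  # brute-force end-to-end check of the observed length
  expect_equal(iv$observed_length,
               sqrt(sum((as.vector(P %*% consistent) / 20)^2)),
               tolerance = 1e-9)
  expect_gt(iv$score, 1.96)
  expect_true(iv$reject_h0)

  # a seeded random responder falls in the bulk of its own null
  set.seed(8)
  rejections <- vapply(1:120, function(i) {
    resp <- sample(c(-1L, 1L), 20, replace = TRUE)
    suppressWarnings(
      infoval(stim, resp, n_iter = 1000, seed = 6)$reject_h0)
  }, logical(1))
  expect_lt(mean(rejections), 0.15)  # ~.05 expected; loose Monte-Carlo bound
})

test_that("identical inputs and seeds give identical scores, and references are cached", {
  stim <- tiny_stimuli()
  resp <- rep(c(1L, -1L), 15)
  suppressWarnings(iv1 <- infoval(stim, resp, n_iter = 300, seed = 9))
  suppressWarnings(iv2 <- infoval(stim, resp, n_iter = 300, seed = 9))
  expect_identical(iv1$score, iv2$score)
  expect_identical(iv1$reference$lengths, iv2$reference$lengths)
  # fresh equal stimulus set reproduces the score from scratch
  stim_b <- stimulus_set(30, tiny_basis(), master_seed = 7)
  suppressWarnings(iv3 <- infoval(stim_b, resp, n_iter = 300, seed = 9))
  expect_equal(iv3$score, iv1$score)
})

test_that("naive scoring method matches the gram method", {
  stim <- tiny_stimuli(10)
  resp <- rep(c(1L, -1L), 5)
  suppressWarnings(a <- infoval(stim, resp, n_iter = 200, seed = 10))
  suppressWarnings(b <- infoval(stim, resp, n_iter = 200, seed = 10,
                                method = "naive"))
  expect_equal(a$observed_length, b$observed_length, tolerance = 1e-9)
  expect_equal(a$score, b$score, tolerance = 1e-6)
})
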