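# Antlion optimizer components and the full ALO-MD selection loop.

test_that("random walks take unit steps from zero", {
  for (s in 1:20) {
    set.seed(s)
    u <- runif(6)
    walk <- random_walk(6, seed = s)
    expect_equal(walk, c(0, cumsum(2 * (u > 0.5) - 1)))
    expect_equal(walk[1], 0)
    expect_true(all(abs(diff(walk)) == 1))
  }
  expect_error(random_walk(0), ">= 1")
  # single step is +1 exactly when the draw exceeds 0.5
  for (s in 1:50) {
    set.seed(s)
    u1 <- runif(1)
    expect_equal(random_walk(1, seed = s)[2], if (u1 > 0.5) 1 else -1)
  }
})

test_that("walk normalization is a min-max rescale into the interval", {
  expect_equal(normalize_walk(c(0, 1, 2), 0, 1), c(0, 0.5, 1))
  expect_equal(normalize_walk(c(5, 5, 5), 0.2, 0.8), rep(0.5, 3))
  expect_equal(normalize_walk(c(0, 1, -2), 0.3, 0.3), rep(0.3, 3))
  for (s in 1:10) {
    w <- random_walk(20, seed = s)
    v <- normalize_walk(w, 0, 1)
    expect_equal(min(v), 0)
    expect_equal(max(v), 1)
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("bound shrinking follows the 10^u * s/S ratio", {
  expect_equal(shrink_bounds(0, 1, 60, 100, u = 4)$ratio_I, 6000)
  expect_equal(shrink_bounds(0, 1, 100, 100, u = 6)$ratio_I, 1e6)
  expect_equal(shrink_bounds(0, 1, 0, 100)$ratio_I, 1)
  sb <- shrink_bounds(-1, 1, 60, 100, u = 4)
  expect_equal(sb$as_vec, -1 / 6000)
  expect_equal(sb$bs_vec, 1 / 6000)
  # widths never grow as iterations proceed under the scheduled u
  widths <- vapply(0:50, function(s) {
    sb <- shrink_bounds(0, 1, s, 50)
    sb$bs_vec - sb$as_vec
  }, numeric(1))
  expect_true(all(diff(widths) <= 1e-12))
  expect_error(shrink_bounds(0, 1, 5, 4), "\\[0, S\\]")
})

test_that("bound shifting recenters on the antlion and clips to the box", {
  b <- shift_bounds(-0.1, 0.1, 0.5)
  expect_equal(b$lower, 0.4)
  expect_equal(b$upper, 0.6)
  b <- shift_bounds(-0.2, 0.2, 0)
  expect_equal(b$lower, 0)
  expect_equal(b$upper, 0.2)
  b <- shift_bounds(0, 0, 0.7)
  expect_equal(b$lower, 0.7)
  expect_equal(b$upper, 0.7)
  # vectorized over dimensions
  b <- shift_bounds(rep(-0.1, 3), rep(0.1, 3), c(0, 0.5, 1))
  expect_equal(b$lower, c(0, 0.4, 0.9))
  expect_equal(b$upper, c(0.1, 0.6, 1))
})

test_that("roulette selection weights by transformed fitness", {
  expect_equal(roulette_select(5), 1L)
  set.seed(1)
  draws <- replicate(1e4, roulette_select(c(1, 0, 0, 0)))
  expect_gte(mean(draws == 1), 0.95)
  draws <- replicate(1e4, roulette_select(c(2, 2, 2, 2)))
  props <- tabulate(draws, 4) / 1e4
  expect_true(all(abs(props - 0.25) < 0.02))
  # minimization flips the preference
  draws <- replicate(1e3, roulette_select(c(0, 1, 1, 1), minimize = TRUE))
  expect_gte(mean(draws == 1), 0.95)
})

test_that("elitism averaging and catch-and-rebuild behave as specified", {
  expect_equal(elitism_combine(c(0, 1), c(1, 0)), c(0.5, 0.5))
  expect_equal(elitism_combine(c(0.3, 0.3), c(0.3, 0.3)), c(0.3, 0.3))
  expect_equal(elitism_combine(c(0.2, 0.4, 0.6), c(0.4, 0.2, 0)),
               c(0.3, 0.3, 0.3))
  state <- list(antlions = matrix(0.5, 2, 3),
                antlion_scores = c(0.4, 0.6),
                elite_pos = rep(0.5, 3), elite_score = 0.3)
  # ant worse than its antlion: nothing changes
  s1 <- catch_and_rebuild(state, rep(0.1, 3), 0.7, 1)
  expect_identical(s1, state)
  # ant better than antlion but worse than elite: antlion only
  s2 <- catch_and_rebuild(state, rep(0.1, 3), 0.35, 2)
  expect_equal(s2$antlion_scores[2], 0.35)
  expect_equal(s2$antlions[2, ], rep(0.1, 3))
  expect_equal(s2$elite_score, 0.3)
  # ant better than both: antlion and elite replaced
  s3 <- catch_and_rebuild(state, rep(0.9, 3), 0.2, 1)
  expect_equal(s3$antlion_scores[1], 0.2)
  expect_equal(s3$elite_score, 0.2)
  expect_equal(s3$elite_pos, rep(0.9, 3))
  # ties keep the incumbent
  s4 <- catch_and_rebuild(state, rep(0.9, 3), 0.4, 1)
  expect_identical(s4, state)
})

test_that("binarization thresholds at 0.5 with an empty-mask rescue", {
  expect_equal(binarize(c(0.9, 0.1, 0.6)), c(1L, 0L, 1L))
  expect_equal(binarize(c(0.5, 0.5)), c(1L, 0L))
  expect_equal(binarize(c(1, 1, 1)), c(1L, 1L, 1L))
  expect_equal(sum(binarize(rep(0, 5))), 1L)
})

test_that("selection fitness combines error and sparsity", {
  fm <- two_clouds(n_per = 15, d = 4, seed = 2)
  spec <- fitness_spec(alpha = 1, folds = 5, seed = 1)
  expect_equal(selection_fitness(c(1, 1, 0, 0), fm, spec), 0)
  expect_equal(selection_fitness(rep(0, 4), fm, spec), 1)
  # same accuracy, fewer features scores lower at alpha < 1
  spec2 <- fitness_spec(alpha = 0.99, folds = 5, seed = 1)
  expect_lt(selection_fitness(c(1, 0, 0, 0), fm, spec2),
            selection_fitness(rep(1, 4), fm, spec2))
  # pure-noise mask on balanced 2-class data sits near chance error
  set.seed(4)
  noise_fm <- feature_matrix(matrix(rnorm(200), 50),
                             rep(c("a", "b"), 25))
  scores <- vapply(1:20, function(s) {
    selection_fitness(rep(1, 4), noise_fm,
                      fitness_spec(alpha = 1, folds = 5, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(scores) - 0.5), 0.15)
})

test_that("ALO-MD finds the exhaustive optimum on a tiny problem", {
  fx <- make_feature_dataset(n_samples = 60, n_classes = 3,
                             n_informative = 2, n_noise = 2,
                             n_redundant = 0, class_separation = 6,
                             seed = 7)
  spec <- fitness_spec(alpha = 0.99, folds = 5, seed = 1)
  oracle <- exhaustive_mask_search(fx$data, spec)
  res <- run_alo_md(fx$data, spec, n_ants = 10, S = 30, seed = 3)
  expect_equal(res$score, oracle$score, tolerance = 1e-12)
})

test_that("ALO-MD runs are seeded, monotone and elite-preserving", {
  fx <- make_feature_dataset(n_samples = 60, n_classes = 3,
                             n_informative = 2, n_noise = 4,
                             n_redundant = 0, seed = 8)
  spec <- fitness_spec(folds = 5, seed = 1)
  r1 <- run_alo_md(fx$data, spec, n_ants = 8, S = 10, seed = 11)
  r2 <- run_alo_md(fx$data, spec, n_ants = 8, S = 10, seed = 11)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$mask, r2$mask)
  expect_true(all(diff(r1$trace) <= 0))
  expect_gte(r1$n_selected, 1)
  # S = 1 degenerates to the best of the initial population plus one move
  r3 <- run_alo_md(fx$data, spec, n_ants = 8, S = 1, seed = 11)
  expect_length(r3$trace, 1)
  # the md toggle changes only the search path, never monotonicity
  r4 <- run_alo_md(fx$data, spec, n_ants = 8, S = 10, seed = 11,
                   md_enabled = FALSE)
  expect_true(all(diff(r4$trace) <= 0))
  expect_error(run_alo_md(fx$data, spec, n_ants = 0, S = 5, seed = 1),
               ">= 1")
})
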