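# Serial fusion, pairwise correlation and the fitness-driven partition.

test_that("serial fusion concatenates aligned matrices", {
  labs <- rep(c("a", "b"), 5)
  m1 <- feature_matrix(matrix(rnorm(30), 10), labs, sprintf("x_%d", 1:3))
  m2 <- feature_matrix(matrix(rnorm(40), 10), labs, sprintf("y_%d", 1:4))
  m3 <- feature_matrix(matrix(rnorm(50), 10), labs, sprintf("z_%d", 1:5))
  fused <- serial_fuse(list(m1, m2, m3))
  expect_equal(ncol(fused$values), 12)
  expect_equal(fused$values[, 4:7], m2$values, ignore_attr = TRUE)
  expect_equal(as.character(fused$labels), labs)
  # single input is the identity
  expect_equal(serial_fuse(list(m1))$values, m1$values)
  # conflicting labels abort
  m_bad <- feature_matrix(m2$values, rev(labs))
  expect_error(serial_fuse(list(m1, m_bad)), "labels")
})

test_that("pairwise correlation matches hand-computed values", {
  labs <- c("a", "b", "a")
  fm <- feature_matrix(cbind(c(1, 2, 3), c(2, 4, 6)), labs)
  expect_equal(pairwise_correlation(fm)$pair_r, 1)
  fm <- feature_matrix(cbind(c(1, 2, 3), c(3, 2, 1)), labs)
  expect_equal(pairwise_correlation(fm)$pair_r, -1)
  fm <- feature_matrix(cbind(c(1, 2, 3, 4), c(1, 3, 2, 4)),
                       c("a", "b", "a", "b"))
  expect_equal(pairwise_correlation(fm)$pair_r, 0.8)
  # constant columns get r = 0 by convention
  fm <- feature_matrix(cbind(rep(1, 4), c(1, 3, 2, 4)),
                       c("a", "b", "a", "b"))
  expect_equal(pairwise_correlation(fm)$pair_r, 0)
  # odd width: last column pairs with itself (r = 1)
  fm <- feature_matrix(matrix(rnorm(15), 5), rep(c("a", "b"), length.out = 5))
  pc <- pairwise_correlation(fm)
  expect_equal(pc$pair_index[2, ], c(first = 3L, second = 3L))
  expect_equal(pc$pair_r[2], 1)
})

test_that("pairwise correlation agrees with the covariance oracle", {
  for (s in 1:20) {
    set.seed(100 + s)
    vals <- matrix(rnorm(50 * 20), 50)
    fm <- feature_matrix(vals, rep(c("a", "b"), 25))
    pc <- pairwise_correlation(fm)
    oracle <- vapply(seq_len(10), function(p) {
      stats::cor(vals[, 2 * p - 1], vals[, 2 * p])
    }, numeric(1))
    expect_lt(max(abs(pc$pair_r - oracle)), 1e-10)
  }
})

test_that("knn fitness separates clouds and tracks chance on noise", {
  fm <- two_clouds(n_per = 20, seed = 1)
  expect_equal(knn_fitness(fm, k = 1, folds = 10, seed = 1), 1)
  # determinism
  expect_identical(knn_fitness(fm, folds = 10, seed = 3),
                   knn_fitness(fm, folds = 10, seed = 3))
  expect_error(knn_fitness(feature_matrix(matrix(rnorm(10), 5),
                                          rep("a", 5))),
               "two classes")
  # permuted labels sit near chance on average
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    fm2 <- feature_matrix(fm$values, sample(as.character(fm$labels)))
    knn_fitness(fm2, k = 1, folds = 5, seed = s)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("fuse_select partitions by correlation and picks the fitter set", {
  labs <- rep(c("a", "b"), 20)
  set.seed(9)
  base <- matrix(rnorm(40 * 3), 40)
  # duplicate every column -> every pair perfectly correlated
  fm <- feature_matrix(base[, rep(1:3, each = 2)], labs)
  fr <- fuse_select(list(fm), threshold = 0.5, folds = 4, seed = 1)
  expect_null(fr$weak_set)
  expect_equal(fr$chosen, "positive")
  expect_equal(fr$fitness_weak, 0)
  # threshold above 1 sends everything to the weak set
  fr2 <- fuse_select(list(fm), threshold = 1 + 1e-9, folds = 4, seed = 1)
  expect_null(fr2$positive_set)
  expect_equal(fr2$chosen, "weak")
  # redundant-pair fixture: informative pairs land in the positive set
  fx <- make_feature_dataset(n_samples = 120, n_classes = 3,
                             n_informative = 4, n_noise = 10,
                             n_redundant = 4, seed = 5)
  fr3 <- fuse_select(list(fx$data), threshold = 0.5, folds = 5, seed = 2)
  pos_names <- fr3$positive_set$feature_names
  expect_setequal(pos_names,
                  fx$data$feature_names[c(fx$informative_idx,
                                          fx$redundant_idx)])
  expect_gt(fr3$fitness_positive, fr3$fitness_weak)
  expect_equal(fr3$chosen, "positive")
})

test_that("partition is complete and scale-invariant on random inputs", {
  for (s in 1:10) {
    set.seed(200 + s)
    k <- sample(3:15, 1)
    fm <- feature_matrix(matrix(rnorm(30 * k), 30),
                         rep(c("a", "b", "c"), 10))
    fr <- fuse_select(list(fm), folds = 3, seed = s)
    n_pos <- if (is.null(fr$positive_set)) 0 else ncol(fr$positive_set$values)
    n_weak <- if (is.null(fr$weak_set)) 0 else ncol(fr$weak_set$values)
    expect_equal(n_pos + n_weak, k)
    # scaling a column by a positive constant leaves the partition alone
    fm2 <- fm
    j <- sample(k, 1)
    fm2$values[, j] <- fm2$values[, j] * 7.3
    fr2 <- fuse_select(list(fm2), folds = 3, seed = s)
    expect_equal(is.null(fr2$positive_set), is.null(fr$positive_set))
    if (!is.null(fr$positive_set)) {
      expect_equal(fr2$positive_set$feature_names,
                   fr$positive_set$feature_names)
    }
  }
})
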