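# Independent oracles shared across test files.

# Per-class one-vs-rest metric oracle: expands a confusion matrix into
# label vectors and recomputes every panel metric from first principles
# (MCC via the covariance of one-hot indicator matrices).
metrics_oracle <- function(cm) {
  classes <- rownames(cm)
  truth <- character(0); pred <- character(0)
  for (i in seq_along(classes)) {
    for (j in seq_along(classes)) {
      truth <- c(truth, rep(classes[i], cm[i, j]))
      pred <- c(pred, rep(classes[j], cm[i, j]))
    }
  }
  present <- classes[vapply(classes, function(cl) any(truth == cl),
                            logical(1))]
  rec <- prec <- f1 <- numeric(length(present))
  for (k in seq_along(present)) {
    cl <- present[k]
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    rec[k] <- tp / (tp + fn)
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) {
      2 * prec[k] * rec[k] / (prec[k] + rec[k])
    } else 0
  }
  acc <- mean(truth == pred)
  pe <- sum(vapply(classes, function(cl) {
    mean(truth == cl) * mean(pred == cl)
  }, numeric(1)))
  kappa <- if (1 - pe > 0) (acc - pe) / (1 - pe) else 0
  ti <- as.integer(factor(truth, classes))
  pi_ <- as.integer(factor(pred, classes))
  Tm <- diag(length(classes))[ti, , drop = FALSE]
  Pm <- diag(length(classes))[pi_, , drop = FALSE]
  cov_tp <- sum(diag(stats::cov(Tm, Pm)))
  cov_tt <- sum(diag(stats::cov(Tm, Tm)))
  cov_pp <- sum(diag(stats::cov(Pm, Pm)))
  mcc <- if (cov_tt > 0 && cov_pp > 0) cov_tp / sqrt(cov_tt * cov_pp) else 0
  list(accuracy = acc, sensitivity = mean(rec), precision = mean(prec),
       f1 = mean(f1), kappa = kappa, mcc = mcc,
       fm = sqrt(mean(prec) * mean(rec)))
}

# Random non-degenerate confusion matrix (every class in the truth).
random_cm <- function(seed, max_classes = 6) {
  set.seed(seed)
  c_n <- sample(2:max_classes, 1)
  m <- matrix(rpois(c_n * c_n, 4), c_n)
  diag(m) <- diag(m) + 1
  dimnames(m) <- list(true = letters[1:c_n], predicted = letters[1:c_n])
  m
}
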