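# Shared builders for small in-code fixtures.

# Constant-color image.
flat_image <- function(value = 0.5, h = 8, w = 8) {
  array(rep(value, length.out = 3)[rep(1:3, each = h * w)],
        dim = c(h, w, 3))
}

# Random valid image.
rand_image <- function(h = 12, w = 12, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), dim = c(h, w, 3))
}

# Two well-separated Gaussian point clouds as a feature_matrix.
two_clouds <- function(n_per = 20, d = 3, center = 10, sigma = 0.1,
                       seed = 1) {
  set.seed(seed)
  vals <- rbind(matrix(rnorm(n_per * d, -center, sigma), n_per),
                matrix(rnorm(n_per * d, center, sigma), n_per))
  feature_matrix(vals, rep(c("a", "b"), each = n_per))
}
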