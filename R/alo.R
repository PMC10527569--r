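# Antlion optimization with mean-deviation re-seeding (ALO-MD) for binary
# wrapper feature selection. Ants random-walk inside adaptively shrinking
# intervals recentered on roulette-selected antlions; the elite antlion is
# preserved across iterations; continuous positions in the unit box are
# binarized at 0.5 into feature masks scored by cross-validated 1-NN error
# plus a sparsity penalty (lower is better).

#' Unbiased random walk of ants
#'
#' Walk of `S` unit steps starting at 0: each step is `+1` when a uniform
#' draw exceeds 0.5 and `-1` otherwise, accumulated by a cumulative sum.
#'
#' @param S number of steps (>= 1).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside the optimizer loop).
#' @return numeric vector of length `S + 1` beginning at 0.
#' @export
random_walk <- function(S, seed = NULL) {
  S <- as.integer(S)
  if (S < 1L) stop("`S` must be >= 1", call. = FALSE)
  with_seed(seed, {
    p <- as.numeric(stats::runif(S) > 0.5)
    c(0, cumsum(2 * p - 1))
  })
}

#' Rescale a raw random walk into a bounded interval
#'
#' Min-max rescaling: the walk's minimum maps to `lower` and its maximum to
#' `upper`, confining the ant's excursion to the current per-dimension
#' interval. A constant walk maps to the interval midpoint; a degenerate
#' interval (`lower == upper`) gives a constant output at that value.
#'
#' @param walk numeric vector (a [random_walk()]).
#' @param lower,upper interval bounds of the current dimension.
#' @return numeric vector of `length(walk)` inside `[lower, upper]`.
#' @export
normalize_walk <- function(walk, lower, upper) {
  if (upper < lower) stop("`upper` must be >= `lower`", call. = FALSE)
  if (upper == lower) return(rep(lower, length(walk)))
  rng <- range(walk)
  if (rng[1] == rng[2]) return(rep((lower + upper) / 2, length(walk)))
  (walk - rng[1]) * (upper - lower) / (rng[2] - rng[1]) + lower
}

# Exploitation-precision schedule: u grows stepwise with iteration progress
# so the walk interval contracts monotonically.
.alo_u <- function(s, S) {
  t <- s / S
  if (t > 0.95) 6 else if (t > 0.9) 5 else if (t > 0.75) 4 else
    if (t > 0.5) 3 else if (t > 0.1) 2 else 1
}

#' Adaptively shrink the walk bounds
#'
#' Divides the search bounds by the ratio `I = 10^u * s / S` (floored at 1,
#' and defined as 1 at `s = 0`), where `u` increases stepwise with
#' iteration progress (`u = 2, 3, 4, 5, 6` past 10/50/75/90/95 percent of
#' the run; 1 before). This mimics ants sliding toward the antlion: the
#' random-walk hypersphere tightens as iterations proceed.
#'
#' @param a,b lower/upper search bounds (scalars or vectors).
#' @param s current iteration, `0 <= s <= S`.
#' @param S maximum iterations.
#' @param u optional override of the scheduled exponent.
#' @return list with `as_vec` (`a / I`), `bs_vec` (`b / I`) and `ratio_I`.
#' @export
shrink_bounds <- function(a, b, s, S, u = NULL) {
  if (s < 0 || s > S) stop("`s` must lie in [0, S]", call. = FALSE)
  ratio <- if (s == 0) 1 else {
    u <- u %||% .alo_u(s, S)
    max(1, 10^u * s / S)
  }
  list(as_vec = a / ratio, bs_vec = b / ratio, ratio_I = ratio)
}

#' Recenter walk bounds on an antlion
#'
#' Translates the shrunk interval onto the selected antlion's position
#' (`lower + pos`, `upper + pos`), clipping the result to the global
#' `[0, 1]` box. The interval width is preserved except where the clip is
#' active.
#'
#' @param as_vec,bs_vec shrunk lower/upper offsets (e.g. `c(-w, +w)` per
#'   dimension).
#' @param antlion_pos position vector of the chosen antlion.
#' @return list with `lower` and `upper` vectors inside `[0, 1]`.
#' @export
shift_bounds <- function(as_vec, bs_vec, antlion_pos) {
  lower <- pmax(as_vec + antlion_pos, 0)
  upper <- pmin(bs_vec + antlion_pos, 1)
  bad <- upper < lower
  if (any(bad)) {
    mid <- clip01(antlion_pos[bad])
    lower[bad] <- mid
    upper[bad] <- mid
  }
  list(lower = lower, upper = upper)
}

#' Roulette-wheel selection of an antlion
#'
#' Draws one index with probability proportional to a min-shifted copy of
#' the fitness values plus a small `eps` (so the worst individual retains a
#' vanishing chance and all-equal fitness gives a uniform draw). With
#' `minimize = TRUE` the transform is max-shifted instead, favoring low
#' scores.
#'
#' @param fitness numeric vector, one value per antlion.
#' @param minimize are lower values better? Default `FALSE`.
#' @param eps positive floor added to every weight.
#' @return a single index in `1:length(fitness)`.
#' @export
roulette_select <- function(fitness, minimize = FALSE, eps = 1e-12) {
  n <- length(fitness)
  if (n < 1) stop("need at least one antlion", call. = FALSE)
  if (n == 1) return(1L)
  w <- if (minimize) max(fitness) - fitness else fitness - min(fitness)
  w <- w + eps
  sample.int(n, 1L, prob = w)
}

#' Average the antlion-guided and elite-guided walks
#'
#' An ant's new position is the elementwise midpoint of its random walk
#' around the roulette-selected antlion and its walk around the elite.
#'
#' @param walk_roulette_pos,walk_elite_pos position vectors of equal length.
#' @return their elementwise mean.
#' @export
elitism_combine <- function(walk_roulette_pos, walk_elite_pos) {
  stopifnot(length(walk_roulette_pos) == length(walk_elite_pos))
  (walk_roulette_pos + walk_elite_pos) / 2
}

#' Catch prey and rebuild the trap
#'
#' If an ant's score is strictly better (lower) than its antlion's, the
#' antlion relocates to the ant's position (consuming it); if the updated
#' antlion beats the elite, the elite is replaced too. Ties keep the
#' incumbent.
#'
#' @param state list with `antlions` (matrix), `antlion_scores`,
#'   `elite_pos`, `elite_score`.
#' @param ant_pos position vector of the ant.
#' @param ant_score the ant's score (lower is better).
#' @param antlion_idx index of the antlion the ant was assigned to.
#' @return the updated state list.
#' @export
catch_and_rebuild <- function(state, ant_pos, ant_score, antlion_idx) {
  if (ant_score < state$antlion_scores[antlion_idx]) {
    state$antlions[antlion_idx, ] <- ant_pos
    state$antlion_scores[antlion_idx] <- ant_score
    if (ant_score < state$elite_score) {
      state$elite_pos <- ant_pos
      state$elite_score <- ant_score
    }
  }
  state
}

#' Binarize a continuous position into a feature mask
#'
#' Coordinates above 0.5 select the corresponding feature. An all-zero mask
#' is rescued by switching on the first maximal coordinate, so every
#' returned mask selects at least one feature.
#'
#' @param position numeric vector in `[0, 1]`.
#' @return integer 0/1 vector of the same length.
#' @export
binarize <- function(position) {
  bits <- as.integer(position > 0.5)
  if (sum(bits) == 0L) bits[which.max(position)] <- 1L
  bits
}

#' Wrapper fitness of a feature mask
#'
#' `alpha * (1 - cv_accuracy) + (1 - alpha) * n_selected / d`: the
#' cross-validated 1-NN error on the masked features plus a weak sparsity
#' penalty. Lower is better; an empty mask scores the worst possible 1.
#'
#' @param mask 0/1 vector over the feature columns.
#' @param data a [feature_matrix()].
#' @param spec a [fitness_spec()].
#' @return scalar score in `[0, 1]`.
#' @export
selection_fitness <- function(mask, data, spec = fitness_spec()) {
  d <- ncol(data$values)
  stopifnot(length(mask) == d)
  n_sel <- sum(mask)
  if (n_sel == 0) return(1)
  acc <- knn_fitness(fm_select(data, which(mask == 1L)),
                     k = spec$k, folds = spec$folds, seed = spec$seed)
  spec$alpha * (1 - acc) + (1 - spec$alpha) * n_sel / d
}

#' Selection-fitness configuration
#'
#' @param alpha weight in `(0, 1]` on the classification error; the
#'   remaining `1 - alpha` weights the selected-feature fraction. The
#'   default 0.99 is accuracy-dominant with weak sparsity pressure.
#' @param k,folds,seed 1-NN cross-validation settings (see [knn_fitness()]).
#' @return an object of class `fitness_spec`.
#' @export
fitness_spec <- function(alpha = 0.99, k = 1L, folds = 10L, seed = 1L) {
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]", call. = FALSE)
  structure(list(alpha = alpha, k = k, folds = folds, seed = seed),
            class = "fitness_spec")
}

# Mask-score cache: the fitness is a pure function of the mask, so each
# distinct subset is evaluated once per run.
.make_scorer <- function(data, spec) {
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  function(position) {
    bits <- binarize(position)
    key <- paste(bits, collapse = "")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- selection_fitness(bits, data, spec)
    cache[[key]] <- val
    val
  }
}

#' Exhaustive search over all non-empty feature subsets
#'
#' Exact reference optimizer for small dimensionalities (`d <= 20`
#' enforced): scores every non-empty subset with [selection_fitness()] and
#' returns the best. Used to certify that the metaheuristic attains the
#' global optimum on small problems.
#'
#' @param data a [feature_matrix()].
#' @param spec a [fitness_spec()].
#' @return list with `mask` (0/1 vector) and `score`.
#' @export
exhaustive_mask_search <- function(data, spec = fitness_spec()) {
  d <- ncol(data$values)
  if (d > 20) stop("exhaustive search limited to d <= 20", call. = FALSE)
  best_mask <- NULL
  best_score <- Inf
  for (code in seq_len(2^d - 1)) {
    mask <- as.integer(bitwAnd(code, 2^(seq_len(d) - 1)) > 0)
    sc <- selection_fitness(mask, data, spec)
    if (sc < best_score) {
      best_score <- sc
      best_mask <- mask
    }
  }
  list(mask = best_mask, score = best_score)
}

# One ant's new position: averaged normalized walks around the roulette
# antlion and the elite, inside the current shrunk interval. The walk's
# value at the current iteration index is used, normalized over the whole
# walk's range.
.ant_step <- function(d, S_walk, s, halfw, guide_pos, elite_pos) {
  walk_pos <- function(center) {
    b <- shift_bounds(rep(-halfw, d), rep(halfw, d), center)
    v <- numeric(d)
    for (i in seq_len(d)) {
      w <- random_walk(S_walk)
      v[i] <- normalize_walk(w, b$lower[i], b$upper[i])[s + 1L]
    }
    v
  }
  clip01(elitism_combine(walk_pos(guide_pos), walk_pos(elite_pos)))
}

#' Run the ALO-MD feature selector
#'
#' Full optimizer loop: initialize ants and antlions uniformly in the unit
#' box, then for `S` iterations (i) shrink the walk interval by the ratio
#' `I` (see [shrink_bounds()]), (ii) move each ant to the average of
#' normalized random walks around a roulette-selected antlion and the
#' elite, (iii) optionally apply the mean-deviation (MD) re-seeding step:
#' ants scoring worse than the cohort mean plus its mean absolute
#' deviation are relocated to the elite with one coordinate redrawn
#' uniformly (a stochastic probe of the trap's immediate neighborhood —
#' in mask space, a single-bit perturbation of the elite) and re-scored,
#' (iv) let antlions catch strictly better ants
#' and update the elite. The elite is never discarded, so the reported
#' trace is non-increasing.
#'
#' @param data a [feature_matrix()] with `d >= 2` feature columns.
#' @param spec a [fitness_spec()].
#' @param n_ants,n_antlions population sizes. Default 20 each.
#' @param S iteration count (also the random-walk length). Default 50.
#' @param seed integer seed; fixes the entire run.
#' @param md_enabled apply the mean-deviation re-seeding step? Default
#'   `TRUE`.
#' @return list with `mask` (binarized elite), `score`, `elite_pos`,
#'   `trace` (elite score after each iteration), `n_selected`, and the
#'   call configuration.
#' @export
run_alo_md <- function(data, spec = fitness_spec(), n_ants = 20L,
                       n_antlions = 20L, S = 50L, seed = 1L,
                       md_enabled = TRUE) {
  d <- ncol(data$values)
  if (d < 2) stop("need at least 2 features", call. = FALSE)
  if (n_ants < 1 || n_antlions < 1 || S < 1) {
    stop("population sizes and `S` must be >= 1", call. = FALSE)
  }
  score_of <- .make_scorer(data, spec)
  with_seed(derive_seed(seed, "alo"), {
    antlions <- matrix(stats::runif(n_antlions * d), n_antlions, d)
    antlion_scores <- apply(antlions, 1, score_of)
    best0 <- which.min(antlion_scores)
    state <- list(antlions = antlions,
                  antlion_scores = antlion_scores,
                  elite_pos = antlions[best0, ],
                  elite_score = antlion_scores[best0])
    trace <- numeric(S)
    for (s in seq_len(S)) {
      sh <- shrink_bounds(0, 1, s, S)
      halfw <- (sh$bs_vec - sh$as_vec) / 2
      ants <- matrix(0, n_ants, d)
      ant_scores <- numeric(n_ants)
      guide_idx <- integer(n_ants)
      for (i in seq_len(n_ants)) {
        j <- roulette_select(state$antlion_scores, minimize = TRUE)
        guide_idx[i] <- j
        ants[i, ] <- .ant_step(d, S, s, halfw, state$antlions[j, ],
                               state$elite_pos)
        ant_scores[i] <- score_of(ants[i, ])
      }
      if (md_enabled && n_ants > 1) {
        mu <- mean(ant_scores)
        mad_ <- mean(abs(ant_scores - mu))
        poor <- which(ant_scores > mu + mad_)
        for (i in poor) {
          cand <- state$elite_pos
          cand[sample.int(d, 1L)] <- stats::runif(1)
          ants[i, ] <- cand
          ant_scores[i] <- score_of(cand)
        }
      }
      for (i in seq_len(n_ants)) {
        state <- catch_and_rebuild(state, ants[i, ], ant_scores[i],
                                   guide_idx[i])
      }
      trace[s] <- state$elite_score
    }
    mask <- binarize(state$elite_pos)
    list(mask = mask,
         score = state$elite_score,
         elite_pos = state$elite_pos,
         trace = trace,
         n_selected = sum(mask),
         config = list(n_ants = n_ants, n_antlions = n_antlions, S = S,
                       seed = seed, md_enabled = md_enabled,
                       alpha = spec$alpha))
  })
}
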