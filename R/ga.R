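# Genetic-algorithm hyperparameter search over a declared space, replacing
# manual assignment. Works against any fitness function mapping a named
# parameter list to a score (higher is better), e.g. hold-out accuracy of
# a downstream classifier.

#' Declare one tunable parameter
#'
#' @param name parameter identifier.
#' @param kind `"log"` (continuous, sampled/mutated on the log10 scale,
#'   e.g. learning rate or L2 factor), `"linear"` (continuous, e.g.
#'   momentum), `"integer"` (e.g. mini-batch size or neighborhood size) or
#'   `"categorical"`.
#' @param lower,upper bounds for non-categorical kinds (`lower < upper`;
#'   strictly positive for `"log"`).
#' @param choices non-empty vector for `"categorical"`.
#' @return an object of class `ga_param`.
#' @export
ga_param <- function(name, kind = c("linear", "log", "integer", "categorical"),
                     lower = NULL, upper = NULL, choices = NULL) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (length(choices) < 1) stop("`choices` must be non-empty", call. = FALSE)
  } else {
    if (is.null(lower) || is.null(upper) || lower >= upper) {
      stop("need ordered bounds `lower < upper`", call. = FALSE)
    }
    if (kind == "log" && lower <= 0) {
      stop("log-scale bounds must be positive", call. = FALSE)
    }
  }
  structure(list(name = name, kind = kind, lower = lower, upper = upper,
                 choices = choices),
            class = "ga_param")
}

#' Declare a hyperparameter search space
#'
#' @param ... [ga_param()] objects.
#' @return an object of class `ga_space` (named list of parameters).
#' @export
ga_space <- function(...) {
  params <- list(...)
  stopifnot(all(vapply(params, inherits, logical(1), "ga_param")))
  names(params) <- vapply(params, function(p) p$name, character(1))
  structure(params, class = "ga_space")
}

.ga_sample_one <- function(p) {
  switch(p$kind,
         linear = stats::runif(1, p$lower, p$upper),
         log = 10^stats::runif(1, log10(p$lower), log10(p$upper)),
         integer = sample(seq(as.integer(p$lower), as.integer(p$upper)), 1),
         categorical = p$choices[[sample.int(length(p$choices), 1)]])
}

.ga_clip_one <- function(p, v) {
  switch(p$kind,
         linear = min(max(v, p$lower), p$upper),
         log = min(max(v, p$lower), p$upper),
         integer = as.integer(min(max(round(v), p$lower), p$upper)),
         categorical = v)
}

.ga_mutate_one <- function(p, v) {
  switch(p$kind,
         linear = .ga_clip_one(p, v + stats::rnorm(1, 0, 0.1 * (p$upper - p$lower))),
         log = .ga_clip_one(p, 10^(log10(v) +
           stats::rnorm(1, 0, 0.1 * (log10(p$upper) - log10(p$lower))))),
         integer = .ga_clip_one(p, v + stats::rnorm(1, 0, 0.1 * (p$upper - p$lower))),
         categorical = p$choices[[sample.int(length(p$choices), 1)]])
}

#' Sample an initial GA population
#'
#' Uniform sampling within each parameter's bounds (log-uniform for
#' `"log"` parameters, uniform over choices for categoricals).
#'
#' @param space a [ga_space()].
#' @param pop_size number of chromosomes (>= 2).
#' @param seed optional integer seed.
#' @return list of chromosomes (named lists of parameter values).
#' @export
init_population <- function(space, pop_size, seed = NULL) {
  if (pop_size < 2) stop("`pop_size` must be >= 2", call. = FALSE)
  with_seed(seed, {
    replicate(pop_size, lapply(space, .ga_sample_one), simplify = FALSE)
  })
}

#' Evolve a population toward the best hyperparameters
#'
#' Generational GA with binary tournament selection, uniform crossover,
#' per-gene mutation (Gaussian on continuous/integer genes, resampling on
#' categorical genes) with bound clipping, and top-`elitism_k` carry-over,
#' so the best-so-far fitness is non-decreasing. A chromosome whose fitness
#' evaluation fails is scored `-Inf` and the run continues.
#'
#' @param space a [ga_space()].
#' @param fitness_fn function(named list) -> scalar score, higher better.
#' @param pop_size population size. Default 20.
#' @param generations number of generations (>= 1). Default 30.
#' @param cx_rate uniform-crossover probability. Default 0.8.
#' @param mut_rate per-gene mutation probability. Default 0.1.
#' @param elitism_k chromosomes copied unchanged each generation. Default 2.
#' @param seed integer seed fixing the whole run.
#' @param population optional initial population (else sampled).
#' @return list with `best` (chromosome), `best_fitness`, `trace`
#'   (best-so-far per generation) and `population` (final generation).
#' @export
ga_evolve <- function(space, fitness_fn, pop_size = 20L, generations = 30L,
                      cx_rate = 0.8, mut_rate = 0.1, elitism_k = 2L,
                      seed = 1L, population = NULL) {
  if (generations < 1) stop("`generations` must be >= 1", call. = FALSE)
  safe_fit <- function(ch) {
    tryCatch(as.numeric(fitness_fn(ch)), error = function(e) -Inf)
  }
  with_seed(derive_seed(seed, "ga"), {
    pop <- population %||% init_population(space, pop_size, seed = NULL)
    pop_size <- length(pop)
    elitism_k <- min(elitism_k, pop_size)
    fit <- vapply(pop, safe_fit, numeric(1))
    trace <- numeric(generations)
    for (g in seq_len(generations)) {
      ord <- order(fit, decreasing = TRUE)
      nxt <- pop[ord[seq_len(elitism_k)]]
      tournament <- function() {
        idx <- sample.int(pop_size, 2L)
        if (fit[idx[1]] >= fit[idx[2]]) pop[[idx[1]]] else pop[[idx[2]]]
      }
      while (length(nxt) < pop_size) {
        p1 <- tournament()
        p2 <- tournament()
        child <- p1
        if (stats::runif(1) < cx_rate) {
          take2 <- stats::runif(length(space)) < 0.5
          child[take2] <- p2[take2]
        }
        for (j in seq_along(space)) {
          if (stats::runif(1) < mut_rate) {
            child[[j]] <- .ga_mutate_one(space[[j]], child[[j]])
          }
        }
        nxt[[length(nxt) + 1L]] <- child
      }
      pop <- nxt
      fit <- vapply(pop, safe_fit, numeric(1))
      trace[g] <- max(fit, if (g > 1) trace[g - 1] else -Inf)
    }
    best_idx <- which.max(fit)
    # the elite guarantees the final generation contains the best-so-far
    list(best = pop[[best_idx]], best_fitness = fit[best_idx],
         trace = trace, population = pop)
  })
}
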