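# Small bounded differential-evolution optimizer (rand/1/bin strategy) used
# by the cluster-correction search. Deterministic for a fixed seed.

#' Bounded differential-evolution minimization
#'
#' Classic rand/1/bin differential evolution with reflection at the bounds.
#' Intended for low-dimensional, non-smooth objectives; deterministic for a
#' fixed seed.
#'
#' @param fn objective function of a numeric vector.
#' @param lower,upper bound vectors (equal length).
#' @param seed integer seed.
#' @param n_pop population size (default `10 * d`).
#' @param n_iter number of generations (default 50).
#' @param f differential weight (default 0.7).
#' @param cr crossover probability (default 0.9).
#' @return list with `par` (best point) and `value`.
#' @export
de_optimize <- function(fn, lower, upper, seed = 1L,
                        n_pop = 10L * length(lower), n_iter = 50L,
                        f = 0.7, cr = 0.9) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  pop <- t(t(matrix(runif(n_pop * d), n_pop, d)) * (upper - lower) + lower)
  val <- apply(pop, 1, fn)
  reflect <- function(x) {
    x <- ifelse(x < lower, 2 * lower - x, x)
    x <- ifelse(x > upper, 2 * upper - x, x)
    pmin(upper, pmax(lower, x))
  }
  for (g in seq_len(n_iter)) {
    for (i in seq_len(n_pop)) {
      idx <- sample(setdiff(seq_len(n_pop), i), 3L)
      mutant <- reflect(pop[idx[1], ] + f * (pop[idx[2], ] - pop[idx[3], ]))
      mask <- runif(d) < cr
      mask[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(mask, mutant, pop[i, ])
      tv <- fn(trial)
      if (tv <= val[i]) { pop[i, ] <- trial; val[i] <- tv }
    }
  }
  best <- which.min(val)
  list(par = pop[best, ], value = val[best])
}
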