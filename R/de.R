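#' Differential evolution global minimizer
#'
#' A box-bounded best/1/bin differential-evolution search: each generation,
#' every member is challenged by a trial vector built from the current best
#' member plus a dithered-weight difference of two random members, with
#' binomial crossover. The search stops early when the spread of population
#' energies falls below `tol` times their absolute mean (the usual DE
#' convergence rule), or after `maxiter` generations.
#'
#' Used internally by [stn_fit()] with population size
#' `popsize_factor * k` for a `k`-parameter model, mirroring the standard
#' global-then-local maximum-likelihood protocol for these models.
#'
#' @param fn objective returning a finite scalar (lower is better).
#' @param lower,upper numeric bounds, one per parameter.
#' @param popsize number of population members (at least 4).
#' @param maxiter maximum number of generations.
#' @param tol relative convergence tolerance on population energies.
#' @param mutation range for the dithered differential weight F.
#' @param crossover binomial crossover probability CR.
#' @param init optional matrix (rows = parameter vectors, natural scale) of
#'   members seeded into the initial population, e.g. the optimum of a
#'   nested model.
#' @return List with `par`, `value`, `iterations`, `converged`, and `nfev`.
#' @export
de_optimize <- function(fn, lower, upper, popsize = 40L, maxiter = 1000L,
                        tol = 0.01, mutation = c(0.5, 1), crossover = 0.7,
                        init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  popsize <- max(4L, as.integer(popsize))
  span <- upper - lower
  to_unit <- function(x) ifelse(span > 0, (x - lower) / span, 0.5)
  from_unit <- function(u) lower + u * span

  pop <- matrix(stats::runif(popsize * d), nrow = popsize)
  if (!is.null(init)) {
    init <- matrix(init, ncol = d)
    n_seed <- min(nrow(init), popsize)
    for (s in seq_len(n_seed)) {
      u <- to_unit(pmin(upper, pmax(lower, init[s, ])))
      pop[s, ] <- pmin(1, pmax(0, u))
    }
  }
  energy <- apply(pop, 1, function(u) fn(from_unit(u)))
  nfev <- popsize
  best_i <- which.min(energy)
  converged <- FALSE
  iter <- 0L
  while (iter < maxiter) {
    iter <- iter + 1L
    F <- stats::runif(1, mutation[1], mutation[2])
    for (i in seq_len(popsize)) {
      r <- sample.int(popsize - 1L, 2L)
      r[r >= i] <- r[r >= i] + 1L
      trial <- pop[best_i, ] + F * (pop[r[1], ] - pop[r[2], ])
      cross <- stats::runif(d) < crossover
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, trial, pop[i, ])
      # reflect out-of-bounds components back into the unit box
      bad <- trial < 0 | trial > 1
      if (any(bad)) trial[bad] <- stats::runif(sum(bad))
      e <- fn(from_unit(trial))
      nfev <- nfev + 1L
      if (e <= energy[i]) {
        pop[i, ] <- trial
        energy[i] <- e
        if (e < energy[best_i]) best_i <- i
      }
    }
    if (stats::sd(energy) <= tol * abs(mean(energy)) + 1e-12) {
      converged <- TRUE
      break
    }
  }
  list(par = from_unit(pop[best_i, ]), value = energy[best_i],
       iterations = iter, converged = converged, nfev = nfev)
}
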