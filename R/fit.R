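#' Fitting control parameters
#'
#' Collects the optimizer settings used by [stn_fit()]. The defaults follow
#' the full estimation protocol for these models: differential evolution
#' with a population of `popsize_factor` times the number of parameters
#' and up to `de_maxiter` generations, followed by bounded local refinement
#' of the negative log-likelihood. `alpha` and `kappa` span \[1, 1e20\] and
#' are searched on a log10 scale internally.
#'
#' @param de_maxiter maximum DE generations (default 5000).
#' @param popsize_factor population members per model parameter (default 20).
#' @param de_tol DE early-stop tolerance on the population energy spread.
#' @param mutation,crossover DE mutation dither range and crossover rate.
#' @param refine logical; run L-BFGS-B refinement from the DE optimum.
#' @param refine_maxit iteration cap for the refinement.
#' @param seed integer seed for the stochastic search.
#' @return A list of class `stn_control`.
#' @export
stn_control <- function(de_maxiter = 5000L, popsize_factor = 20L,
                        de_tol = 1e-4, mutation = c(0.5, 1),
                        crossover = 0.7, refine = TRUE,
                        refine_maxit = 200L, seed = 1L) {
  structure(list(de_maxiter = as.integer(de_maxiter),
                 popsize_factor = as.integer(popsize_factor),
                 de_tol = de_tol, mutation = mutation, crossover = crossover,
                 refine = isTRUE(refine), refine_maxit = as.integer(refine_maxit),
                 seed = as.integer(seed)),
            class = "stn_control")
}

# internal <-> natural scale (alpha, kappa on log10)
to_internal <- function(par, space) {
  out <- as.numeric(par)
  out[space$log10] <- log10(out[space$log10])
  out
}
from_internal <- function(par, space) {
  out <- as.numeric(par)
  out[space$log10] <- 10^out[space$log10]
  stats::setNames(out, space$names)
}

TAU_PENALTY <- 1e7

fit_objective <- function(space, grid) {
  d <- grid[grid$included, , drop = FALSE]
  y <- d$y
  coords <- as.matrix(d[, c("x1", "x2", "x3")])
  lgy1 <- lgamma(y + 1)
  function(par_int) {
    par <- from_internal(par_int, space)
    viol <- space$constrain(par)
    pl <- as.list(par)
    mu <- predict_mean(pl, coords, model_id = space$model_id)
    nll <- -sum(nb_logpmf_core(y, mu, pl$alpha, lgy1))
    if (!is.finite(nll)) nll <- 1e12
    if (viol > 0) nll <- nll + TAU_PENALTY * (1 + viol)
    nll
  }
}

# moment-based starting point, and embedding of a homogeneous-model optimum
# into a larger model's parameter vector (feasible, same likelihood)
moment_start <- function(space, grid) {
  y <- grid$y[grid$included]
  m <- max(mean(y), 1e-6)
  v <- stats::var(y)
  a <- if (is.finite(v) && v > m) m^2 / (v - m) else 1e6
  a <- min(max(a, 1), 1e20)
  par <- stats::setNames(numeric(space$k), space$names)
  par["lambda0"] <- min(max(log(m), -15), 200)
  par["alpha"] <- a
  fill_defaults(par, space)
}

fill_defaults <- function(par, space) {
  if ("beta1" %in% space$names && par[["beta1"]] == 0 && par[["beta2"]] == 0) {
    par["beta1"] <- 1 / 3
    par["beta2"] <- 0.5
  }
  if ("tau1" %in% space$names && par[["tau1"]] == 0) {
    par["tau1"] <- 0.3
    par["tau2"] <- 0.7
  }
  if ("kappa" %in% space$names && par[["kappa"]] == 0) par["kappa"] <- 10
  par
}

embed_params <- function(params, space) {
  par <- stats::setNames(numeric(space$k), space$names)
  common <- intersect(names(params), space$names)
  par[common] <- unlist(params)[common]
  fill_defaults(par, space)
}

#' Fit one spatial model to a sector grid
#'
#' Maximum-likelihood fit of one of the four negative-binomial spatial
#' models (see [stn_models]) to the included sectors of a grid. The search
#' runs a seeded differential evolution within the printed parameter bounds
#' (population `popsize_factor * k`, early stopping), then refines the
#' optimum with bounded L-BFGS-B on the negative log-likelihood. The
#' optimum of any nested model supplied via `init` (e.g. the homogeneous
#' Model A when fitting B-D) is injected into the initial population, which
#' guarantees the fitted deviance can never be worse than the nested fit.
#'
#' @param grid a [sector_grid()] (outlier exclusion applied beforehand;
#'   see [exclude_outliers()]).
#' @param model_id one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param control an [stn_control()] list.
#' @param init optional list of named parameter vectors (natural scale)
#'   seeded into the initial population.
#' @return An object of class `stn_fit` with components `model_id`,
#'   `params` (named, natural scale), `nll`, `n`, `k`, `bic`, `seed`,
#'   `converged`, `identifiable`, `p_range` (projection normalization for
#'   Models C/D), and the fitted grid.
#' @seealso [stn_select()] for fitting and comparing all four models.
#' @examples
#' g <- simulate_intensities(model_params("A", lambda0 = log(20), alpha = 10),
#'                           grid_shape = c(5, 5, 5), seed = 1)
#' f <- stn_fit(g, "A", control = stn_control(de_maxiter = 50, seed = 1))
#' coef(f)
#' @export
stn_fit <- function(grid, model_id, control = stn_control(), init = NULL) {
  stopifnot(inherits(grid, "sector_grid"))
  model_id <- match.arg(model_id, MODEL_IDS)
  space <- param_space(model_id)
  n <- sum(grid$included)
  if (n <= space$k) {
    stop("grid has ", n, " included sectors but model ", model_id,
         " needs more than its ", space$k, " parameters", call. = FALSE)
  }
  y <- grid$y[grid$included]
  identifiable <- !(stats::var(y) == 0 && model_id != "A")

  obj <- fit_objective(space, grid)
  seeds <- rbind(to_internal(moment_start(space, grid), space))
  if (!is.null(init)) {
    for (p in init) {
      seeds <- rbind(seeds, to_internal(embed_params(p, space), space))
    }
  }
  set.seed(control$seed)
  de <- de_optimize(obj,
                    lower = to_internal(space$lower, space),
                    upper = to_internal(space$upper, space),
                    popsize = control$popsize_factor * space$k,
                    maxiter = control$de_maxiter,
                    tol = control$de_tol,
                    mutation = control$mutation,
                    crossover = control$crossover,
                    init = seeds)
  best <- de$par
  value <- de$value
  if (control$refine) {
    ref <- tryCatch(
      stats::optim(best, obj, method = "L-BFGS-B",
                   lower = to_internal(space$lower, space),
                   upper = to_internal(space$upper, space),
                   control = list(maxit = control$refine_maxit)),
      error = function(e) NULL)
    if (!is.null(ref) && is.finite(ref$value) && ref$value <= value) {
      best <- ref$par
      value <- ref$value
    }
  }
  params <- from_internal(best, space)
  nll <- nb_neg_loglik(c(as.list(params), model_id = model_id), grid)
  p_range <- if (model_id %in% c("C", "D")) {
    d <- grid[grid$included, , drop = FALSE]
    w <- projection_weights(params[["beta1"]], params[["beta2"]])
    range(as.matrix(d[, c("x1", "x2", "x3")]) %*% w)
  } else NULL

  structure(list(model_id = model_id,
                 params = params,
                 nll = nll,
                 n = n,
                 k = space$k,
                 bic = bic_score(nll, space$k, n),
                 seed = control$seed,
                 converged = de$converged,
                 identifiable = identifiable,
                 feasible = space$constrain(params) == 0,
                 de_iterations = de$iterations,
                 p_range = p_range,
                 grid = grid),
            class = "stn_fit")
}

#' @export
print.stn_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Negative-binomial spatial model %s (%s)\n", x$model_id,
              model_label(x$model_id)))
  cat(sprintf("  specimen %s, marker %s, n = %d included sectors\n",
              attr(x$grid, "specimen_id"), attr(x$grid, "marker"), x$n))
  cat("  coefficients:\n")
  print(round(x$params, digits))
  cat(sprintf("  -logLik = %.*f, k = %d, BIC = %.*f\n",
              digits, x$nll, x$k, digits, x$bic))
  invisible(x)
}

model_label <- function(id) {
  switch(id,
         A = "homogeneous",
         B = "linear gradient",
         C = "three subdivisions",
         D = "sigmoidal gradient")
}

#' @export
coef.stn_fit <- function(object, ...) object$params

#' @export
logLik.stn_fit <- function(object, ...) {
  structure(-object$nll, df = object$k, nobs = object$n, class = "logLik")
}

#' Predicted mean immunoreactivity
#'
#' @param object an `stn_fit`.
#' @param newdata optional data frame with columns `x1, x2, x3`; defaults
#'   to the fitted sectors. For Models C/D the projection axis is normalized
#'   with the min/max learned during fitting.
#' @param type `"response"` for the mean, `"link"` for the linear predictor.
#' @param ... unused.
#' @export
predict.stn_fit <- function(object, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    newdata <- object$grid[object$grid$included, , drop = FALSE]
  }
  coords <- as.matrix(newdata[, c("x1", "x2", "x3")])
  mu <- predict_mean(as.list(object$params), coords,
                     model_id = object$model_id, p_range = object$p_range)
  if (type == "link") log(mu) else mu
}

#' @export
fitted.stn_fit <- function(object, ...) predict(object)

#' Residuals of a fitted spatial model
#'
#' @param object an `stn_fit`.
#' @param type `"pearson"` (default) standardizes by the NB standard
#'   deviation `sqrt(mu + mu^2/alpha)`; `"response"` is `y - mu`;
#'   `"deviance"` uses the NB unit deviance at the fitted dispersion.
#' @param ... unused.
#' @export
residuals.stn_fit <- function(object,
                              type = c("pearson", "response", "deviance"),
                              ...) {
  type <- match.arg(type)
  d <- object$grid[object$grid$included, , drop = FALSE]
  mu <- predict(object)
  y <- d$y
  a <- object$params[["alpha"]]
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu + mu^2 / a),
         deviance = {
           t1 <- ifelse(y > 0, y * log(y / mu), 0)
           t2 <- (y + a) * log((y + a) / (mu + a))
           sign(y - mu) * sqrt(pmax(0, 2 * (t1 - t2)))
         })
}

#' Simulate from a fitted spatial model
#'
#' Draws negative-binomial replicates at the fitted mean surface and
#' dispersion, one column per simulation, rows matching the included
#' sectors.
#'
#' @param object an `stn_fit`.
#' @param nsim number of replicate draws.
#' @param seed optional integer seed.
#' @param ... unused.
#' @export
simulate.stn_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  a <- object$params[["alpha"]]
  out <- as.data.frame(replicate(nsim, stats::rnbinom(length(mu), size = a, mu = mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
summary.stn_fit <- function(object, ...) {
  r <- residuals(object, "pearson")
  structure(list(fit = object,
                 pearson_range = range(r),
                 pearson_sd = stats::sd(r),
                 mean_observed = mean(object$grid$y[object$grid$included]),
                 mean_fitted = mean(predict(object))),
            class = "summary.stn_fit")
}

#' @export
print.summary.stn_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  mean observed %.4g, mean fitted %.4g\n",
              x$mean_observed, x$mean_fitted))
  cat(sprintf("  Pearson residuals: sd %.3f, range [%.2f, %.2f]\n",
              x$pearson_sd, x$pearson_range[1], x$pearson_range[2]))
  cat(sprintf("  DE %sconverged in %d generations (seed %d)\n",
              if (x$fit$converged) "" else "NOT ", x$fit$de_iterations,
              x$fit$seed))
  invisible(x)
}

#' Plot a fitted spatial model
#'
#' Observed sector intensities against the fitted mean, plus the fitted
#' profile along the dominant spatial direction (the normalized projection
#' for Models C/D, the largest-weight coordinate for Model B, `x1` for A).
#'
#' @param x an `stn_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stn_fit <- function(x, ...) {
  d <- x$grid[x$grid$included, , drop = FALSE]
  mu <- predict(x)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(mu, d$y, xlab = "fitted mean", ylab = "observed y",
                 main = paste("Model", x$model_id), ...)
  graphics::abline(0, 1, col = "grey50")
  ax <- switch(x$model_id,
               A = d$x1,
               B = {
                 w <- abs(unlist(x$params[c("lambda1", "lambda2", "lambda3")]))
                 d[[paste0("x", which.max(w))]]
               },
               model_projection(as.list(x$params),
                                as.matrix(d[, c("x1", "x2", "x3")]),
                                x$p_range))
  ord <- order(ax)
  graphics::plot(ax, d$y, xlab = "spatial coordinate", ylab = "y",
                 main = "profile", col = "grey60")
  graphics::lines(ax[ord], mu[ord], lwd = 2)
  invisible(x)
}
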