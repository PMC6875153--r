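#' The four spatial organization models
#'
#' Immunoreactivity counts in the rasterized nucleus are modelled with
#' negative-binomial errors and four alternative log-mean structures over
#' the normalized anatomical coordinates `x1, x2, x3`:
#'
#' * **Model A** (homogeneous): `mu = exp(lambda0)`.
#' * **Model B** (linear gradient):
#'   `mu = exp(lambda0 + lambda1*x1 + lambda2*x2 + lambda3*x3)`.
#' * **Model C** (tripartite, abrupt borders): locations are projected onto
#'   the axis `p = beta1*x1 + beta2'*x2 + beta3'*x3` with simplex weights
#'   `beta2' = beta2*(1 - beta1)`, `beta3' = 1 - beta1 - beta2'`; dummies
#'   `d1 = 1` below the border fraction `tau1` of the (min-max normalized)
#'   projection and `d2 = 1` above `tau2`, and
#'   `mu = exp(lambda0 + lambda1*d1 + lambda2*d2)`.
#' * **Model D** (sigmoidal gradient): the same projection with smooth
#'   border transitions,
#'   `mu = exp(lambda0 + lambda1/(1 + exp(-kappa*(tau1 - p))) +
#'   lambda2/(1 + exp(-kappa*(tau2 - p))))`, where `p` is the normalized
#'   projection and `kappa` the boundary smoothness. As `kappa` grows, both
#'   sigmoids approach steps activating below their border, so Model D
#'   contains a reparameterized Model C as a limit.
#'
#' The observation model is `y ~ NB(mu, alpha)` with shape (gamma rate)
#' dispersion `alpha`: `Var(y) = mu + mu^2/alpha`, giving the Poisson limit
#' as `alpha -> Inf`.
#'
#' @name stn_models
NULL

MODEL_IDS <- c("A", "B", "C", "D")

model_param_names <- function(model_id) {
  switch(model_id,
         A = c("lambda0", "alpha"),
         B = c("lambda0", "lambda1", "lambda2", "lambda3", "alpha"),
         C = c("lambda0", "lambda1", "lambda2", "beta1", "beta2",
               "tau1", "tau2", "alpha"),
         D = c("lambda0", "lambda1", "lambda2", "beta1", "beta2",
               "tau1", "tau2", "kappa", "alpha"),
         stop("unknown model id: ", model_id, call. = FALSE))
}

#' Parameter space of a model
#'
#' Returns the optimization bounds, parameter count and constraint of one of
#' the four models. Bounds: lambda0 in \[-15, 200\] (all models) as are
#' lambda1-2 of Models C-D; lambda1-3 of Model B in \[-2, 2\]; beta1-2 in
#' \[0, 1\]; tau1 in \[0.2, 0.6\] and tau2 in \[0.4, 0.8\] with the middle
#' subdivision constrained to span at least 20% of the projection axis
#' (tau2 - tau1 >= 0.2); kappa and alpha in \[1, 1e20\].
#'
#' @param model_id one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return List with `names`, `lower`, `upper` (natural scale), `k`
#'   (parameter count), `log10` (logical vector marking parameters searched
#'   on a log10 scale), and `constrain(par)` returning the constraint
#'   violation (0 when feasible).
#' @export
param_space <- function(model_id) {
  model_id <- match.arg(model_id, MODEL_IDS)
  nm <- model_param_names(model_id)
  lower <- upper <- stats::setNames(numeric(length(nm)), nm)
  for (p in nm) {
    b <- switch(p,
                lambda0 = c(-15, 200),
                lambda1 = ,
                lambda2 = if (model_id == "B") c(-2, 2) else c(-15, 200),
                lambda3 = c(-2, 2),
                beta1 = ,
                beta2 = c(0, 1),
                tau1 = c(0.2, 0.6),
                tau2 = c(0.4, 0.8),
                kappa = ,
                alpha = c(1, 1e20))
    lower[p] <- b[1]; upper[p] <- b[2]
  }
  constrain <- if (model_id %in% c("C", "D")) {
    function(par) max(0, 0.2 - (par[["tau2"]] - par[["tau1"]]))
  } else {
    function(par) 0
  }
  list(model_id = model_id, names = nm, lower = lower, upper = upper,
       k = length(nm), log10 = nm %in% c("alpha", "kappa"),
       constrain = constrain)
}

#' Projection axis for the subdivision models
#'
#' Collapses the three normalized anatomical coordinates onto the single
#' axis along which subdivision borders are placed:
#' `p = beta1*x1 + beta2'*x2 + beta3'*x3` with simplex weights
#' `beta2' = beta2*(1 - beta1)` and `beta3' = 1 - beta1 - beta2'` (the three
#' weights are nonnegative and sum to 1). The returned `p_norm` is `p`
#' min-max scaled to \[0, 1\] over the supplied locations, the scale on
#' which the border fractions `tau1`, `tau2` live.
#'
#' @param coords numeric matrix (n x 3) of normalized coordinates.
#' @param beta1,beta2 projection weights in \[0, 1\].
#' @return List with `p`, `p_norm`, `weights`, and the `range` of `p` used
#'   for normalization.
#' @export
projection <- function(coords, beta1, beta2) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L)
  if (beta1 < 0 || beta1 > 1 || beta2 < 0 || beta2 > 1) {
    stop("beta1 and beta2 must lie in [0, 1]", call. = FALSE)
  }
  w <- projection_weights(beta1, beta2)
  p <- drop(coords %*% w)
  rng <- range(p)
  if (rng[2] - rng[1] <= 0) {
    stop("degenerate projection axis: all locations project to one point",
         call. = FALSE)
  }
  list(p = p, p_norm = (p - rng[1]) / (rng[2] - rng[1]),
       weights = w, range = rng)
}

projection_weights <- function(beta1, beta2) {
  b2p <- beta2 * (1 - beta1)
  c(beta1, b2p, 1 - beta1 - b2p)
}

# linear predictor clamp; keeps exp() finite with lambda0 bounded at 200
ETA_CLAMP <- 700

#' Model mean surface
#'
#' Evaluates the per-sector mean `mu > 0` of one of the four models at the
#' given normalized coordinates. The linear predictor is clamped to
#' \[-700, 700\] before exponentiation so the mean is always finite.
#'
#' @param params named list or vector of model parameters (see
#'   [param_space()] for the fields of each model).
#' @param coords numeric matrix (n x 3) of normalized coordinates.
#' @param model_id model identifier; defaults to `params$model_id`.
#' @param p_range optional fixed min/max of the raw projection used to
#'   normalize `p` (so a fitted axis can be applied to new locations).
#' @return Numeric vector of means.
#' @export
predict_mean <- function(params, coords, model_id = NULL, p_range = NULL) {
  params <- as.list(params)
  if (is.null(model_id)) model_id <- params$model_id
  model_id <- match.arg(model_id, MODEL_IDS)
  coords <- as.matrix(coords)
  eta <- switch(model_id,
    A = rep(params$lambda0, nrow(coords)),
    B = params$lambda0 + params$lambda1 * coords[, 1] +
        params$lambda2 * coords[, 2] + params$lambda3 * coords[, 3],
    C = ,
    D = {
      pr <- model_projection(params, coords, p_range)
      if (model_id == "C") {
        d1 <- as.numeric(pr < params$tau1)
        d2 <- as.numeric(pr > params$tau2)
        params$lambda0 + params$lambda1 * d1 + params$lambda2 * d2
      } else {
        # 1/(1+exp(-z)) is overflow-safe: exp(Inf) -> Inf gives weight 0
        s1 <- 1 / (1 + exp(-params$kappa * (params$tau1 - pr)))
        s2 <- 1 / (1 + exp(-params$kappa * (params$tau2 - pr)))
        params$lambda0 + params$lambda1 * s1 + params$lambda2 * s2
      }
    })
  exp(pmin(ETA_CLAMP, pmax(-ETA_CLAMP, eta)))
}

model_projection <- function(params, coords, p_range = NULL) {
  w <- projection_weights(params$beta1, params$beta2)
  p <- drop(as.matrix(coords) %*% w)
  if (is.null(p_range)) p_range <- range(p)
  if (p_range[2] - p_range[1] <= 0) {
    # degenerate axis: all sectors in the middle subdivision
    return(rep(0.5, length(p)))
  }
  (p - p_range[1]) / (p_range[2] - p_range[1])
}

#' Negative-binomial log-density (shape parameterization)
#'
#' Log-density of `y ~ NB(mu, alpha)` with `Var = mu + mu^2/alpha`, in the
#' gamma-function form that accepts non-integer `y` (continuous
#' densitometric intensities). For `alpha > 1e8` a Stirling-series expansion
#' of `lgamma(y + alpha) - lgamma(alpha)` is used, which keeps the Poisson
#' limit accurate where the naive difference of lgamma values loses all
#' precision.
#'
#' @param y nonnegative observations (not necessarily integer).
#' @param mu positive means.
#' @param alpha positive dispersion (shape); larger is closer to Poisson.
#' @return Vector of log-densities.
#' @export
nb_logpmf <- function(y, mu, alpha) {
  if (any(!is.finite(y)) || any(y < 0)) stop("y must be finite, >= 0", call. = FALSE)
  if (alpha <= 0 || !is.finite(alpha)) stop("alpha must be positive and finite", call. = FALSE)
  nb_logpmf_core(y, mu, alpha, lgamma(y + 1))
}

nb_logpmf_core <- function(y, mu, alpha, lgy1) {
  mu <- pmax(mu, 1e-300)
  log_ratio <- if (alpha > 1e8) {
    # lgamma(a+y)-lgamma(a) via Stirling: accurate to O(y^3/a^2)
    l1p <- log1p(y / alpha)
    (alpha + y - 0.5) * l1p + y * (log(alpha) - 1) +
      1 / (12 * (alpha + y)) - 1 / (12 * alpha)
  } else {
    lgamma(alpha + y) - lgamma(alpha)
  }
  log_ratio - lgy1 - alpha * log1p(mu / alpha) +
    y * (log(mu) - log(alpha) - log1p(mu / alpha))
}

#' Negative log-likelihood of a model on a sector grid
#'
#' Sum of negative NB log-densities over the *included* sectors of a grid,
#' with the model mean surface evaluated at the sector coordinates.
#'
#' @param params named list/vector of parameters including `alpha`.
#' @param grid a [sector_grid()].
#' @param model_id model identifier; defaults to `params$model_id`.
#' @return Scalar negative log-likelihood (finite for valid inputs).
#' @export
nb_neg_loglik <- function(params, grid, model_id = NULL) {
  params <- as.list(params)
  if (is.null(model_id)) model_id <- params$model_id
  d <- grid[grid$included, , drop = FALSE]
  mu <- predict_mean(params, as.matrix(d[, c("x1", "x2", "x3")]),
                     model_id = model_id)
  -sum(nb_logpmf(d$y, mu, params$alpha))
}
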