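#' Construct a model parameter set
#'
#' Builds and validates a named parameter list for one of the four spatial
#' models, used both as fitting truth in the synthetic generator and as
#' input to [predict_mean()] / [nb_neg_loglik()]. Unsupplied parameters
#' take neutral defaults (`lambda* = 0`, `beta1 = 1/3`, `beta2 = 0.5`,
#' `tau = (0.3, 0.7)`, `kappa = 10`, `alpha = 10`).
#'
#' @param model_id one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param lambda0 log-scale intercept.
#' @param ... further model parameters by name (see [param_space()]).
#' @param alpha NB dispersion (shape), > 0.
#' @return Named list with class `model_params` including `model_id`.
#' @examples
#' model_params("B", lambda0 = log(30), lambda1 = 1, lambda2 = -1)
#' @export
model_params <- function(model_id, lambda0 = 0, ..., alpha = 10) {
  model_id <- match.arg(model_id, MODEL_IDS)
  space <- param_space(model_id)
  neutral <- c(lambda0 = 0, lambda1 = 0, lambda2 = 0, lambda3 = 0,
               beta1 = 1 / 3, beta2 = 0.5, tau1 = 0.3, tau2 = 0.7,
               kappa = 10, alpha = 10)
  par <- as.list(neutral[space$names])
  par$lambda0 <- lambda0
  par$alpha <- alpha
  extra <- list(...)
  unknown <- setdiff(names(extra), space$names)
  if (length(unknown) > 0L) {
    stop("parameter(s) not in model ", model_id, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  par[names(extra)] <- extra
  if (par$alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (model_id %in% c("C", "D") && par$tau1 >= par$tau2) {
    stop("tau1 must be below tau2", call. = FALSE)
  }
  structure(c(par, list(model_id = model_id)), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model", x$model_id, "parameters:\n")
  v <- unlist(x[model_param_names(x$model_id)])
  print(v)
  invisible(x)
}
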