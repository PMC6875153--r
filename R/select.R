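#' Bayesian information criterion
#'
#' `BIC = 2 * nll + k * log(n)` for a fit with negative log-likelihood
#' `nll`, `k` parameters and `n` observations. Lower values indicate a more
#' parsimonious trade-off between fit quality and complexity.
#'
#' @param nll negative log-likelihood at the optimum.
#' @param k number of model parameters.
#' @param n number of observations (included sectors).
#' @return Scalar BIC.
#' @export
bic_score <- function(nll, k, n) {
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  2 * nll + k * log(n)
}

#' BIC weights
#'
#' Normalized exponential model weights
#' `w_i = exp(-Delta_i/2) / sum_k exp(-Delta_k/2)` with
#' `Delta_i = BIC_i - min(BIC)`, computed on the differences so the weights
#' are overflow-safe and invariant to adding a constant to all BICs. They
#' can be read as the probability that model i generated the data, assuming
#' the generating model is among the candidates.
#'
#' @param bics numeric vector of per-model BICs (at least one finite).
#' @return Weights in (0, 1\] summing to 1, same names as `bics`.
#' @export
wbic_weights <- function(bics) {
  if (!any(is.finite(bics))) stop("all BICs are non-finite", call. = FALSE)
  delta <- bics - min(bics, na.rm = TRUE)
  w <- exp(-delta / 2)
  w[!is.finite(bics)] <- 0
  w / sum(w)
}

# exact correspondence between the threshold model C and the steep-sigmoid
# limit of Model D: regionwise log-means (lo, mid, hi) match under
# lambda0_D = lambda0_C + lambda2_C, lambda2_D = -lambda2_C
map_c_to_d <- function(p) {
  list(lambda0 = p[["lambda0"]] + p[["lambda2"]], lambda1 = p[["lambda1"]],
       lambda2 = -p[["lambda2"]], beta1 = p[["beta1"]], beta2 = p[["beta2"]],
       tau1 = p[["tau1"]], tau2 = p[["tau2"]], kappa = 1e6,
       alpha = p[["alpha"]])
}

map_d_to_c <- function(p) {
  list(lambda0 = p[["lambda0"]] + p[["lambda2"]], lambda1 = p[["lambda1"]],
       lambda2 = -p[["lambda2"]], beta1 = p[["beta1"]], beta2 = p[["beta2"]],
       tau1 = p[["tau1"]], tau2 = p[["tau2"]], alpha = p[["alpha"]])
}

# deterministic preference: lowest BIC; ties -> fewer parameters, then
# alphabetical model id
pick_preferred <- function(bics, ks) {
  o <- order(bics, ks, names(bics))
  names(bics)[o[1]]
}

#' Fit and compare the four spatial models on one grid
#'
#' Fits Models A-D by [stn_fit()] and ranks them by BIC. Model A is fitted
#' first and its optimum is injected into the initial populations of the
#' larger models, so the best-found likelihood is monotone over the nesting
#' (Models B-D can never fit worse than A). Ties in BIC are broken toward
#' the model with fewer parameters, then alphabetically.
#'
#' @param grid a [sector_grid()].
#' @param models subset of `c("A","B","C","D")` to compare.
#' @param control an [stn_control()].
#' @return An object of class `stn_selection`: list with `fits`, a `table`
#'   (model, k, nll, bic, wbic), and `preferred`.
#' @examples
#' g <- simulate_intensities(model_params("B", lambda0 = log(30), lambda1 = 1),
#'                           grid_shape = c(6, 6, 6), seed = 2)
#' sel <- stn_select(g, control = stn_control(de_maxiter = 60, seed = 1,
#'                                            popsize_factor = 8))
#' sel$preferred
#' @export
stn_select <- function(grid, models = MODEL_IDS, control = stn_control()) {
  models <- match.arg(models, MODEL_IDS, several.ok = TRUE)
  models <- MODEL_IDS[MODEL_IDS %in% models]
  fits <- list()
  base_init <- NULL
  for (m in models) {
    init <- base_init
    if (m == "D" && !is.null(fits[["C"]])) {
      # a threshold optimum is a steep-sigmoid optimum: seed it
      init <- c(init, list(map_c_to_d(fits[["C"]]$params)))
    }
    fits[[m]] <- stn_fit(grid, m, control = control, init = init)
    if (m == "A") base_init <- list(as.list(fits[["A"]]$params))
  }
  if (!is.null(fits[["C"]]) && !is.null(fits[["D"]])) {
    # polish C from the (reparameterized) D optimum so the C-vs-D decision
    # reflects the likelihoods, not which search got luckier
    ctl0 <- control
    ctl0$de_maxiter <- 0L
    c2 <- stn_fit(grid, "C", control = ctl0,
                  init = c(base_init,
                           list(map_d_to_c(fits[["D"]]$params),
                                as.list(fits[["C"]]$params))))
    if (c2$nll < fits[["C"]]$nll) fits[["C"]] <- c2
  }
  tab <- data.frame(model = names(fits),
                    k = vapply(fits, `[[`, 0, "k"),
                    nll = vapply(fits, `[[`, 0, "nll"),
                    bic = vapply(fits, `[[`, 0, "bic"),
                    row.names = NULL)
  tab$wbic <- wbic_weights(stats::setNames(tab$bic, tab$model))
  preferred <- pick_preferred(stats::setNames(tab$bic, tab$model),
                              stats::setNames(tab$k, tab$model))
  structure(list(fits = fits, table = tab, preferred = preferred,
                 specimen_id = attr(grid, "specimen_id"),
                 marker = attr(grid, "marker")),
            class = "stn_selection")
}

#' @export
print.stn_selection <- function(x, digits = 4, ...) {
  cat(sprintf("Model comparison: specimen %s, marker %s\n",
              x$specimen_id, x$marker))
  tab <- x$table
  tab$nll <- round(tab$nll, digits)
  tab$bic <- round(tab$bic, digits)
  tab$wbic <- round(tab$wbic, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Preferred model (lowest BIC): %s (%s)\n",
              x$preferred, model_label(x$preferred)))
  invisible(x)
}

#' @export
summary.stn_selection <- function(object, ...) {
  print(object, ...)
}

#' @export
plot.stn_selection <- function(x, ...) {
  graphics::barplot(stats::setNames(x$table$wbic, x$table$model),
                    ylab = "BIC weight", xlab = "model",
                    main = sprintf("%s / %s (preferred: %s)",
                                   x$specimen_id, x$marker, x$preferred),
                    ...)
  invisible(x)
}

#' Model selection across a whole study
#'
#' Runs [stn_select()] on every (specimen, marker) grid and collects a
#' preference table: one row per grid with the four BICs, BIC weights and
#' the preferred model.
#'
#' @param grids list of [sector_grid()] objects (e.g. from
#'   [generate_study()] or [read_sector_table()]).
#' @param models models to compare.
#' @param control an [stn_control()]; each grid gets a distinct seed
#'   derived from `control$seed`.
#' @param exclude apply [exclude_outliers()] to each grid first.
#' @return An object of class `stn_preferences`: data frame with columns
#'   `specimen`, `marker`, `preferred`, `bic_A..D`, `wbic_A..D`.
#' @export
select_study <- function(grids, models = MODEL_IDS,
                         control = stn_control(), exclude = TRUE) {
  stopifnot(length(grids) > 0L)
  rows <- vector("list", length(grids))
  for (idx in seq_along(grids)) {
    g <- grids[[idx]]
    if (exclude) g <- exclude_outliers(g)
    ctl <- control
    ctl$seed <- derive_seed(control$seed, idx)
    sel <- stn_select(g, models = models, control = ctl)
    row <- data.frame(specimen = sel$specimen_id, marker = sel$marker,
                      preferred = sel$preferred)
    for (m in sel$table$model) {
      row[[paste0("bic_", m)]] <- sel$table$bic[sel$table$model == m]
      row[[paste0("wbic_", m)]] <- sel$table$wbic[sel$table$model == m]
    }
    rows[[idx]] <- row
  }
  structure(do.call(rbind, rows), class = c("stn_preferences", "data.frame"))
}

#' Tally model preferences
#'
#' Percentage of specimen/marker combinations preferring each model, over
#' the full grid of combinations.
#'
#' @param x an `stn_preferences` table from [select_study()], a data frame
#'   with a `preferred` column, a character matrix of model labels
#'   (specimens x markers), or a character vector of labels.
#' @return Named numeric vector of percentages over models A-D (summing
#'   to 100).
#' @examples
#' tally_preferences(published_preferences())
#' @export
tally_preferences <- function(x) {
  labels <- if (is.character(x)) {
    as.vector(x)
  } else if (is.matrix(x)) {
    as.vector(x)
  } else if (is.data.frame(x) && "preferred" %in% names(x)) {
    x$preferred
  } else if (is.data.frame(x)) {
    unlist(x[vapply(x, is.character, TRUE)], use.names = FALSE)
  } else {
    stop("cannot interpret preference input", call. = FALSE)
  }
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) stop("empty preference table", call. = FALSE)
  bad <- setdiff(unique(labels), MODEL_IDS)
  if (length(bad) > 0L) {
    stop("unknown model label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(labels, levels = MODEL_IDS))
  stats::setNames(100 * as.vector(counts) / length(labels), MODEL_IDS)
}

#' Marginal preference winners
#'
#' Aggregates a study preference table into per-specimen, per-marker and
#' overall winners, each defined as the model with the highest mean BIC
#' weight across the margin (ties broken toward the simpler model).
#' With `method = "bic"` the winner is the lowest mean BIC instead.
#'
#' @param table an `stn_preferences` data frame from [select_study()] with
#'   complete `wbic_*` columns.
#' @param method `"wbic"` (default) or `"bic"`.
#' @return List with data frames `by_specimen`, `by_marker`, and `overall`.
#' @export
aggregate_preferences <- function(table, method = c("wbic", "bic")) {
  method <- match.arg(method)
  cols <- paste0(if (method == "wbic") "wbic_" else "bic_", MODEL_IDS)
  cols <- cols[cols %in% names(table)]
  if (length(cols) == 0L) stop("no per-model score columns found", call. = FALSE)
  complete <- stats::complete.cases(table[, cols])
  if (!all(complete)) {
    warning(sum(!complete), " incomplete row(s) excluded from aggregation")
    table <- table[complete, , drop = FALSE]
  }
  ks <- vapply(sub("^(wbic|bic)_", "", cols),
               function(m) param_space(m)$k, 0)
  winner <- function(d) {
    m <- colMeans(d[, cols, drop = FALSE])
    score <- if (method == "wbic") -m else m
    ids <- sub("^(wbic|bic)_", "", cols)
    ids[order(score, ks, ids)][1]
  }
  by_spec <- do.call(rbind, lapply(split(table, table$specimen), function(d) {
    data.frame(specimen = d$specimen[1], winner = winner(d))
  }))
  by_marker <- do.call(rbind, lapply(split(table, table$marker), function(d) {
    data.frame(marker = d$marker[1], winner = winner(d))
  }))
  rownames(by_spec) <- rownames(by_marker) <- NULL
  list(by_specimen = by_spec, by_marker = by_marker,
       overall = winner(table))
}

#' Published preferred-model grid
#'
#' The preferred-model label grid reported for the seven-specimen,
#' twelve-marker post-mortem STN immunohistochemistry study (rows =
#' specimens, columns = protein markers; each cell is the model with the
#' lowest BIC for that combination). Shipped as a plain-text fixture so the
#' preference tally can be reproduced without refitting the tissue data.
#'
#' @return Character matrix (7 specimens x 12 markers) of model labels.
#' @export
published_preferences <- function() {
  path <- system.file("extdata", "published_preferences.csv",
                      package = "stngrad", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  m
}
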