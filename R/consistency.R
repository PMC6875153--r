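#' Standardize sector intensities within one specimen
#'
#' Demeans and scales the sector intensities of one grid to mean 0 and
#' sample standard deviation 1 (divisor `n - 1`), putting specimens with
#' different overall staining intensity on a common scale before the
#' across-specimen consistency tests.
#'
#' @param x a [sector_grid()] (its `y` values, ordered by `(i, j, k)`) or a
#'   numeric vector.
#' @return Numeric vector of standardized values.
#' @export
standardize_sectors <- function(x) {
  if (inherits(x, "sector_grid")) {
    x <- x[order(x$i, x$j, x$k), ]
    v <- x$y
  } else {
    v <- as.numeric(x)
  }
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize: sector values have zero variance",
         call. = FALSE)
  }
  (v - mean(v)) / s
}

#' Per-sector one-sample t tests across specimens
#'
#' Given standardized sector vectors from several specimens (rows =
#' specimens, columns = sectors), tests each sector's mean against zero
#' with a two-sided one-sample t test (`df = n_specimens - 1`). Sectors
#' whose values are identical across specimens are degenerate: a constant
#' zero gives `t = 0, p = 1`; a constant non-zero mean has no defined test
#' and is flagged `NA` (excluded from the FDR family downstream).
#'
#' @param mat numeric matrix, specimens x sectors.
#' @return Data frame with columns `sector`, `t`, `p`.
#' @export
sector_ttests <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least two specimens", call. = FALSE)
  res <- apply(mat, 2, function(v) {
    s <- stats::sd(v)
    if (s == 0) {
      if (mean(v) == 0) c(t = 0, p = 1) else c(t = NA_real_, p = NA_real_)
    } else {
      ht <- stats::t.test(v, mu = 0)
      c(t = unname(ht$statistic), p = ht$p.value)
    }
  })
  data.frame(sector = seq_len(ncol(mat)), t = res["t", ], p = res["p", ],
             row.names = NULL)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with significance flags at the given
#' threshold; `NA` p-values are excluded from the family and stay `NA`.
#'
#' @param p p-values in \[0, 1\] (may contain `NA`).
#' @param q significance threshold on the adjusted values (default 0.05).
#' @return Data frame with columns `p`, `q`, `significant`.
#' @export
fdr_adjust <- function(p, q = 0.05) {
  if (length(p) == 0L) {
    return(data.frame(p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  qv <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q = qv, significant = !is.na(qv) & qv < q)
}

#' Across-specimen consistency of a marker's spatial pattern
#'
#' The coarse-sector consistency analysis for one protein marker: each
#' specimen's sector grid (typically 3x3x3 = 27 sectors) is standardized
#' within specimen, each sector is tested across specimens with a
#' two-sided one-sample t test against zero, and the per-marker family of
#' sector p-values receives a Benjamini-Hochberg FDR correction.
#' Significant sectors indicate consistently altered local
#' immunoreactivity.
#'
#' @param grids list of [sector_grid()] objects for the same marker, one
#'   per specimen, with identical sector layouts.
#' @param q FDR significance threshold (default 0.05).
#' @return An object of class `stn_consistency`: data frame with columns
#'   `marker`, `i`, `j`, `k`, `t`, `p`, `q`, `significant`, and attribute
#'   `n_specimens`.
#' @export
consistency_test <- function(grids, q = 0.05) {
  stopifnot(length(grids) >= 2L)
  marker <- attr(grids[[1]], "marker")
  layout <- grids[[1]][order(grids[[1]]$i, grids[[1]]$j, grids[[1]]$k),
                       c("i", "j", "k")]
  mat <- t(vapply(grids, function(g) {
    gl <- g[order(g$i, g$j, g$k), c("i", "j", "k")]
    if (!identical(unname(as.matrix(gl)), unname(as.matrix(layout)))) {
      stop("specimens have different sector layouts", call. = FALSE)
    }
    standardize_sectors(g)
  }, numeric(nrow(layout))))
  tt <- sector_ttests(mat)
  fd <- fdr_adjust(tt$p, q = q)
  out <- data.frame(marker = marker, layout, t = tt$t, p = tt$p,
                    q = fd$q, significant = fd$significant,
                    row.names = NULL)
  structure(out, n_specimens = length(grids), q_threshold = q,
            class = c("stn_consistency", "data.frame"))
}

#' @export
print.stn_consistency <- function(x, ...) {
  cat(sprintf("Consistency analysis: marker %s, %d specimens, %d sectors, %d significant (q < %g)\n",
              x$marker[1], attr(x, "n_specimens"), nrow(x),
              sum(x$significant, na.rm = TRUE), attr(x, "q_threshold")))
  NextMethod()
  invisible(x)
}
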