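#' Sector grids
#'
#' A sector grid holds the rasterized immunoreactivity of one specimen and
#' one protein marker: one row per occupied sector of a `k1 x k2 x k3`
#' division of the nucleus, with 0-based sector indices `i, j, k`, normalized
#' axis coordinates `x1, x2, x3` in \[0, 1\] (rostrocaudal, first and second
#' in-plane principal axes), a nonnegative count-like intensity `y`, and an
#' `included` flag used by outlier exclusion.
#'
#' @param records data frame with columns `i, j, k, x1, x2, x3, y` and
#'   optionally `included` (defaults to `TRUE`).
#' @param specimen_id specimen label.
#' @param marker protein marker label.
#' @param shape integer triple, the number of sector divisions per axis.
#'   Defaults to `max(index) + 1` per axis.
#' @return An object of class `sector_grid`: the records data frame with
#'   `specimen_id`, `marker` and `shape` attributes.
#' @examples
#' rec <- expand.grid(i = 0:2, j = 0:2, k = 0:2)
#' rec$x1 <- (rec$i + 0.5) / 3; rec$x2 <- (rec$j + 0.5) / 3
#' rec$x3 <- (rec$k + 0.5) / 3; rec$y <- rpois(27, 20)
#' g <- sector_grid(rec, "spec1", "CALR")
#' dim(g)
#' @export
sector_grid <- function(records, specimen_id, marker, shape = NULL) {
  stopifnot(is.data.frame(records))
  needed <- c("i", "j", "k", "x1", "x2", "x3", "y")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("sector grid is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(records$included)) records$included <- TRUE
  records <- records[, c(needed, "included")]
  records$i <- as.integer(records$i)
  records$j <- as.integer(records$j)
  records$k <- as.integer(records$k)
  records$included <- as.logical(records$included)
  if (is.null(shape)) {
    shape <- c(max(records$i), max(records$j), max(records$k)) + 1L
  }
  shape <- as.integer(shape)
  g <- structure(records,
                 specimen_id = as.character(specimen_id),
                 marker = as.character(marker),
                 shape = shape,
                 class = c("sector_grid", "data.frame"))
  validate_sector_grid(g)
  g
}

#' Validate a sector grid
#'
#' Checks the structural invariants of a [sector_grid()]: indices within the
#' grid shape, no duplicate sectors, nonnegative intensities, coordinates in
#' \[0, 1\] that are monotone with the sector index along each axis.
#'
#' @param g a `sector_grid`.
#' @return `g`, invisibly; errors describe the first violated invariant.
#' @export
validate_sector_grid <- function(g) {
  stopifnot(inherits(g, "sector_grid"))
  shape <- attr(g, "shape")
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("grid shape must be three positive integers", call. = FALSE)
  }
  idx <- cbind(g$i, g$j, g$k)
  if (any(idx < 0L) || any(t(idx) >= shape)) {
    stop("sector indices out of range for shape (",
         paste(shape, collapse = ","), ")", call. = FALSE)
  }
  key <- paste(g$i, g$j, g$k)
  if (anyDuplicated(key)) {
    stop("duplicate sector index (i,j,k) in grid for specimen ",
         attr(g, "specimen_id"), ", marker ", attr(g, "marker"),
         call. = FALSE)
  }
  if (any(!is.finite(g$y)) || any(g$y < 0)) {
    stop("intensity y must be finite and nonnegative", call. = FALSE)
  }
  for (ax in 1:3) {
    x <- g[[paste0("x", ax)]]
    if (any(x < -1e-9) || any(x > 1 + 1e-9)) {
      stop("coordinate x", ax, " outside [0, 1]", call. = FALSE)
    }
    id <- idx[, ax]
    if (max(id) > min(id)) {
      lo <- tapply(x, id, min)
      hi <- tapply(x, id, max)
      ord <- order(as.integer(names(lo)))
      lo <- lo[ord]; hi <- hi[ord]
      if (any(hi[-length(hi)] > lo[-1] + 1e-9)) {
        stop("coordinate x", ax, " is not monotone with sector index",
             call. = FALSE)
      }
    }
  }
  invisible(g)
}

grid_id <- function(g) {
  paste(attr(g, "specimen_id"), attr(g, "marker"), sep = "|")
}

#' @export
print.sector_grid <- function(x, ...) {
  cat(sprintf("Sector grid: specimen %s, marker %s, shape %s, %d sectors (%d included)\n",
              attr(x, "specimen_id"), attr(x, "marker"),
              paste(attr(x, "shape"), collapse = "x"),
              nrow(x), sum(x$included)))
  NextMethod()
  invisible(x)
}

grid_as_table <- function(g) {
  data.frame(specimen = attr(g, "specimen_id"),
             marker = attr(g, "marker"),
             g[, c("i", "j", "k", "x1", "x2", "x3", "y", "included")],
             row.names = NULL)
}

#' Write sector grids to a CSV table
#'
#' Serializes one or more sector grids into the canonical comma-separated
#' table with header `specimen,marker,i,j,k,x1,x2,x3,y,included`, 0-based
#' indices, rows ordered by (specimen, marker, i, j, k). Numeric columns are
#' written with 17 significant digits so that a read/write roundtrip
#' reproduces the doubles exactly.
#'
#' @param grids a `sector_grid` or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_sector_table()]
#' @export
write_sector_table <- function(grids, path) {
  if (inherits(grids, "sector_grid")) grids <- list(grids)
  header <- "specimen,marker,i,j,k,x1,x2,x3,y,included"
  if (length(grids) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  tab <- do.call(rbind, lapply(grids, grid_as_table))
  tab <- tab[order(tab$specimen, tab$marker, tab$i, tab$j, tab$k), ]
  num <- function(v) sprintf("%.17g", v)
  lines <- paste(tab$specimen, tab$marker, tab$i, tab$j, tab$k,
                 num(tab$x1), num(tab$x2), num(tab$x3), num(tab$y),
                 tolower(tab$included), sep = ",")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(path)
}

#' Read sector grids from a CSV table
#'
#' Parses the canonical sector table (see [write_sector_table()]) and returns
#' one validated [sector_grid()] per (specimen, marker) combination. The grid
#' shape is taken as `max(index) + 1` per axis within each combination.
#'
#' @param path path to a delimited sector table.
#' @return Named list of `sector_grid` objects; names are `"specimen|marker"`.
#' @export
read_sector_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("specimen", "marker", "i", "j", "k", "x1", "x2", "x3", "y")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L) {
    stop("sector table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(tab$included)) tab$included <- TRUE
  if (nrow(tab) == 0L) return(structure(list(), names = character(0)))
  keys <- paste(tab$specimen, tab$marker, sep = "|")
  grids <- lapply(split(tab, keys), function(d) {
    sector_grid(d[, c("i", "j", "k", "x1", "x2", "x3", "y", "included")],
                specimen_id = d$specimen[1], marker = d$marker[1])
  })
  grids[unique(keys)]
}
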