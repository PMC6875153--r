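# reduced optimizer budget used throughout the suite; the full protocol
# (popsize 20k, 5000 generations) is the package default
fast_ctl <- function(seed = 1L, maxiter = 400L, popsize = 8L, tol = 1e-3) {
  stn_control(de_maxiter = maxiter, popsize_factor = popsize,
              de_tol = tol, seed = seed)
}

# small deterministic grid: full k^3 lattice with supplied or Poisson-ish y
toy_grid <- function(k = 3L, y = NULL, specimen = "S01", marker = "CALR",
                     seed = 1L) {
  rec <- expand.grid(i = 0:(k - 1), j = 0:(k - 1), k = 0:(k - 1))
  rec$x1 <- (rec$i + 0.5) / k
  rec$x2 <- (rec$j + 0.5) / k
  rec$x3 <- (rec$k + 0.5) / k
  if (is.null(y)) {
    set.seed(seed)
    y <- rpois(nrow(rec), 20)
  }
  rec$y <- y
  sector_grid(rec, specimen_id = specimen, marker = marker,
              shape = c(k, k, k))
}
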