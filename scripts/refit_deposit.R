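#!/usr/bin/env Rscript

# Optional, not part of the test or acceptance runs: recompute the full
# preference table from the deposited 10x10x10 sector data (download the
# archive manually and convert it to the canonical sector-table CSV first;
# see ?read_sector_table for the schema). Runs roughly 84 x 4 fits at the
# full optimizer budget, which takes hours on one CPU.
#
# Usage: Rscript scripts/refit_deposit.R <sector_table.csv> <out_dir>

suppressPackageStartupMessages(library(stngrad))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 2) stop("usage: refit_deposit.R <sector_table.csv> <out_dir>")

grids <- read_sector_table(args[1])
dir.create(args[2], recursive = TRUE, showWarnings = FALSE)

excluded <- lapply(grids, exclude_outliers)
n_total <- sum(vapply(excluded, nrow, 0L))
n_out <- sum(vapply(excluded, function(g) sum(!g$included), 0L))
cat(sprintf("outlier exclusion: %d of %d sectors (%.3f%%)\n",
            n_out, n_total, 100 * n_out / n_total))

prefs <- select_study(excluded, control = stn_control(seed = 1L),
                      exclude = FALSE)
write.csv(as.data.frame(prefs), file.path(args[2], "preferences.csv"),
          row.names = FALSE)
pct <- tally_preferences(prefs)
print(round(pct, 2))
ag <- aggregate_preferences(prefs)
cat("overall preferred model:", ag$overall, "\n")
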