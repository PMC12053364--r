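#!/usr/bin/env Rscript
# Recomputes the calibration diagnostics for the packaged growth and
# hydraulic defaults: the quantities the defaults were tuned against.
#
#   Rscript scripts/calibrate.R [--seeds N] [--t-end DAYS]
#
# Prints, for the oldest (S. Dickkopf) and most modern (Tommi) packaged
# cultivars: day-70 total root length, the day-10-12 whole-root-system
# conductance, the log10 span of Krs over the simulation, and the
# time-averaged percent Krs deficit of the modern cultivar (days 5-70).

suppressPackageStartupMessages(library(rootkrs))

args <- commandArgs(trailingOnly = TRUE)
getArg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else as.numeric(args[i + 1L])
}
n_seeds <- getArg("--seeds", 6)
t_end <- getArg("--t-end", 70)

s <- krsDynamicsSummary(seeds = seq_len(n_seeds), t_end = t_end)

cat(sprintf("replicates: %d, t_end: %g d\n", n_seeds, t_end))
cat(sprintf("day-70 total root length: old %.1f m (calibration bound > 120), modern %.1f m (> 63)\n",
            s$final_length_old_m, s$final_length_modern_m))
cat(sprintf("day-10-12 Krs: old %.3g (measured 1.3e-10), modern %.3g (measured 0.7e-10) m^3 MPa^-1 s^-1\n",
            s$krs_day10_12_old, s$krs_day10_12_modern))
cat(sprintf("log10 Krs span (old cultivar): %.2f (calibration target ~3)\n",
            s$log10_span_old))
cat(sprintf("mean Krs deficit of modern vs old, days 5-70: %.1f %% (measured-panel reference 50.8)\n",
            s$deficit_pct))
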