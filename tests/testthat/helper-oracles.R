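# Independent oracles used across the suite. These deliberately avoid the
# package's fitting code paths.

# brute-force Michaelis-Menten fit: exhaustive search over a (Km, Vmax) grid
mm_grid_oracle <- function(atp, v, km_range = NULL, vmax_range = NULL,
                           n = 160L) {
  if (is.null(km_range)) km_range <- c(max(atp) / 100, 4 * max(atp))
  if (is.null(vmax_range)) vmax_range <- c(max(v) / 2, 3 * max(v))
  kms <- seq(km_range[1L], km_range[2L], length.out = n)
  vmaxs <- seq(vmax_range[1L], vmax_range[2L], length.out = n)
  best <- c(rss = Inf, km = NA, vmax = NA)
  for (km in kms) {
    pred_unit <- atp / (km + atp)
    for (vm in vmaxs) {
      rss <- sum((v - vm * pred_unit)^2)
      if (rss < best["rss"]) best <- c(rss = rss, km = km, vmax = vm)
    }
  }
  best
}

# closed-form OLS slope/intercept (spreadsheet-style)
ols_oracle <- function(x, y) {
  sx <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sx / sum((x - mean(x))^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# simple noiseless exponential curve, built without simulate_spot
exp_curve <- function(y0, ymax, k, cycles = seq(2, 60, 2)) {
  data.frame(cycle = cycles,
             signal = y0 + ymax * (1 - exp(-k * cycles)),
             background = 0)
}

# design for an ATP titration at fixed peptide/enzyme
atp_titration_design <- function(construct_id, enzyme_pmol,
                                 atp_levels = c(0, 25, 50, 100, 200, 400),
                                 replicates = 3L) {
  d <- expand.grid(construct_id = construct_id, enzyme_pmol = enzyme_pmol,
                   atp_uM = atp_levels, replicate = seq_len(replicates),
                   control_type = "none", KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$control_type[d$atp_uM == 0] <- "no_atp"
  d
}
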