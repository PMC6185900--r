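#!/usr/bin/env Rscript
## Stage 2: decompose the stage-1 decays into discrete T2 components.
##
## For each CSV under results/decays/: estimate the component count from the
## ln-signal, fit the bi-exponential model, gate on the nominal SNR stored in
## the file header, and tabulate recovered parameters next to the stored
## truth in results/fits.csv.

library(relaxdry)

files <- list.files(file.path("results", "decays"), pattern = "\\.csv$",
                    full.names = TRUE)
if (!length(files)) stop("run analysis/01_simulate_decays.R first")

rows <- lapply(files, function(f) {
  cv <- read_decay_csv(f)
  k_est <- estimate_component_count(cv)
  fit <- fit_multiexponential(cv, k = 2)
  snr <- cv$meta$snr_nominal
  if (is.character(snr)) snr <- as.numeric(snr)   # "Inf" survives as text
  fit <- gate_by_snr(fit, snr)
  p <- assign_compartments(fit)
  data.frame(curve = sub("\\.csv$", "", basename(f)),
             k_estimated = k_est, snr = snr, accepted = fit$accepted,
             r_squared = fit$r_squared,
             t2_long_ms = fit$model$t2[1], t2_short_ms = fit$model$t2[2],
             icw_pct = p[["icw_pct"]], fw_pct = p[["fw_pct"]],
             truth_icw_pct = cv$meta$truth_long_pct,
             icw_error_pp = p[["icw_pct"]] - cv$meta$truth_long_pct)
})
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(tab, file.path("results", "fits.csv"), row.names = FALSE)

print(tab[, c("curve", "k_estimated", "accepted", "t2_long_ms", "icw_pct",
              "icw_error_pp")], digits = 4)
cat(sprintf("\nlargest |ICW error|: %.2f pp\n", max(abs(tab$icw_error_pp))))
cat("note: the ln-plot regime count is resolution-limited -- the noiseless\n",
    "fresh curve (T2 ratio 2.8, slope change ~10%) reads as one regime,\n",
    "while noisy acquisitions of the same truth typically read as two.\n",
    sep = "")
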