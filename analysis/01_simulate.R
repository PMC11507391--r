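#!/usr/bin/env Rscript

# Step 1: simulate the oil cohort that the rest of the workflow analyses.
# 153 samples, acid values on 0.32-1.59 mg/g (right-skewed, mean ~0.70),
# 512-band reflectance spectra on 870-1720 nm, and a per-sample scene whose
# image texture roughens with AV. Writes the reference table and cohort
# summary; the cohort itself is regenerated from its seed by later steps.

suppressMessages(library(oleospec))
dir.create("results", showWarnings = FALSE)

cohort_seed <- 42
coh <- generate_cohort(n = 153, seed = cohort_seed)

write.csv(coh$reference, "results/reference_avs.csv", row.names = FALSE)

av <- coh$reference$av
summary_tab <- data.frame(
  set = "all", n = length(av),
  av_min = round(min(av), 2), av_max = round(max(av), 2),
  av_mean = round(mean(av), 2), av_sd = round(sd(av), 2))

# the split later steps will share, computed on 2nd-derivative spectra
X2 <- apply_pretreatment(coh$spectra, "2Der")
sp <- ks_split(unclass(X2))
for (part in c("calibration", "prediction")) {
  idx <- sp[[part]]
  summary_tab <- rbind(summary_tab, data.frame(
    set = part, n = length(idx),
    av_min = round(min(av[idx]), 2), av_max = round(max(av[idx]), 2),
    av_mean = round(mean(av[idx]), 2), av_sd = round(sd(av[idx]), 2)))
}
write.csv(summary_tab, "results/cohort_summary.csv", row.names = FALSE)

split_tab <- data.frame(sample_id = coh$reference$sample_id,
                        set = ifelse(seq_len(153) %in% sp$calibration,
                                     "cal", "pred"))
write.csv(split_tab, "results/ks_split.csv", row.names = FALSE)

cat("Simulated cohort (seed ", cohort_seed, "): ", nrow(coh$spectra),
    " samples x ", ncol(coh$spectra), " bands\n", sep = "")
print(summary_tab, row.names = FALSE)
cat("Kennard-Stone 3:2 split:", length(sp$calibration), "calibration /",
    length(sp$prediction), "prediction samples\n")
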