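#!/usr/bin/env Rscript
# The cut-point analysis: on a synthetic 22/26 cohort with five HRV features
# carrying a d = 1.5 group effect, sweep every admissible evaluation-score
# split, count the features that significantly separate the groups at each
# cut, and report the marker table at the best split. A matched null cohort
# shows the selection effect the synthetic baseline exists to expose.
#
# Writes: results/sweep/ (curve, markers, group summary, run metadata)

library(hrvei)

out_dir <- "results/sweep"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

inj <- c("HF", "lnHF", "RSA", "LFp", "LF_HF")
coh <- generate_cohort(cohort_spec(
  n_low = 22, n_high = 26, score_cut = 820,
  effect_map = stats::setNames(rep(1.5, 5), inj), seed = 42
))
write_cohort_csv(coh, out_dir)

sw <- sweep_splits(coh$scores$score, coh$features[, hrv_index_names()],
                   min_group = 5, alpha = c(0.05, 0.01))
write_sweep_csv(sw, out_dir)

cat(sprintf("Swept %d candidate cuts on 48 participants x 21 features.\n",
            nrow(sw$curve)))
cat(sprintf("Best cut: %g points -> %d low / %d high, %d features at p < 0.05 (%d at p < 0.01).\n",
            sw$best$cut_score, sw$best$n_low, sw$best$n_high,
            sw$best$sig_05, sw$best$sig_01))
cat(sprintf("Injected markers recovered at the best split: %d of %d (%s).\n",
            sum(inj %in% sw$markers$feature), length(inj),
            paste(intersect(sw$markers$feature, inj), collapse = ", ")))
cat("\nMarker table:\n")
print(as.data.frame(sw$markers[, c("feature", "source", "stars", "p_value")]),
      row.names = FALSE)

# matched null: same design, no effects — the best-split count stays near
# the binomial false-positive level but above any fixed split's count
null_coh <- generate_cohort(cohort_spec(n_low = 22, n_high = 26, seed = 4242))
null_sw <- sweep_splits(null_coh$scores$score,
                        null_coh$features[, hrv_index_names()])
cat(sprintf("\nNull cohort: best-split count %d (expected false positives per split: %.2f).\n",
            max(null_sw$curve$sig_05), 0.05 * 21))
cat("Counts at a post-hoc best split overstate a fixed split's rate;\n")
cat("compare observed counts against this null sweep, not against 0.05 * 21.\n")
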