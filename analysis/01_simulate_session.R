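#!/usr/bin/env Rscript
# Simulate one participant's stimulus session: 6 min neutral baseline,
# 6 min emotional stimulus, 3 min trailing neutral. The stimulus epoch
# carries a blunted high-frequency (respiratory-band) modulation relative
# to baseline — the vagal-withdrawal pattern the pipeline is built to
# quantify — so later steps have a known effect to find.
#
# Writes: results/session/ecg.csv, annotations.csv, rr_truth.csv + spec YAMLs

library(hrvei)

out_dir <- "results/session"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
set.seed(20260927)

epoch_spec <- list(
  baseline_neutral = rr_gen_spec(820, list(c(amplitude = 45, frequency = 0.25)),
                                 noise_sd = 12, duration = 360, seed = 101),
  stimulus = rr_gen_spec(780, list(c(amplitude = 20, frequency = 0.25),
                                   c(amplitude = 25, frequency = 0.1)),
                         noise_sd = 12, duration = 360, seed = 102),
  post_neutral = rr_gen_spec(810, list(c(amplitude = 40, frequency = 0.25)),
                             noise_sd = 12, duration = 180, seed = 103)
)

# splice the three epochs into one beat-time axis; each epoch contributes
# only beats strictly inside its own span so the seams stay monotone
offset <- 0
beats <- numeric(0)
for (nm in names(epoch_spec)) {
  rr <- generate_rr_series(epoch_spec[[nm]])
  bt <- rr$beat_times
  bt <- bt[bt < epoch_spec[[nm]]$duration - 1e-9] + offset
  if (length(beats)) bt <- bt[-1]
  beats <- c(beats, bt)
  offset <- offset + epoch_spec[[nm]]$duration
}
rr_session <- rr_series(beats, t_start = 0, t_end = 900)

ann <- epoch_table(
  start_s = c(0, 360, 720), end_s = c(360, 720, 900),
  kind = c("baseline_neutral", "stimulus", "post_neutral"),
  domain = c("none", "HAHV", "none")
)

ecg <- synthesize_ecg(rr_session, fs = 500)
write_ecg_csv(ecg, file.path(out_dir, "ecg.csv"))
write_annotations_csv(ann, file.path(out_dir, "annotations.csv"))
write_rr_csv(rr_session, file.path(out_dir, "rr_truth.csv"))
for (nm in names(epoch_spec)) {
  write_spec_yaml(epoch_spec[[nm]], file.path(out_dir, paste0("spec_", nm, ".yaml")))
}

cat(sprintf("Simulated a 15-min session: %d beats, ECG %.0f s at 500 Hz.\n",
            length(rr_session$beat_times), (length(ecg$samples) - 1) / 500))
cat("Baseline HF modulation 45 ms; stimulus HF modulation blunted to 20 ms",
    "with an added 25 ms LF component.\n")
cat("Wrote ECG, annotations, ground-truth RR and spec YAMLs to", out_dir, "\n")
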