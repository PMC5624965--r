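#!/usr/bin/env Rscript
# Flap-rate arithmetic: Strouhal-model predictions vs observed rates for
# the two large woodpeckers, the raw-to-intrinsic chain for the cruising
# video, and frame-count conversions at 60 fps.

library(woodknock)

dir.create("results", showWarnings = FALSE)

rep <- flap_report()
print(rep, row.names = FALSE)
write_flap_report_csv(rep, "results/flap_report.csv")

raw <- raw_flap_rate(15, 2.27)
cat(sprintf("raw flap rate: 15 flaps / 2.27 s = %.2f Hz\n", raw))
cat(sprintf("intrinsic (duty 0.714): %.2f Hz\n", intrinsic_from_raw(raw, 0.714)))

frames <- data.frame(frames_per_flap = c(6, 7, 8, 12))
frames$rate_hz <- rate_from_frames(frames$frames_per_flap, fps = 60)
print(frames, row.names = FALSE)
write.table(frames, "results/frame_rates.csv", sep = ",", quote = FALSE, row.names = FALSE)
cat("wrote results/flap_report.csv and results/frame_rates.csv\n")
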