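#!/usr/bin/env Rscript
# Simulate the two reference forcing regimes of the impact oscillator
# (periodic drive -> drumming; impulsive pulse -> double knock) and write
# the dense trajectories and impact tables.

library(woodknock)

dir.create("results", showWarnings = FALSE)

for (name in c("fig2-periodic", "fig2-impulsive")) {
  cfg <- fig2_preset(name)
  traj <- simulate_oscillator(cfg$params, cfg$forcing, cfg$ic, cfg$settings)
  write_trajectory_csv(traj, file.path("results", paste0(name, "_trajectory.csv")))
  write_impacts_csv(traj, file.path("results", paste0(name, "_impacts.csv")))
  cat(sprintf("%s: %d impacts, first at t = %.3f, last at t = %.3f\n",
              name, nrow(traj$impacts),
              min(traj$impacts$time), max(traj$impacts$time)))
}

# two-panel figure of the solutions, dashed lines at the forcing landmarks
per <- simulate_oscillator(oscillator_params(), forcing_periodic())
imp <- simulate_oscillator(oscillator_params(), forcing_impulsive())
grDevices::pdf("results/fig2_panels.pdf", width = 7, height = 5)
op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
plot(per$times, per$x, type = "l", xlab = "t", ylab = "x",
     main = "periodic forcing")
abline(v = c(2 * pi, 20 * pi), lty = 2)
plot(imp$times, imp$x, type = "l", xlab = "t", ylab = "x",
     main = "impulsive forcing")
abline(v = 20 * pi, lty = 2)
par(op)
grDevices::dev.off()
cat("wrote results/fig2_panels.pdf\n")
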