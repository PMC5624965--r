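# Independent brute-force integrator used to pin the adaptive solver:
# classical fixed-step RK4 with bisection location of wall crossings.
# Deliberately shares no code with simulate_oscillator().
oracle_simulate <- function(p = 0.2, q = 0.3, alpha = 0.8, x0 = 0.2,
                            forcing_fn, t_end = 30 * pi, dt = 1e-3,
                            bisect_tol = 1e-10, y0 = c(0, 0)) {
  f <- function(t, y) c(y[2], forcing_fn(t) - p * y[2] - q * y[1])
  rk4 <- function(t, y, h) {
    k1 <- f(t, y); k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2); k4 <- f(t + h, y + h * k3)
    y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  t <- 0; y <- y0
  times <- numeric(); speed_in <- numeric()
  for (i in seq_len(ceiling(t_end / dt))) {
    y2 <- rk4(t, y, dt)
    if (y2[1] > x0 && y2[2] > 0 && y[1] <= x0) {
      lo <- 0; hi <- dt
      while (hi - lo > bisect_tol) {
        mid <- (lo + hi) / 2
        if (rk4(t, y, mid)[1] > x0) hi <- mid else lo <- mid
      }
      h <- (lo + hi) / 2
      yi <- rk4(t, y, h)
      times <- c(times, t + h); speed_in <- c(speed_in, yi[2])
      yi[2] <- -alpha * yi[2]
      y <- rk4(t + h, yi, dt - h)
    } else {
      y <- y2
    }
    t <- t + dt
  }
  data.frame(time = times, speed_in = speed_in, speed_out = alpha * speed_in)
}

oracle_forcing_periodic <- function(t) if (t > 2 * pi && t < 20 * pi) sin(t) else 0
oracle_forcing_impulsive <- function(t) exp(-(t - 20 * pi)^2)

# Frozen oracle impact tables for the two reference presets
# (regenerate with tools/make-oracle-fixtures.R).
fig2_fixture <- function(name) {
  utils::read.csv(test_path("fixtures", paste0(name, "_impacts.csv")))
}

# Cache adaptive simulations of the presets across test files.
.preset_cache <- new.env(parent = emptyenv())
preset_trajectory <- function(name) {
  if (is.null(.preset_cache[[name]])) {
    cfg <- fig2_preset(name)
    .preset_cache[[name]] <- simulate_oscillator(cfg$params, cfg$forcing,
                                                 cfg$ic, cfg$settings)
  }
  .preset_cache[[name]]
}
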