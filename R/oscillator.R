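#' Oscillator parameters for the drumming model
#'
#' A drumming woodpecker is modelled as a damped harmonic oscillator
#' \deqn{x'' + p x' + q x = R(t)}
#' whose displacement `x` (positive toward the wood) is limited by a rigid
#' wall at `x = x0`, where the bill strikes and rebounds with a coefficient
#' of restitution: the impact replaces the velocity `v` by `-alpha * v`.
#' All quantities are dimensionless; the model illustrates the qualitative
#' behaviours (driven periodic response vs. impulsive transient), not a
#' dimensional mechanics of a real bill and neck.
#'
#' @param damping_p Damping coefficient (rate, >= 0).
#' @param stiffness_q Stiffness coefficient (rate squared, > 0); the
#'   undamped natural angular frequency is `sqrt(q)`.
#' @param restitution_alpha Coefficient of restitution in (0, 1]: the
#'   fraction of impact speed retained after each rebound.
#' @param wall_x0 Wall position (> 0): displacement at which the bill
#'   strikes the wood.
#' @return An object of class `"oscillator_params"`.
#' @seealso [simulate_oscillator()], [fig2_preset()]
#' @export
#' @examples
#' oscillator_params()  # the reference configuration p=0.2, q=0.3, alpha=0.8, x0=0.2
oscillator_params <- function(damping_p = 0.2, stiffness_q = 0.3,
                              restitution_alpha = 0.8, wall_x0 = 0.2) {
  stopifnot(is.numeric(damping_p), length(damping_p) == 1L, is.finite(damping_p),
            is.numeric(stiffness_q), length(stiffness_q) == 1L, is.finite(stiffness_q),
            is.numeric(restitution_alpha), length(restitution_alpha) == 1L,
            is.numeric(wall_x0), length(wall_x0) == 1L, is.finite(wall_x0))
  if (damping_p < 0) stop("damping_p must be >= 0", call. = FALSE)
  if (stiffness_q <= 0) stop("stiffness_q must be > 0", call. = FALSE)
  if (restitution_alpha <= 0 || restitution_alpha > 1)
    stop("restitution_alpha must lie in (0, 1]", call. = FALSE)
  if (wall_x0 <= 0) stop("wall_x0 must be > 0", call. = FALSE)
  structure(list(damping_p = damping_p, stiffness_q = stiffness_q,
                 restitution_alpha = restitution_alpha, wall_x0 = wall_x0),
            class = "oscillator_params")
}

#' Forcing functions R(t)
#'
#' Constructors for the forcing term of the oscillator. The periodic variant
#' is a windowed sinusoid `A * sin(omega * t)` active on the open interval
#' `(t_on, t_off)` and zero outside; it drives sustained drumming. The
#' impulsive variant is a single Gaussian pulse
#' `A * exp(-((t - center) / width)^2)`, the model of the one body thrust
#' behind a Campephilus double knock. Defaults reproduce the reference
#' drumming configuration: unit-amplitude sine on (2*pi, 20*pi) and a unit
#' Gaussian centred at 20*pi with unit width.
#'
#' @param amplitude Peak forcing amplitude.
#' @param angular_frequency Angular frequency of the periodic drive.
#' @param t_on,t_off Open window on which the periodic drive acts
#'   (`t_on < t_off`).
#' @param center Time of the impulsive pulse maximum.
#' @param width Gaussian width of the pulse (> 0).
#' @param fn For `forcing_custom()`, a vectorised function of time
#'   returning the force.
#' @return An object of class `"forcing_spec"`.
#' @export
forcing_periodic <- function(amplitude = 1, angular_frequency = 1,
                             t_on = 2 * pi, t_off = 20 * pi) {
  stopifnot(is.numeric(amplitude), is.numeric(angular_frequency),
            is.numeric(t_on), is.numeric(t_off))
  if (!(t_on < t_off)) stop("t_on must be < t_off", call. = FALSE)
  structure(list(variant = "periodic", amplitude = amplitude,
                 angular_frequency = angular_frequency,
                 t_on = t_on, t_off = t_off),
            class = "forcing_spec")
}

#' @rdname forcing_periodic
#' @export
forcing_impulsive <- function(amplitude = 1, center = 20 * pi, width = 1) {
  stopifnot(is.numeric(amplitude), is.numeric(center), is.numeric(width))
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  structure(list(variant = "impulsive", amplitude = amplitude,
                 center = center, width = width),
            class = "forcing_spec")
}

#' @rdname forcing_periodic
#' @export
forcing_none <- function() {
  structure(list(variant = "none"), class = "forcing_spec")
}

#' @rdname forcing_periodic
#' @export
forcing_custom <- function(fn) {
  if (!is.function(fn)) stop("fn must be a function of time", call. = FALSE)
  structure(list(variant = "custom", fn = fn), class = "forcing_spec")
}

#' Evaluate a forcing function at given times
#'
#' @param spec A [forcing_spec][forcing_periodic] object.
#' @param t Numeric vector of times.
#' @return Numeric vector of forces, same length as `t`.
#' @export
#' @examples
#' evaluate_forcing(forcing_periodic(), pi)       # 0: before onset
#' evaluate_forcing(forcing_periodic(), 5 * pi / 2)  # 1: sine maximum
#' evaluate_forcing(forcing_impulsive(), 20 * pi)    # 1: pulse peak
evaluate_forcing <- function(spec, t) {
  if (!inherits(spec, "forcing_spec")) stop("spec must be a forcing_spec", call. = FALSE)
  stopifnot(is.numeric(t))
  switch(spec$variant,
    periodic = ifelse(t > spec$t_on & t < spec$t_off,
                      spec$amplitude * sin(spec$angular_frequency * t), 0),
    impulsive = spec$amplitude * exp(-((t - spec$center) / spec$width)^2),
    none = rep(0, length(t)),
    custom = {
      out <- spec$fn(t)
      if (!is.numeric(out) || length(out) != length(t))
        stop("custom forcing must return a numeric vector the length of t", call. = FALSE)
      out
    },
    stop("malformed forcing_spec", call. = FALSE))
}

#' Initial conditions and solver settings
#'
#' @param x,v,t Initial displacement, velocity and time. The displacement
#'   must not start beyond the wall of the paired [oscillator_params()].
#' @return An object of class `"initial_conditions"`.
#' @export
initial_conditions <- function(x = 0, v = 0, t = 0) {
  stopifnot(is.numeric(x), is.numeric(v), is.numeric(t),
            all(is.finite(c(x, v, t))))
  structure(list(x = x, v = v, t = t), class = "initial_conditions")
}

#' @rdname initial_conditions
#' @param t_end End of the integration span (> start time).
#' @param rel_tol,abs_tol Relative and absolute tolerances of the adaptive
#'   integrator.
#' @param max_step Largest internal step. Bounded so the solver cannot step
#'   over a narrow forcing pulse from a quiescent state.
#' @param event_tol Time tolerance to which wall crossings are located.
#' @param chatter_speed_eps Impact speeds below this are treated as the bill
#'   coming to rest on the wood: the velocity is zeroed instead of reflected,
#'   truncating the Zeno chattering sequence that a restitution law < 1 can
#'   produce.
#' @param chatter_cap Maximum consecutive sub-`chatter_speed_eps` contacts
#'   before a warning is issued.
#' @param sample_dt Spacing of the dense trajectory output.
#' @export
solver_settings <- function(t_end = 30 * pi, rel_tol = 1e-9, abs_tol = 1e-12,
                            max_step = 1, event_tol = 1e-9,
                            chatter_speed_eps = 1e-6, chatter_cap = 100L,
                            sample_dt = 0.01) {
  stopifnot(rel_tol > 0, abs_tol > 0, max_step > 0, event_tol > 0,
            chatter_speed_eps > 0, chatter_cap >= 1, sample_dt > 0)
  structure(list(t_end = t_end, rel_tol = rel_tol, abs_tol = abs_tol,
                 max_step = max_step, event_tol = event_tol,
                 chatter_speed_eps = chatter_speed_eps,
                 chatter_cap = as.integer(chatter_cap), sample_dt = sample_dt),
            class = "solver_settings")
}

#' Simulate the vibro-impact oscillator
#'
#' Integrates `x'' + p x' + q x = R(t)` with an adaptive solver
#' ([deSolve::ode()], `lsodar`) between impacts. Whenever the displacement
#' reaches the wall `x0` while moving toward it (`v > 0`), the crossing is
#' located by the solver's root finder, an impact is recorded, displacement
#' stays continuous, and the velocity is instantaneously replaced by
#' `-alpha * v`.
#'
#' Sub-threshold contacts (incoming speed below `chatter_speed_eps`) are the
#' bill settling onto the wood: the velocity is zeroed and, if the net force
#' still presses the bill into the wood, the state is held at the wall until
#' the forcing releases it — a sticking phase that truncates the Zeno
#' chattering an `alpha < 1` restitution law can otherwise accumulate.
#' Runs of sub-threshold contacts beyond `chatter_cap` raise a warning.
#'
#' @param params [oscillator_params()].
#' @param forcing A [forcing_spec][forcing_periodic].
#' @param ic [initial_conditions()]; the rest state at `t = 0` by default.
#' @param settings [solver_settings()].
#' @return An object of class `"impact_trajectory"`: a list with `times`,
#'   `x`, `v` (dense output at `sample_dt` spacing) and `impacts`, a
#'   data frame with columns `time`, `speed_in`, `speed_out` ordered in time.
#' @export
#' @examples
#' traj <- simulate_oscillator(oscillator_params(), forcing_impulsive(),
#'                             settings = solver_settings(t_end = 30 * pi))
#' nrow(traj$impacts)  # the short decaying double-knock train
simulate_oscillator <- function(params, forcing, ic = initial_conditions(),
                                settings = solver_settings()) {
  if (!inherits(params, "oscillator_params")) stop("params must be oscillator_params", call. = FALSE)
  if (!inherits(forcing, "forcing_spec")) stop("forcing must be a forcing_spec", call. = FALSE)
  if (!inherits(ic, "initial_conditions")) ic <- do.call(initial_conditions, as.list(ic))
  if (!inherits(settings, "solver_settings")) stop("settings must be solver_settings", call. = FALSE)
  if (ic$x > params$wall_x0)
    stop("initial displacement exceeds the wall position", call. = FALSE)
  if (settings$t_end <= ic$t) stop("t_end must exceed the start time", call. = FALSE)

  p <- params$damping_p; q <- params$stiffness_q
  alpha <- params$restitution_alpha; x0 <- params$wall_x0
  eps <- settings$chatter_speed_eps
  # restart offset from the wall after a rebound, so the crossing just
  # handled is not re-detected as a root at the segment start
  nudge <- max(10 * settings$abs_tol, 1e-12)

  deriv <- function(t, y, parms) {
    list(c(y[2L], evaluate_forcing(forcing, t) - p * y[2L] - q * y[1L]))
  }
  rootfn <- function(t, y, parms) y[1L] - x0

  grid <- seq(ic$t, settings$t_end, by = settings$sample_dt)
  if (grid[length(grid)] < settings$t_end) grid <- c(grid, settings$t_end)
  ng <- length(grid)
  xs <- rep(NA_real_, ng); vs <- rep(NA_real_, ng)

  t_cur <- ic$t
  y <- c(min(ic$x, x0 - nudge), ic$v)
  xs[1L] <- y[1L]; vs[1L] <- y[2L]
  imp_time <- numeric(); imp_speed <- numeric()
  chatter_run <- 0L; chatter_warned <- FALSE

  while (t_cur < settings$t_end - settings$event_tol) {
    seg <- unique(c(t_cur, grid[grid > t_cur + settings$event_tol]))
    if (length(seg) < 2L) break
    out <- deSolve::ode(y = y, times = seg, func = deriv, parms = NULL,
                        method = "lsodar", rtol = settings$rel_tol,
                        atol = settings$abs_tol, hmax = settings$max_step,
                        hini = min(settings$sample_dt, settings$max_step) / 10,
                        maxsteps = 100000L, rootfunc = rootfn)
    if (any(!is.finite(out)))
      stop(sprintf("integration produced non-finite state near t = %g",
                   out[which(!stats::complete.cases(unclass(out)))[1L], 1L]),
           call. = FALSE)
    # store dense samples that fall on the output grid
    m <- match(round((out[, 1L] - ic$t) / settings$sample_dt), round((grid - ic$t) / settings$sample_dt))
    on_grid <- !is.na(m) & abs(grid[ifelse(is.na(m), 1L, m)] - out[, 1L]) < settings$sample_dt * 1e-6
    xs[m[on_grid]] <- out[on_grid, 2L]
    vs[m[on_grid]] <- out[on_grid, 3L]

    troot <- attr(out, "troot")
    if (is.null(troot) || !length(troot)) break  # reached t_end impact-free

    tr <- troot[1L]
    y_root <- out[nrow(out), 2:3]
    v_in <- y_root[2L]
    if (v_in >= eps) {                      # genuine impact: restitution
      chatter_run <- 0L
      imp_time <- c(imp_time, tr)
      imp_speed <- c(imp_speed, v_in)
      y <- c(x0 - nudge, -alpha * v_in)
    } else if (v_in >= 0) {                 # bill settles: chatter handling
      chatter_run <- chatter_run + 1L
      if (chatter_run >= settings$chatter_cap && !chatter_warned) {
        chatter_warned <- TRUE
        warning(sprintf("chatter: %d consecutive wall contacts below speed %g near t = %g; bill treated as resting",
                        chatter_run, eps, tr), call. = FALSE)
      }
      if (evaluate_forcing(forcing, tr) - q * x0 > 0) {
        # net force presses into the wood: stick until the forcing releases
        rest <- grid > tr
        released <- rest & (evaluate_forcing(forcing, grid) - q * x0 < 0)
        xs[rest & !cumsum(released) > 0] <- x0
        vs[rest & !cumsum(released) > 0] <- 0
        if (!any(released)) { t_cur <- settings$t_end; break }
        tr <- grid[which(released)[1L]]
      }
      y <- c(x0 - nudge, 0)
    } else {                                # grazing root moving away
      y <- c(min(y_root[1L], x0 - nudge), v_in)
    }
    t_cur <- tr
  }

  filled <- !is.na(xs)
  impacts <- data.frame(time = imp_time, speed_in = imp_speed,
                        speed_out = alpha * imp_speed)
  structure(list(times = grid[filled], x = xs[filled], v = vs[filled],
                 impacts = impacts, params = params, forcing = forcing,
                 settings = settings),
            class = "impact_trajectory")
}

#' @export
print.impact_trajectory <- function(x, ...) {
  cat(sprintf("<impact_trajectory> t in [%.3g, %.3g], %d samples, %d impacts\n",
              x$times[1L], x$times[length(x$times)], length(x$times), nrow(x$impacts)))
  invisible(x)
}

#' @export
as.data.frame.impact_trajectory <- function(x, ...) {
  data.frame(t = x$times, x = x$x, v = x$v)
}

#' Impact trains
#'
#' `extract_impact_train()` reduces a simulated trajectory to its ordered
#' impact times, the inter-impact intervals, and the pre/post-impact speeds.
#' `impact_train()` builds the same structure from raw vectors, e.g. from a
#' synthetic knock generator, so the cadence tools accept either source.
#'
#' @param traj An `impact_trajectory` from [simulate_oscillator()].
#' @return An object of class `"impact_train"`: list with `times`,
#'   `intervals` (length `n - 1`), `speed_in`, `speed_out`.
#' @export
extract_impact_train <- function(traj) {
  if (!inherits(traj, "impact_trajectory")) stop("traj must be an impact_trajectory", call. = FALSE)
  impact_train(traj$impacts$time, traj$impacts$speed_in, traj$impacts$speed_out)
}

#' @rdname extract_impact_train
#' @param times Ordered impact times.
#' @param speed_in,speed_out Impact speeds just before / after each rebound;
#'   synthetic knock amplitudes may stand in for speeds.
#' @export
impact_train <- function(times, speed_in = NULL, speed_out = NULL) {
  stopifnot(is.numeric(times))
  if (is.unsorted(times, strictly = FALSE)) stop("impact times must be ordered", call. = FALSE)
  n <- length(times)
  if (is.null(speed_in)) speed_in <- rep(NA_real_, n)
  if (is.null(speed_out)) speed_out <- rep(NA_real_, n)
  stopifnot(length(speed_in) == n, length(speed_out) == n)
  structure(list(times = as.numeric(times),
                 intervals = if (n >= 2L) diff(times) else numeric(),
                 speed_in = as.numeric(speed_in),
                 speed_out = as.numeric(speed_out)),
            class = "impact_train")
}

#' Reference drumming and double-knock configurations
#'
#' The two named presets used throughout: a periodically driven drummer
#' (unit sine on the open window `(2*pi, 20*pi)`) and an impulsively driven
#' double-knocker (unit Gaussian pulse at `20*pi`), both with the reference
#' oscillator `p = 0.2, q = 0.3, alpha = 0.8, x0 = 0.2`, rest start at
#' `t = 0`, integrated to `30*pi`.
#'
#' @param name `"fig2-periodic"` or `"fig2-impulsive"`.
#' @return A list with components `params`, `forcing`, `ic`, `settings`
#'   ready to pass to [simulate_oscillator()].
#' @export
fig2_preset <- function(name = c("fig2-periodic", "fig2-impulsive")) {
  name <- match.arg(name)
  list(params = oscillator_params(),
       forcing = if (name == "fig2-periodic") forcing_periodic() else forcing_impulsive(),
       ic = initial_conditions(0, 0, 0),
       settings = solver_settings(t_end = 30 * pi))
}

#' Read an oscillator run configuration
#'
#' Reads a flat YAML config with sections `oscillator`, `forcing`,
#' `initial` and `solver` (all optional; defaults fill in). Unknown keys in
#' any section are rejected. Two shipped configs mirror the named presets:
#' `system.file("extdata", "fig2-periodic.yaml", package = "woodknock")`.
#'
#' @param path Path to the YAML file.
#' @return As [fig2_preset()]: list of `params`, `forcing`, `ic`, `settings`.
#' @export
read_oscillator_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known_sections <- c("oscillator", "forcing", "initial", "solver")
  extra <- setdiff(names(cfg), known_sections)
  if (length(extra)) stop("unknown config section(s): ", paste(extra, collapse = ", "), call. = FALSE)
  take <- function(section, builder, rename = c()) {
    args <- cfg[[section]]
    if (is.null(args)) args <- list()
    for (old in names(rename)) {
      if (old %in% names(args)) {
        args[[rename[[old]]]] <- args[[old]]; args[[old]] <- NULL
      }
    }
    ok <- names(formals(builder))
    extra <- setdiff(names(args), ok)
    if (length(extra)) stop(sprintf("unknown key(s) in [%s]: %s", section,
                                    paste(extra, collapse = ", ")), call. = FALSE)
    do.call(builder, args)
  }
  fargs <- cfg$forcing
  if (is.null(fargs)) fargs <- list(variant = "none")
  variant <- fargs$variant
  if (is.null(variant)) stop("forcing section needs a 'variant' key", call. = FALSE)
  fargs$variant <- NULL
  builder <- switch(variant,
                    periodic = forcing_periodic, impulsive = forcing_impulsive,
                    none = forcing_none,
                    stop("unknown forcing variant: ", variant, call. = FALSE))
  extra <- setdiff(names(fargs), names(formals(builder)))
  if (length(extra)) stop("unknown key(s) in [forcing]: ", paste(extra, collapse = ", "), call. = FALSE)
  forcing <- do.call(builder, fargs)
  list(params = take("oscillator", oscillator_params),
       forcing = forcing,
       ic = take("initial", initial_conditions),
       settings = take("solver", solver_settings))
}

#' Write trajectory and impact tables
#'
#' Plain UTF-8 CSV, `.` decimal separator. Trajectory header `t,x,v`;
#' impacts header `time,speed_in,speed_out`.
#'
#' @param traj An `impact_trajectory`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
write_impacts_csv <- function(traj, path) {
  utils::write.table(traj$impacts, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
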