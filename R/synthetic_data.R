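# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Synthetic knock patterns
#'
#' Ground-truth templates for the two signal types: a double knock (two
#' blows from a single body thrust, the second quieter) and a drum roll
#' (a rapid near-periodic series with gently decaying amplitude). Timing
#' jitter is Gaussian on each knock time.
#'
#' @param inter_knock_interval_s Interval between the two knocks (s, > 0).
#' @param amplitude_ratio Second-knock amplitude relative to the first,
#'   in (0, 1].
#' @param timing_jitter_sd_s Standard deviation of Gaussian timing jitter (s,
#'   >= 0).
#' @param seed Integer seed for reproducible jitter, or `NULL`.
#' @return An object of class `"knock_pattern"`.
#' @export
double_knock_pattern <- function(inter_knock_interval_s = 0.1,
                                 amplitude_ratio = 0.8,
                                 timing_jitter_sd_s = 0, seed = NULL) {
  if (inter_knock_interval_s <= 0) stop("inter_knock_interval_s must be > 0", call. = FALSE)
  if (amplitude_ratio <= 0 || amplitude_ratio > 1)
    stop("amplitude_ratio must lie in (0, 1]", call. = FALSE)
  if (timing_jitter_sd_s < 0) stop("timing_jitter_sd_s must be >= 0", call. = FALSE)
  structure(list(kind = "double_knock",
                 inter_knock_interval_s = inter_knock_interval_s,
                 amplitude_ratio = amplitude_ratio,
                 timing_jitter_sd_s = timing_jitter_sd_s, seed = seed),
            class = "knock_pattern")
}

#' @rdname double_knock_pattern
#' @param n_knocks Number of knocks in the roll (>= 1).
#' @param period_s Nominal knock period (s, > 0).
#' @param amplitude_decay Per-knock amplitude factor in (0, 1].
#' @export
drum_roll_pattern <- function(n_knocks = 10L, period_s = 0.06,
                              amplitude_decay = 0.95,
                              timing_jitter_sd_s = 0, seed = NULL) {
  if (n_knocks < 1) stop("n_knocks must be >= 1", call. = FALSE)
  if (period_s <= 0) stop("period_s must be > 0", call. = FALSE)
  if (amplitude_decay <= 0 || amplitude_decay > 1)
    stop("amplitude_decay must lie in (0, 1]", call. = FALSE)
  if (timing_jitter_sd_s < 0) stop("timing_jitter_sd_s must be >= 0", call. = FALSE)
  structure(list(kind = "drum_roll", n_knocks = as.integer(n_knocks),
                 period_s = period_s, amplitude_decay = amplitude_decay,
                 timing_jitter_sd_s = timing_jitter_sd_s, seed = seed),
            class = "knock_pattern")
}

#' Generate a knock train from a pattern
#'
#' Knock times are the nominal grid plus independent Gaussian jitter,
#' re-sorted; amplitudes follow the pattern's decay (first knock amplitude
#' 1). Identical patterns and seeds give identical trains.
#'
#' @param pattern A [double_knock_pattern()] or [drum_roll_pattern()].
#' @return A data frame of class `"knock_train"` with columns `time_s`,
#'   `amplitude`; the first knock is at time 0 before jitter.
#' @export
generate_impact_train <- function(pattern) {
  if (!inherits(pattern, "knock_pattern")) stop("pattern must be a knock_pattern", call. = FALSE)
  if (pattern$kind == "double_knock") {
    nominal <- c(0, pattern$inter_knock_interval_s)
    amp <- c(1, pattern$amplitude_ratio)
  } else {
    nominal <- (seq_len(pattern$n_knocks) - 1L) * pattern$period_s
    amp <- pattern$amplitude_decay^(seq_len(pattern$n_knocks) - 1L)
  }
  times <- with_seed(pattern$seed,
                     nominal + stats::rnorm(length(nominal), 0, pattern$timing_jitter_sd_s))
  out <- data.frame(time_s = sort(times), amplitude = amp)
  class(out) <- c("knock_train", "data.frame")
  out
}

#' Audio rendering of a knock train
#'
#' Each knock contributes an exponentially decaying sinusoid — a minimal
#' resonant-impact model — starting at the knock time:
#' `a * exp(-(t - t_k) / decay) * sin(2 pi f_ring (t - t_k))`, plus Gaussian
#' white noise of the given RMS. The rendered waveform is peak-limited to 1.
#'
#' @param sample_rate_hz Sample rate (>= 8000).
#' @param knock_ring_freq_hz Ring (resonance) frequency of a knock (Hz).
#' @param knock_decay_s Exponential decay time of the ring (s, > 0).
#' @param noise_rms RMS of the additive white noise (>= 0).
#' @param duration_s Buffer length; `NULL` sizes it to the train.
#' @param seed Integer seed for the noise, or `NULL`.
#' @return An object of class `"audio_render_spec"`.
#' @export
audio_render_spec <- function(sample_rate_hz = 22050, knock_ring_freq_hz = 1200,
                              knock_decay_s = 0.01, noise_rms = 0,
                              duration_s = NULL, seed = NULL) {
  if (sample_rate_hz < 8000) stop("sample_rate_hz must be >= 8000", call. = FALSE)
  if (knock_decay_s <= 0) stop("knock_decay_s must be > 0", call. = FALSE)
  if (noise_rms < 0) stop("noise_rms must be >= 0", call. = FALSE)
  structure(list(sample_rate_hz = sample_rate_hz,
                 knock_ring_freq_hz = knock_ring_freq_hz,
                 knock_decay_s = knock_decay_s, noise_rms = noise_rms,
                 duration_s = duration_s, seed = seed),
            class = "audio_render_spec")
}

#' @rdname audio_render_spec
#' @param train A non-empty [knock_train][generate_impact_train].
#' @param spec An `audio_render_spec`.
#' @return `render_audio()`: an object of class `"knock_audio"`, a list with
#'   `samples` (numeric in \[-1, 1\]) and `sample_rate_hz`.
#' @export
render_audio <- function(train, spec = audio_render_spec()) {
  if (!inherits(train, "knock_train") || nrow(train) == 0L)
    stop("train must be a non-empty knock_train", call. = FALSE)
  if (!inherits(spec, "audio_render_spec")) stop("spec must be an audio_render_spec", call. = FALSE)
  if (any(train$time_s < 0)) stop("knock times must be >= 0", call. = FALSE)
  sr <- spec$sample_rate_hz
  dur <- if (is.null(spec$duration_s))
    max(train$time_s) + 10 * spec$knock_decay_s + 0.05 else spec$duration_s
  if (max(train$time_s) >= dur)
    stop("knock times extend beyond the audio buffer", call. = FALSE)
  n <- ceiling(dur * sr)
  t <- (seq_len(n) - 1L) / sr
  w <- numeric(n)
  for (k in seq_len(nrow(train))) {
    i0 <- floor(train$time_s[k] * sr) + 1L
    tau <- t[i0:n] - train$time_s[k]
    w[i0:n] <- w[i0:n] + train$amplitude[k] * exp(-tau / spec$knock_decay_s) *
      sin(2 * pi * spec$knock_ring_freq_hz * tau)
  }
  if (spec$noise_rms > 0)
    w <- w + with_seed(spec$seed, stats::rnorm(n, 0, spec$noise_rms))
  peak <- max(abs(w))
  if (peak > 1) w <- w / peak
  structure(list(samples = w, sample_rate_hz = sr), class = "knock_audio")
}

#' Detect knock onsets in a waveform
#'
#' Computes a causal moving-RMS envelope (5 ms window), thresholds it at a
#' fraction of its maximum, and reports upward threshold crossings separated
#' by at least `min_gap_s`. A new onset can only fire after the envelope has
#' re-armed by dropping below `rearm_frac` of the threshold, so a knock's own
#' ring-down cannot re-trigger near the threshold boundary. Deterministic.
#'
#' @param audio A `knock_audio`, or a numeric waveform (then supply
#'   `sample_rate_hz`).
#' @param sample_rate_hz Sample rate when `audio` is a bare numeric vector.
#' @param threshold_frac Threshold as a fraction of the envelope maximum,
#'   in (0, 1).
#' @param min_gap_s Minimum spacing between reported onsets (s, > 0).
#' @param window_s RMS window length (s).
#' @param rearm_frac Hysteresis: fraction of the threshold the envelope must
#'   fall below before the next onset can trigger, in (0, 1\].
#' @return Numeric vector of onset times in seconds (possibly empty).
#' @export
detect_onsets <- function(audio, sample_rate_hz = NULL, threshold_frac = 0.2,
                          min_gap_s = 0.02, window_s = 0.005,
                          rearm_frac = 0.5) {
  if (inherits(audio, "knock_audio")) {
    w <- audio$samples; sr <- audio$sample_rate_hz
  } else {
    w <- as.numeric(audio); sr <- sample_rate_hz
    if (is.null(sr)) stop("sample_rate_hz required for a bare waveform", call. = FALSE)
  }
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must lie in (0, 1)", call. = FALSE)
  if (min_gap_s <= 0) stop("min_gap_s must be > 0", call. = FALSE)
  nw <- max(2L, round(window_s * sr))
  env <- sqrt(stats::filter(w^2, rep(1 / nw, nw), sides = 1))
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  emax <- max(env)
  if (emax <= 0) return(numeric())
  th <- threshold_frac * emax
  above <- env >= th
  crossings <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(crossings)) return(numeric())
  keep <- crossings[1L]
  gap <- min_gap_s * sr
  rearm <- rearm_frac * th
  for (i in crossings[-1L]) {
    last <- keep[length(keep)]
    if (i - last >= gap && any(env[last:i] < rearm)) keep <- c(keep, i)
  }
  (keep - 1L) / sr
}

#' Write and read mono 16-bit PCM WAV
#'
#' Minimal RIFF writer/reader for the synthetic knock audio (mono, 16-bit
#' PCM, little-endian). Samples are clipped to \[-1, 1\] on write.
#'
#' @param audio A `knock_audio`.
#' @param path File path.
#' @return `write_wav()`: the path, invisibly. `read_wav()`: a
#'   `knock_audio`.
#' @export
write_wav <- function(audio, path) {
  if (!inherits(audio, "knock_audio")) stop("audio must be a knock_audio", call. = FALSE)
  x <- pmin(1, pmax(-1, audio$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  sr <- as.integer(audio$sample_rate_hz)
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(2L * sr, con, size = 4, endian = "little")      # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file", call. = FALSE)
  sr <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!nzchar(id)) stop("no data chunk found", call. = FALSE)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1L] != 1L || fmt[2L] != 1L) stop("only mono PCM supported", call. = FALSE)
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "raw", sz - 8L)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", sz %/% 2L, size = 2, endian = "little")
      return(structure(list(samples = pcm / 32767, sample_rate_hz = sr),
                       class = "knock_audio"))
    } else readBin(con, "raw", sz)
  }
}

#' Generate a frame-indexed flap sequence
#'
#' Emulates counting wing events in video of intermittent flight. The
#' intrinsic rate `f` sets the active flap duration `1/f` (so
#' `round(fps / f)` frames per flap); the duty fraction stretches each full
#' cycle to `1 / (f * duty)` seconds, the remainder being the wings-closed
#' pause, so the raw rate of the sequence is `f * duty`. Flap start frames
#' sit on that cycle grid plus optional Gaussian jitter (in frames).
#'
#' @param true_f_hz Ground-truth intrinsic flap rate (Hz).
#' @param duty Duty fraction in (0, 1].
#' @param fps Video frame rate; must exceed `2 * true_f_hz` for the flaps to
#'   be resolvable.
#' @param n_flaps Number of flaps (>= 2).
#' @param jitter_frames_sd Gaussian jitter sd on start frames (frames).
#' @param seed Integer seed, or `NULL`.
#' @return A data frame of class `"flap_sequence"` with columns `flap_idx`,
#'   `start_frame`, `end_frame`; attributes `true_f_hz`, `duty`, `fps`.
#' @export
generate_flap_sequence <- function(true_f_hz, duty, fps = 60, n_flaps = 15L,
                                   jitter_frames_sd = 0, seed = NULL) {
  stopifnot(true_f_hz > 0, fps > 0, jitter_frames_sd >= 0)
  if (duty <= 0 || duty > 1) stop("duty fraction must lie in (0, 1]", call. = FALSE)
  if (n_flaps < 2) stop("n_flaps must be >= 2", call. = FALSE)
  if (fps <= 2 * true_f_hz)
    stop(sprintf("fps = %g cannot resolve flaps at %g Hz (need fps > %g)",
                 fps, true_f_hz, 2 * true_f_hz), call. = FALSE)
  period_frames <- fps / (true_f_hz * duty)   # full cycle: flap + pause
  flap_len <- max(1L, as.integer(round(fps / true_f_hz)))
  nominal <- (seq_len(n_flaps) - 1L) * period_frames
  starts <- with_seed(seed,
                      round(nominal + stats::rnorm(n_flaps, 0, jitter_frames_sd)))
  starts <- sort(as.integer(starts))
  out <- data.frame(flap_idx = seq_len(n_flaps),
                    start_frame = starts,
                    end_frame = starts + flap_len)
  attr(out, "true_f_hz") <- true_f_hz
  attr(out, "duty") <- duty
  attr(out, "fps") <- fps
  class(out) <- c("flap_sequence", "data.frame")
  out
}

#' Estimate flap rates from a flap sequence
#'
#' The raw flap rate is recovered from the flap start frames: `n` flaps
#' span `n - 1` full cycles from the first to the last start, so
#' `f_raw = (n - 1) / ((start_n - start_1) / fps)` — the flaps-per-elapsed-
#' time definition with the elapsed interval covering whole cycles. With the
#' duty fraction known, the intrinsic rate follows from
#' [intrinsic_from_raw()].
#'
#' @param seq_df A [generate_flap_sequence()] result (or any data frame with
#'   `start_frame`).
#' @param fps Frame rate; defaults to the sequence's own.
#' @param duty Duty fraction; defaults to the sequence's own.
#' @return List with `raw_hz`, `intrinsic_hz`, `span_frames` (extrapolated
#'   whole-cycle span of the sequence).
#' @export
estimate_flap_rates <- function(seq_df, fps = attr(seq_df, "fps"),
                                duty = attr(seq_df, "duty")) {
  n <- nrow(seq_df)
  if (is.null(fps)) stop("fps must be supplied", call. = FALSE)
  if (n < 2L) stop("need at least two flaps", call. = FALSE)
  span01 <- seq_df$start_frame[n] - seq_df$start_frame[1L]
  if (span01 <= 0) stop("degenerate flap sequence: zero span", call. = FALSE)
  raw <- (n - 1) / (span01 / fps)
  list(raw_hz = raw,
       intrinsic_hz = if (is.null(duty)) NA_real_ else intrinsic_from_raw(raw, duty),
       span_frames = span01 * n / (n - 1))
}

#' Write synthetic-data tables
#'
#' Knock trains as `time_s,amplitude`; flap sequences as
#' `flap_idx,start_frame,end_frame`. Plain UTF-8, `.` decimal separator.
#'
#' @param x A `knock_train` or `flap_sequence`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_knock_train_csv <- function(x, path) {
  utils::write.table(x, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_knock_train_csv
#' @export
write_flap_sequence_csv <- function(x, path) {
  utils::write.table(x, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
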