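#' Cadence statistics of an impact train
#'
#' Reduces an impact train to the quantities the drumming/double-knock
#' hypothesis reasons about: how many impacts there are, how regular the
#' inter-impact intervals are, how fast impact speeds decay, and how the
#' impacts split around the forcing window. For a periodic drive, impacts up
#' to `t_off` count as "during forcing"; for an impulsive drive the split is
#' at the pulse maximum (impacts at or before the pulse centre count as
#' during). With no forcing all impacts count as during.
#'
#' @param train An [impact_train()].
#' @param forcing Optional [forcing_spec][forcing_periodic] defining the
#'   forcing window.
#' @return An object of class `"cadence_summary"`: list with `n_impacts`,
#'   `times`, `during` (logical mask), `intervals`, `interval_mean`,
#'   `interval_cv` (population CV), `speed_decay_ratios`
#'   (`speed_in[i+1] / speed_in[i]`), `n_during_forcing`, `n_after_forcing`.
#'   Interval statistics are `NA` when there are fewer than two impacts.
#' @export
summarize_cadence <- function(train, forcing = NULL) {
  if (!inherits(train, "impact_train")) stop("train must be an impact_train", call. = FALSE)
  if (is.unsorted(train$times)) stop("impact train must be ordered by time", call. = FALSE)
  n <- length(train$times)
  split_t <- if (is.null(forcing)) Inf else switch(forcing$variant,
    periodic = forcing$t_off, impulsive = forcing$center, Inf)
  during <- train$times <= split_t
  intervals <- train$intervals
  mu <- if (n >= 2L) mean(intervals) else NA_real_
  # population (n-denominator) CV: descriptive statistic on the whole train
  cv <- if (n >= 2L) sqrt(mean((intervals - mu)^2)) / mu else NA_real_
  decay <- if (n >= 2L) train$speed_in[-1L] / train$speed_in[-n] else numeric()
  structure(list(n_impacts = n, times = train$times, during = during,
                 intervals = intervals, interval_mean = mu, interval_cv = cv,
                 speed_decay_ratios = decay,
                 n_during_forcing = sum(during),
                 n_after_forcing = sum(!during)),
            class = "cadence_summary")
}

#' Regime classification thresholds
#'
#' The hypothesis under test is qualitative — drumming is a sustained
#' near-periodic impact train while forcing is on; a double knock is a short
#' transient of decaying impacts — so the numeric cut-offs are conventions,
#' exposed here and overridable.
#'
#' @param min_periodic_impacts Minimum length of a steady impact run to call
#'   the regime periodic (>= 3).
#' @param max_periodic_cv Maximum population CV of the intervals within that
#'   run.
#' @param max_transient_impacts Maximum total impacts for a transient
#'   (double-knock-like) train.
#' @return An object of class `"regime_thresholds"`.
#' @export
regime_thresholds <- function(min_periodic_impacts = 5L, max_periodic_cv = 0.1,
                              max_transient_impacts = 4L) {
  if (min_periodic_impacts < 3L) stop("min_periodic_impacts must be >= 3", call. = FALSE)
  if (max_periodic_cv <= 0 || max_transient_impacts <= 0)
    stop("thresholds must be > 0", call. = FALSE)
  structure(list(min_periodic_impacts = as.integer(min_periodic_impacts),
                 max_periodic_cv = max_periodic_cv,
                 max_transient_impacts = as.integer(max_transient_impacts)),
            class = "regime_thresholds")
}

# Longest run of consecutive impact times whose inter-impact intervals have
# population CV <= max_cv. Returns the run length in impacts (0 or 1 when no
# interval exists). Quadratic scan; trains are short.
longest_steady_run <- function(times, max_cv) {
  n <- length(times)
  if (n < 2L) return(n)
  iv <- diff(times)
  best <- 1L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i, n - 1L)) {
      w <- iv[i:j]
      mu <- mean(w)
      cv <- sqrt(mean((w - mu)^2)) / mu
      if (cv <= max_cv) best <- max(best, j - i + 2L)
    }
  }
  best
}

#' Classify an impact train as drumming or a double-knock transient
#'
#' A summary is labelled `"periodic"` (drumming) when the during-forcing
#' impacts contain a run of at least `min_periodic_impacts` consecutive
#' impacts whose intervals have population CV at most `max_periodic_cv` —
#' the onset transient is thereby allowed to precede the steady drum roll.
#' It is `"transient"` (double-knock-like) when the whole train has at most
#' `max_transient_impacts` impacts and every impact is slower than the one
#' before. Anything else is `"mixed"`. Deterministic.
#'
#' @param summary A [summarize_cadence()] result.
#' @param thresholds [regime_thresholds()].
#' @return `"periodic"`, `"transient"`, or `"mixed"`.
#' @export
classify_regime <- function(summary, thresholds = regime_thresholds()) {
  if (!inherits(summary, "cadence_summary")) stop("summary must be a cadence_summary", call. = FALSE)
  if (!inherits(thresholds, "regime_thresholds")) stop("thresholds must be regime_thresholds", call. = FALSE)
  run <- longest_steady_run(summary$times[summary$during], thresholds$max_periodic_cv)
  if (summary$n_during_forcing >= thresholds$min_periodic_impacts &&
      run >= thresholds$min_periodic_impacts) return("periodic")
  if (summary$n_impacts <= thresholds$max_transient_impacts &&
      all(summary$speed_decay_ratios < 1, na.rm = TRUE)) return("transient")
  "mixed"
}

#' Count impacts audible at a distance
#'
#' The number of knocks detected far from the tree is modelled as the number
#' of impacts whose incoming speed reaches a detection threshold — a proxy
#' for radiated intensity; no acoustic propagation is modelled. The count is
#' monotone non-increasing in the threshold and equals the train size at
#' threshold zero.
#'
#' @param train An [impact_train()].
#' @param detection_speed_threshold Non-negative speed threshold.
#' @return Integer count of impacts with `speed_in >= threshold`.
#' @export
count_audible_knocks <- function(train, detection_speed_threshold) {
  if (!inherits(train, "impact_train")) stop("train must be an impact_train", call. = FALSE)
  stopifnot(is.numeric(detection_speed_threshold), length(detection_speed_threshold) == 1L)
  if (detection_speed_threshold < 0)
    stop("detection_speed_threshold must be >= 0", call. = FALSE)
  sum(train$speed_in >= detection_speed_threshold)
}

#' Write a one-row cadence report
#'
#' Header `n_impacts,interval_mean,interval_cv,n_during,n_after,label`.
#'
#' @param summary A [summarize_cadence()] result.
#' @param label Regime label, e.g. from [classify_regime()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cadence_csv <- function(summary, label, path) {
  df <- data.frame(n_impacts = summary$n_impacts,
                   interval_mean = summary$interval_mean,
                   interval_cv = summary$interval_cv,
                   n_during = summary$n_during_forcing,
                   n_after = summary$n_after_forcing,
                   label = label)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
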