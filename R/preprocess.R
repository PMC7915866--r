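#' Band-pass filter a recording and remove zero drift
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass to every
#' channel, then subtracts the per-channel mean. Zero-phase filtering
#' doubles the effective order but introduces no group delay, which matters
#' downstream when lagged couplings between channel envelopes are probed.
#'
#' @param rec an `emg_recording`.
#' @param low,high band edges in Hz; must satisfy `0 < low < high <
#'   rate / 2`.
#' @param order Butterworth order of the underlying one-pass filter
#'   (default 4).
#' @param trim seconds to drop from both ends of every repetition after
#'   filtering (default 0, i.e. keep everything); guards against edge
#'   transients when requested.
#' @return The filtered `emg_recording`, same shape and annotations.
#' @examples
#' cfg <- sim_config(n_channels = 3, rate = 200, band = c(20, 80),
#'                   phase_durations = c(0.5, 0.3, 0.5), n_repetitions = 2)
#' rec <- generate_recording(cfg)$recording
#' filt <- preprocess_recording(rec, low = 20, high = 80)
#' @export
preprocess_recording <- function(rec, low = 20, high = 450, order = 4,
                                 trim = 0) {
  stopifnot(inherits(rec, "emg_recording"))
  nyq <- rec$rate / 2
  if (!(low > 0 && low < high)) {
    stop("need 0 < low < high", call. = FALSE)
  }
  if (high >= nyq) {
    stop(sprintf("high (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 high, nyq), call. = FALSE)
  }
  bad <- which(!apply(is.finite(rec$signals), 2, all))
  if (length(bad) > 0) {
    stop(sprintf("non-finite samples in channel(s) %s",
                 paste(rec$channels[bad], collapse = ", ")), call. = FALSE)
  }
  flt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- apply(rec$signals, 2, function(x) {
    # centring first removes the DC drift before it can ring through the
    # filter's edge transients
    y <- signal::filtfilt(flt, x - mean(x))
    y - mean(y)
  })
  colnames(out) <- rec$channels
  rec$signals <- out
  if (trim > 0) {
    rec <- trim_repetitions(rec, trim)
  }
  rec
}

# Drop `trim` seconds from the head and tail of every repetition and remap
# the phase table onto the trimmed sample axis.
trim_repetitions <- function(rec, trim) {
  n_trim <- round(trim * rec$rate)
  n <- nrow(rec$signals)
  keep <- logical(n)
  for (r in unique(rec$phases$rep)) {
    rows <- rec$phases$rep == r
    lo <- min(rec$phases$start[rows]) + n_trim
    hi <- max(rec$phases$end[rows]) - n_trim
    if (lo <= hi) keep[lo:hi] <- TRUE
  }
  pos <- cumsum(keep) # new index of each kept sample
  ph <- rec$phases
  new_start <- new_end <- integer(nrow(ph))
  for (i in seq_len(nrow(ph))) {
    rng <- ph$start[i]:ph$end[i]
    kept <- rng[keep[rng]]
    if (length(kept) == 0) {
      new_start[i] <- NA_integer_
    } else {
      new_start[i] <- pos[kept[1]]
      new_end[i] <- pos[kept[length(kept)]]
    }
  }
  ok <- !is.na(new_start)
  ph <- ph[ok, , drop = FALSE]
  ph$start <- new_start[ok]
  ph$end <- new_end[ok]
  rec$signals <- rec$signals[keep, , drop = FALSE]
  rec$phases <- ph
  rec
}

#' Extract per-repetition analysis windows for one movement phase
#'
#' @param rec an `emg_recording` whose `phases` table annotates repetition
#'   and phase sample ranges.
#' @param phase phase label to extract (default `"lift"`, the phase where
#'   prosthesis--stump interaction concentrates).
#' @return A list with one `emg_segment` per repetition, ordered by
#'   repetition index. Each segment carries the sample matrix plus `rate`,
#'   `condition`, `rep` and `phase` fields.
#' @examples
#' cfg <- sim_config(n_channels = 3, rate = 200, band = c(20, 80),
#'                   phase_durations = c(0.5, 0.3, 0.5), n_repetitions = 2)
#' rec <- generate_recording(cfg)$recording
#' length(segment_phase(rec, "lift"))
#' @export
segment_phase <- function(rec, phase = "lift") {
  stopifnot(inherits(rec, "emg_recording"))
  ph <- rec$phases
  if (is.null(ph) || nrow(ph) == 0) {
    return(list())
  }
  known <- unique(ph$phase)
  if (!phase %in% known) {
    stop(sprintf("unknown phase '%s'; recording has: %s", phase,
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  rows <- ph[ph$phase == phase, , drop = FALSE]
  rows <- rows[order(rows$rep), , drop = FALSE]
  if (any(rows$end > nrow(rec$signals)) || any(rows$start < 1)) {
    stop("phase boundaries exceed the recording length", call. = FALSE)
  }
  lapply(seq_len(nrow(rows)), function(i) {
    structure(list(
      signals = rec$signals[rows$start[i]:rows$end[i], , drop = FALSE],
      rate = rec$rate, condition = rec$condition,
      rep = rows$rep[i], phase = phase
    ), class = "emg_segment")
  })
}

#' @export
print.emg_segment <- function(x, ...) {
  cat(sprintf("<emg_segment> rep %d, phase '%s', %d x %d @ %g Hz\n",
              x$rep, x$phase, nrow(x$signals), ncol(x$signals), x$rate))
  invisible(x)
}
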