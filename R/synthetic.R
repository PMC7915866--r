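#' Configuration for a synthetic multichannel EMG recording
#'
#' Describes a surrogate recording that emulates a repeated lift/hold/lower
#' movement protocol recorded from `n_channels` surface electrodes. Each
#' channel is a band-limited stochastic carrier, amplitude-modulated by a
#' per-phase activation envelope. Dependence between channels is planted at
#' two levels: a `global` latent source shared by every channel (common
#' drive) and one latent source per channel group (synergy-like local
#' coupling), mixed as
#'
#' \deqn{carrier_c = g \cdot G + (1-g)\,[s_c Z_{group(c)} + (1-s_c)\,\epsilon_c]}
#'
#' where `g` is `global_strength` and `s_c` the (possibly per-channel)
#' `group_strength`. With `global_strength = 0` and `group_strength = 0` all
#' channels are independent; with `group_strength = 1` (and zero global
#' weight) channels of one group are identical.
#'
#' @param n_channels number of electrodes (default 33, labelled `V1`..`Vn`).
#' @param rate sampling rate in Hz (default 2000).
#' @param phase_durations named numeric triple, seconds for the lift, hold
#'   and lower phases (default `c(lift = 1.5, hold = 1, lower = 1.5)`).
#' @param n_repetitions number of movement repetitions (default 10).
#' @param condition movement-condition label (e.g. `"appropriate"`,
#'   `"excessive"`, `"too_small"`).
#' @param group_assignment integer vector mapping each channel to a latent
#'   source index. Default: for 33 channels, the six electrode areas of
#'   [default_area_map()]; otherwise a single group.
#' @param group_strength mixing weight in `[0, 1]` of the group source;
#'   scalar or one value per channel.
#' @param global_strength mixing weight in `[0, 1]` of the common-drive
#'   source shared by all channels.
#' @param noise_sd overall amplitude scale of the generated signals.
#' @param am_strength depth in `[0, 1)` of the slow amplitude modulation
#'   applied to every latent source and noise component (default 0.35).
#'   Surface EMG amplitude drifts on a 0.3--1 s timescale (common-drive
#'   fluctuation); this is also what makes activation envelopes
#'   predictable over short lags, a prerequisite for envelope-level
#'   cross-mapping.
#' @param am_freq knot frequency in Hz of the slow modulation (default 2).
#' @param band numeric pair, band-pass edges in Hz of the stochastic
#'   carriers (default 20--450 Hz). Must satisfy `rate > 2 * band[2]`.
#' @param coupling optional directed couplings: a data frame (or list of
#'   lists) with columns `from`, `to` (channel labels or indices),
#'   `strength` (>= 0, canonical range 0.1--0.35), `lag` (seconds, default
#'   0.05) and `depth` (modulation contrast, default 2). The driver
#'   channel is amplitude-modulated by a free-running chaotic logistic map
#'   stepped every `lag` seconds; each target by a logistic map receiving
#'   the driver map's lagged quadratic influence. The target envelope
#'   hence integrates the driver's envelope history through recurrent
#'   dynamics, planting a directed influence detectable by convergent
#'   cross-mapping. All couplings must share one `lag`; a target cannot
#'   itself be a driver.
#' @param envelope_floor resting envelope level in `(0, 1)`; the lift phase
#'   ramps from this floor to 1, the lower phase back down.
#' @param seed integer seed; generation is fully deterministic given the
#'   configuration.
#' @return An object of class `sim_config`.
#' @seealso [generate_recording()]
#' @export
sim_config <- function(n_channels = 33, rate = 2000,
                       phase_durations = c(lift = 1.5, hold = 1, lower = 1.5),
                       n_repetitions = 10, condition = "appropriate",
                       group_assignment = NULL, group_strength = 0.5,
                       global_strength = 0.25, noise_sd = 1,
                       am_strength = 0.35, am_freq = 2,
                       band = c(20, 450), coupling = NULL,
                       envelope_floor = 0.1, seed = 1) {
  if (n_channels < 2) stop("n_channels must be >= 2", call. = FALSE)
  if (length(phase_durations) != 3 || any(phase_durations <= 0)) {
    stop("phase_durations must be three positive durations", call. = FALSE)
  }
  if (is.null(names(phase_durations))) {
    names(phase_durations) <- c("lift", "hold", "lower")
  }
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2]) {
    stop("band must be an increasing positive Hz pair", call. = FALSE)
  }
  if (rate <= 2 * band[2]) {
    stop(sprintf(
      "rate (%g Hz) must exceed twice the upper band edge (%g Hz)",
      rate, band[2]
    ), call. = FALSE)
  }
  if (is.null(group_assignment)) {
    group_assignment <- if (n_channels == 33) {
      default_area_map()$area
    } else {
      rep(1L, n_channels)
    }
  }
  if (length(group_assignment) != n_channels) {
    stop("group_assignment must name a source for every channel",
         call. = FALSE)
  }
  group_strength <- rep_len(group_strength, n_channels)
  if (any(group_strength < 0 | group_strength > 1)) {
    stop("group_strength must lie in [0, 1]", call. = FALSE)
  }
  if (global_strength < 0 || global_strength > 1) {
    stop("global_strength must lie in [0, 1]", call. = FALSE)
  }
  if (envelope_floor <= 0 || envelope_floor > 1) {
    stop("envelope_floor must lie in (0, 1]", call. = FALSE)
  }
  if (am_strength < 0 || am_strength >= 1) {
    stop("am_strength must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(coupling)) coupling <- normalize_coupling(coupling, n_channels)
  structure(list(
    n_channels = as.integer(n_channels), rate = rate,
    phase_durations = phase_durations,
    n_repetitions = as.integer(n_repetitions), condition = condition,
    group_assignment = as.integer(group_assignment),
    group_strength = group_strength, global_strength = global_strength,
    noise_sd = noise_sd, am_strength = am_strength, am_freq = am_freq,
    band = band, coupling = coupling,
    envelope_floor = envelope_floor, seed = as.integer(seed)
  ), class = "sim_config")
}

normalize_coupling <- function(coupling, n_channels) {
  if (!is.data.frame(coupling)) {
    coupling <- do.call(rbind, lapply(coupling, function(e) {
      as.data.frame(e, stringsAsFactors = FALSE)
    }))
  }
  if (is.null(coupling$lag)) coupling$lag <- 0.05
  if (is.null(coupling$strength)) coupling$strength <- 0.2
  if (is.null(coupling$depth)) coupling$depth <- 2
  labels <- channel_labels(n_channels)
  to_idx <- function(x) {
    if (is.numeric(x)) as.integer(x) else match(as.character(x), labels)
  }
  coupling$from <- to_idx(coupling$from)
  coupling$to <- to_idx(coupling$to)
  if (any(is.na(coupling$from)) || any(is.na(coupling$to)) ||
      any(coupling$from < 1) || any(coupling$to < 1) ||
      any(coupling$from > n_channels) || any(coupling$to > n_channels)) {
    stop("coupling refers to unknown channels", call. = FALSE)
  }
  if (any(coupling$from == coupling$to)) {
    stop("coupling cannot be a self-loop", call. = FALSE)
  }
  if (any(coupling$strength < 0)) {
    stop("coupling strength must be >= 0", call. = FALSE)
  }
  if (any(coupling$depth <= 0)) {
    stop("coupling depth must be positive", call. = FALSE)
  }
  coupling[c("from", "to", "strength", "lag", "depth")]
}

channel_labels <- function(n) paste0("V", seq_len(n))

# Activation envelope for one repetition: ramp floor -> 1 (lift),
# plateau (hold), ramp 1 -> floor (lower).
phase_envelope <- function(n_lift, n_hold, n_lower, floor) {
  c(
    seq(floor, 1, length.out = n_lift),
    rep(1, n_hold),
    seq(1, floor, length.out = n_lower)
  )
}

# White Gaussian noise band-pass filtered to `band`, scaled to unit sd.
band_limited_noise <- function(n, rate, band, flt = NULL) {
  if (is.null(flt)) {
    flt <- signal::butter(4, band / (rate / 2), type = "pass")
  }
  x <- signal::filtfilt(flt, rnorm(n))
  x / sd(x)
}

# Smooth slow modulation: unit-sd cubic-spline interpolation of Gaussian
# knots drawn at `freq` per second. Multiplied onto a source as
# (1 + strength * m), floored to stay positive.
slow_modulator <- function(n, rate, freq, strength) {
  if (strength <= 0) {
    return(rep(1, n))
  }
  nk <- max(4L, ceiling(n / rate * freq) + 3L)
  m <- stats::spline(seq(0, 1, length.out = nk), rnorm(nk),
                     xout = seq(0, 1, length.out = n))$y
  m <- (m - mean(m)) / sd(m)
  pmax(1 + strength * m, 0.05)
}

# Slow modulators for directed couplings: the driver channel's private
# component is amplitude-modulated by a free-running chaotic logistic map
# stepped every `lag` seconds, and each target's by a logistic map with a
# lagged quadratic driver term, m_T <- m_T (r_t - r_t m_T - beta m_D).
# The target modulator therefore integrates the driver's envelope history
# through its own recurrent dynamics -- the signature convergent
# cross-mapping detects. Knot sequences are spline-upsampled to the sample
# rate and normalized to mean 1.
coupling_modulators <- function(edges, n, rate, r_driver = 3.8,
                                r_target = 3.72) {
  if (length(unique(edges$lag)) > 1) {
    stop("all couplings must share the same lag", call. = FALSE)
  }
  if (any(edges$to %in% edges$from)) {
    stop("chained couplings (a target acting as driver) are not supported",
         call. = FALSE)
  }
  step <- max(1L, round(edges$lag[1] * rate))
  nk <- ceiling(n / step) + 1L
  burn <- 100L
  drivers <- unique(edges$from)
  maps <- list()
  for (d in drivers) {
    x <- numeric(nk + burn)
    x[1] <- stats::runif(1, 0.2, 0.8)
    for (t in seq_len(nk + burn - 1L)) {
      x[t + 1L] <- x[t] * (r_driver - r_driver * x[t])
    }
    maps[[as.character(d)]] <- x
  }
  for (k in seq_len(nrow(edges))) {
    xd <- maps[[as.character(edges$from[k])]]
    beta <- edges$strength[k]
    y <- numeric(nk + burn)
    y[1] <- stats::runif(1, 0.2, 0.8)
    for (t in seq_len(nk + burn - 1L)) {
      y[t + 1L] <- y[t] * (r_target - r_target * y[t] - beta * xd[t])
      if (y[t + 1L] <= 0 || y[t + 1L] >= 1) {
        stop(sprintf(
          "coupling modulator left (0, 1); reduce strength (%g)", beta
        ), call. = FALSE)
      }
    }
    maps[[as.character(edges$to[k])]] <- y
  }
  # Modulation depth per channel: drivers take the maximum depth of their
  # out-edges, targets the depth of their in-edge. Depth > 1 deepens the
  # burst-like excursions, lifting the planted dynamics above the
  # carrier-induced envelope estimation noise.
  depth <- numeric(0)
  for (k in seq_len(nrow(edges))) {
    f <- as.character(edges$from[k])
    t <- as.character(edges$to[k])
    depth[f] <- max(depth[f], edges$depth[k], na.rm = TRUE)
    depth[t] <- edges$depth[k]
  }
  knot_t <- (seq_len(nk) - 0.5) * step
  out <- lapply(names(maps), function(nm) {
    x <- maps[[nm]][(burn + 1L):(burn + nk)]
    m <- stats::spline(knot_t, x, xout = seq_len(n))$y
    m <- pmax(m, 1e-3)
    # power law deepens the modulation smoothly and invertibly
    m <- (m / mean(m))^depth[[nm]]
    m / mean(m)
  })
  names(out) <- names(maps)
  out
}

#' Generate a synthetic multichannel EMG recording with known ground truth
#'
#' Realizes the model described in [sim_config()]: per-group and global
#' band-limited latent sources mixed into each channel, multiplied by the
#' repetition-wise lift/hold/lower activation envelope, with optional
#' directed envelope couplings. The returned truth record states the planted
#' group structure and directed edges, so downstream network and causality
#' analyses can be validated against it.
#'
#' @param config a [sim_config()] object.
#' @return A list with components:
#'   \describe{
#'     \item{recording}{an `emg_recording`: `signals` (samples x channels
#'       matrix), `rate`, `channels`, `condition`, `phases` (data frame with
#'       `rep`, `phase`, `start`, `end` sample ranges) and `seed`.}
#'     \item{truth}{a `truth_record`: `groups` (channel to source),
#'       `edges` (planted directed couplings) and the echoed `config`.}
#'   }
#' @examples
#' cfg <- sim_config(n_channels = 4, rate = 200, band = c(20, 80),
#'                   phase_durations = c(0.5, 0.3, 0.5), n_repetitions = 2)
#' rec <- generate_recording(cfg)
#' dim(rec$recording$signals)
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rate <- config$rate
  nc <- config$n_channels
  n_phase <- round(config$phase_durations * rate)
  rep_len <- sum(n_phase)
  n_rep <- config$n_repetitions
  total <- rep_len * n_rep
  env1 <- phase_envelope(n_phase[1], n_phase[2], n_phase[3],
                         config$envelope_floor)
  env <- rep(env1, n_rep)

  flt <- signal::butter(4, config$band / (rate / 2), type = "pass")
  groups <- config$group_assignment
  src_ids <- sort(unique(groups))
  am <- config$am_strength
  am_f <- config$am_freq
  # Every latent source and every channel noise stream carries its own
  # slow amplitude modulation (common drive within a group, private drive
  # per channel).
  make_source <- function() {
    band_limited_noise(total, rate, config$band, flt) *
      slow_modulator(total, rate, am_f, am)
  }
  global <- make_source()
  Z <- vapply(src_ids, function(g) make_source(), numeric(total))
  colnames(Z) <- as.character(src_ids)

  # Channels taking part in a directed coupling carry chaotic-map
  # modulators on their private component instead of the generic slow
  # drive; the target maps integrate the driver map's lagged quadratic
  # influence, planting a cross-mapping-detectable causal direction.
  edges <- config$coupling
  cmods <- if (!is.null(edges) && nrow(edges) > 0) {
    coupling_modulators(edges, total, rate)
  } else {
    list()
  }

  g <- config$global_strength
  signals <- matrix(0, total, nc)
  for (c in seq_len(nc)) {
    s <- config$group_strength[c]
    eps <- make_source()
    local <- s * Z[, as.character(groups[c])] + (1 - s) * eps
    sig <- config$noise_sd * (g * global + (1 - g) * local) * env
    cm <- cmods[[as.character(c)]]
    if (!is.null(cm)) sig <- sig * cm # chaotic activation drive
    signals[, c] <- sig
  }

  labels <- channel_labels(nc)
  colnames(signals) <- labels
  phases <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
    off <- (r - 1L) * rep_len
    starts <- off + cumsum(c(0L, n_phase[-3])) + 1L
    data.frame(
      rep = r, phase = names(config$phase_durations),
      start = starts, end = off + cumsum(n_phase),
      stringsAsFactors = FALSE
    )
  }))
  rownames(phases) <- NULL

  recording <- structure(list(
    signals = signals, rate = rate, channels = labels,
    condition = config$condition, phases = phases, seed = config$seed
  ), class = "emg_recording")
  truth <- structure(list(
    groups = stats::setNames(groups, labels),
    edges = if (is.null(edges)) {
      data.frame(from = integer(), to = integer(),
                 strength = numeric(), lag = numeric(), depth = numeric())
    } else edges,
    modulators = cmods,
    config = config
  ), class = "truth_record")
  list(recording = recording, truth = truth)
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> %d channels x %d samples @ %g Hz, condition '%s', %d repetitions\n",
    ncol(x$signals), nrow(x$signals), x$rate, x$condition,
    max(x$phases$rep)
  ))
  invisible(x)
}

#' Specification of a pair of coupled logistic maps
#'
#' Canonical nonlinear benchmark system for cross-mapping causality:
#' \deqn{x_{t+1} = x_t (r_x - r_x x_t - \beta_{xy} y_t)}
#' \deqn{y_{t+1} = y_t (r_y - r_y y_t - \beta_{yx} x_t)}
#' `beta_yx` is the influence of `x` on `y` (so `beta_yx > 0` plants the
#' causal direction x -> y), and `beta_xy` the influence of `y` on `x`.
#'
#' @param r_x,r_y logistic growth rates.
#' @param beta_xy,beta_yx coupling strengths, `>= 0`.
#' @param length number of samples generated (burn-in included).
#' @param burn_in initial samples discarded; must be `< length`.
#' @param init length-2 initial values in `(0, 1)`.
#' @param seed integer seed used to jitter `init` reproducibly when
#'   `jitter_init = TRUE`.
#' @param jitter_init add a small seeded perturbation to `init` so that
#'   different seeds explore different trajectories of the same system.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(r_x = 3.8, r_y = 3.5, beta_xy = 0, beta_yx = 0,
                          length = 1100, burn_in = 100,
                          init = c(0.4, 0.2), seed = 1, jitter_init = TRUE) {
  if (length <= burn_in) {
    stop("length must exceed burn_in", call. = FALSE)
  }
  if (any(init <= 0 | init >= 1)) {
    stop("init values must lie in (0, 1)", call. = FALSE)
  }
  if (beta_xy < 0 || beta_yx < 0) {
    stop("coupling strengths must be >= 0", call. = FALSE)
  }
  structure(list(
    r_x = r_x, r_y = r_y, beta_xy = beta_xy, beta_yx = beta_yx,
    length = as.integer(length), burn_in = as.integer(burn_in),
    init = init, seed = as.integer(seed), jitter_init = jitter_init
  ), class = "coupling_spec")
}

#' Generate a pair of (possibly unidirectionally) coupled logistic maps
#'
#' @param spec a [coupling_spec()].
#' @return A list with numeric vectors `x` and `y` of length
#'   `spec$length - spec$burn_in`, plus the echoed `spec`.
#' @examples
#' xy <- generate_coupled_logistic(coupling_spec(beta_yx = 0.32, seed = 7))
#' range(xy$x)
#' @export
generate_coupled_logistic <- function(spec) {
  stopifnot(inherits(spec, "coupling_spec"))
  set.seed(spec$seed)
  init <- spec$init
  if (isTRUE(spec$jitter_init)) {
    init <- init + stats::runif(2, -0.05, 0.05)
    init <- pmin(pmax(init, 1e-3), 1 - 1e-3)
  }
  n <- spec$length
  x <- numeric(n)
  y <- numeric(n)
  x[1] <- init[1]
  y[1] <- init[2]
  for (t in seq_len(n - 1L)) {
    x[t + 1L] <- x[t] * (spec$r_x - spec$r_x * x[t] - spec$beta_xy * y[t])
    y[t + 1L] <- y[t] * (spec$r_y - spec$r_y * y[t] - spec$beta_yx * x[t])
    if (!is.finite(x[t + 1L]) || !is.finite(y[t + 1L]) ||
        x[t + 1L] <= 0 || x[t + 1L] >= 1 ||
        y[t + 1L] <= 0 || y[t + 1L] >= 1) {
      stop(sprintf(
        paste0("coupled logistic trajectory left (0, 1) at step %d ",
               "(r_x = %g, r_y = %g, beta_xy = %g, beta_yx = %g)"),
        t + 1L, spec$r_x, spec$r_y, spec$beta_xy, spec$beta_yx
      ), call. = FALSE)
    }
  }
  keep <- (spec$burn_in + 1L):n
  list(x = x[keep], y = y[keep], spec = spec)
}

#' Write / read a recording as CSV plus a JSON sidecar
#'
#' The CSV holds one sample per row with channel labels as the header; the
#' sidecar records the sampling rate, condition, repetition/phase sample
#' ranges, seed and (optionally) the planted ground truth.
#'
#' @param rec an `emg_recording`.
#' @param csv path of the CSV file; the sidecar defaults to the same path
#'   with a `.json` extension.
#' @param sidecar path of the JSON sidecar.
#' @param truth optional `truth_record` to embed in the sidecar.
#' @return `write_recording()` returns the sidecar path invisibly;
#'   `read_recording()` returns the `emg_recording` (with the truth record,
#'   if present, attached as attribute `"truth"`).
#' @export
write_recording <- function(rec, csv,
                            sidecar = sub("\\.csv$", ".json", csv),
                            truth = NULL) {
  stopifnot(inherits(rec, "emg_recording"))
  write.csv(as.data.frame(rec$signals), csv, row.names = FALSE)
  meta <- list(
    rate = rec$rate, condition = rec$condition, seed = rec$seed,
    channels = rec$channels, phases = rec$phases
  )
  if (!is.null(truth)) {
    meta$truth <- list(groups = as.list(truth$groups), edges = truth$edges)
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @rdname write_recording
#' @export
read_recording <- function(csv, sidecar = sub("\\.csv$", ".json", csv)) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  signals <- as.matrix(read.csv(csv, check.names = FALSE))
  rec <- structure(list(
    signals = signals, rate = meta$rate,
    channels = colnames(signals), condition = meta$condition,
    phases = as.data.frame(meta$phases), seed = meta$seed
  ), class = "emg_recording")
  if (!is.null(meta$truth)) {
    attr(rec, "truth") <- list(
      groups = unlist(meta$truth$groups),
      edges = as.data.frame(meta$truth$edges)
    )
  }
  rec
}
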