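# Convergent cross-mapping (CCM): delay embedding, simplex-projection
# cross-map skill, and convergence over library length.
#
# Direction convention used throughout: `cross_map_skill(x, y)` is the
# skill of estimating x from the delay-embedded manifold of y ("Mx" skill).
# If x drives y, the history of y encodes x, so high Mx skill is evidence
# for the causal direction x -> y.

#' Delay embedding of a time series
#'
#' Builds the reconstructed manifold of points
#' \deqn{x(t) = \langle x[t], x[t-\tau], \ldots, x[t-(E-1)\tau] \rangle}
#' for `t = (E-1)*tau + 1, ..., length(x)`, giving
#' `length(x) - (E-1)*tau` points.
#'
#' @param x numeric series.
#' @param E embedding dimension (`>= 1`; `E = 1` returns the raw samples).
#' @param tau embedding delay in samples (`>= 1`).
#' @return A `manifold`: `points` (matrix, one point per row, lag 0 in
#'   column 1), `times` (the sample index `t` of each point), `E`, `tau`.
#' @examples
#' delay_embed(0:9, E = 3, tau = 2)$points[1, ] # c(4, 2, 0)
#' @export
delay_embed <- function(x, E = 3, tau = 1) {
  E <- as.integer(E)
  tau <- as.integer(tau)
  if (E < 1 || tau < 1) stop("need E >= 1 and tau >= 1", call. = FALSE)
  n <- length(x)
  first <- (E - 1L) * tau + 1L
  if (n < first + 1L) {
    stop(sprintf("series too short to embed: need length > %d for E = %d, tau = %d",
                 first, E, tau), call. = FALSE)
  }
  times <- first:n
  points <- vapply(0:(E - 1L), function(lag) x[times - lag * tau],
                   numeric(length(times)))
  points <- matrix(points, nrow = length(times))
  structure(list(points = points, times = times, E = E, tau = tau),
            class = "manifold")
}

# Embed one or more segments of a (x, y) pair on a common time axis.
# Segments get well-separated time stamps so the Theiler window never
# bridges segment boundaries, while points from other segments remain
# admissible neighbours.
embed_pair <- function(x, y, E, tau, theiler) {
  xs <- if (is.list(x)) x else list(x)
  ys <- if (is.list(y)) y else list(y)
  if (length(xs) != length(ys)) {
    stop("x and y must have the same number of segments", call. = FALSE)
  }
  pts <- list()
  times <- integer(0)
  xv <- yv <- numeric(0)
  offset <- 0L
  for (s in seq_along(xs)) {
    if (length(xs[[s]]) != length(ys[[s]])) {
      stop("paired segments must have equal length", call. = FALSE)
    }
    my <- delay_embed(ys[[s]], E, tau)
    mx <- delay_embed(xs[[s]], E, tau)
    pts[[s]] <- list(y = my$points, x = mx$points)
    times <- c(times, my$times + offset)
    xv <- c(xv, xs[[s]][my$times])
    yv <- c(yv, ys[[s]][my$times])
    offset <- offset + length(xs[[s]]) + theiler + 10L
  }
  list(
    My = do.call(rbind, lapply(pts, `[[`, "y")),
    Mx = do.call(rbind, lapply(pts, `[[`, "x")),
    times = times, xv = xv, yv = yv
  )
}

# One cross-map skill evaluation: correlation between observed values and
# their simplex-projection estimates from the given manifold.
skill_once <- function(M, vals, times, lib, pred, k, theiler, uniform) {
  est <- simplex_predict_cpp(M, vals, times, lib, pred, k, theiler, uniform)
  ok <- is.finite(est)
  if (sum(ok) < 3) {
    warning("too few admissible predictions; skill set to 0", call. = FALSE)
    return(0)
  }
  obs <- vals[pred][ok]
  if (sd(obs) == 0 || sd(est[ok]) == 0) {
    warning("degenerate variance in cross-map skill; r set to 0",
            call. = FALSE)
    return(0)
  }
  cor(est[ok], obs)
}

#' Cross-map skill between two series
#'
#' Estimates `x` by simplex projection from the delay-embedded manifold of
#' `y`: for each prediction point, the `E + 1` nearest library neighbours
#' on the y-manifold (excluding temporally adjacent points within a Theiler
#' window) are combined with exponential distance weights
#' `w_i = exp(-d_i / d_1)`, and the skill is the Pearson correlation `r`
#' between the estimates and the observed `x`. High skill means the
#' information of `x` is recoverable from `y` -- evidence for `x -> y`.
#'
#' @param x,y numeric series of equal length, or lists of paired segments
#'   (embedded separately and pooled into one manifold).
#' @param E embedding dimension (default 3).
#' @param tau embedding delay in samples; `NULL` picks the first minimum
#'   of the autocorrelation of `y` (capped at `tau_cap`).
#' @param lib_size library size (number of manifold points used as
#'   neighbour candidates); default all points.
#' @param repeats number of random library draws (default 10); the skill
#'   is averaged over draws.
#' @param n_pred number of prediction points (default: all).
#' @param theiler temporal exclusion radius in samples; default
#'   `(E - 1) * tau`.
#' @param weights `"exponential"` (standard simplex weighting) or
#'   `"as_printed"` (uniform weights over the `E + 1` neighbours).
#' @param tau_cap upper bound for the automatically chosen delay.
#' @param seed integer seed for the library draws.
#' @return A list: `r_mean`, `r_sd`, `r` (per draw), `lib_size`, `E`,
#'   `tau`.
#' @export
cross_map_skill <- function(x, y, E = 3, tau = 1, lib_size = NULL,
                            repeats = 10, n_pred = NULL, theiler = NULL,
                            weights = c("exponential", "as_printed"),
                            tau_cap = 10, seed = NULL) {
  weights <- match.arg(weights)
  if (is.null(tau)) tau <- select_tau(if (is.list(y)) y[[1]] else y, tau_cap)
  if (is.null(theiler)) theiler <- (E - 1L) * tau
  emb <- embed_pair(x, y, E, tau, theiler)
  N <- nrow(emb$My)
  k <- E + 1L
  if (is.null(lib_size)) lib_size <- N
  if (lib_size > N) {
    stop(sprintf("lib_size (%d) exceeds available points (%d)",
                 lib_size, N), call. = FALSE)
  }
  if (lib_size < k + 1L) {
    stop("lib_size too small for E + 1 neighbours", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pred <- if (is.null(n_pred) || n_pred >= N) {
    seq_len(N)
  } else {
    sort(sample.int(N, n_pred))
  }
  r <- vapply(seq_len(repeats), function(i) {
    lib <- sample.int(N, lib_size)
    skill_once(emb$My, emb$xv, emb$times, lib, pred, k, theiler,
               weights == "as_printed")
  }, numeric(1))
  list(r_mean = mean(r), r_sd = sd(r), r = r,
       lib_size = lib_size, E = E, tau = tau)
}

# First local minimum of the autocorrelation function, capped.
select_tau <- function(x, cap = 10) {
  cap <- max(1L, as.integer(cap))
  a <- as.numeric(acf(x, lag.max = cap, plot = FALSE,
                      demean = TRUE)$acf)[-1]
  if (length(a) >= 2) {
    for (k in seq_len(length(a) - 1L)) {
      if (a[k + 1L] > a[k]) {
        return(k)
      }
    }
  }
  cap
}

#' Rectified low-pass activation envelope of an EMG signal
#'
#' Full-wave rectification followed by a zero-phase Butterworth low-pass
#' and decimation. The envelope, not the raw band-limited carrier, is what
#' state-space reconstruction can work with: the carrier is
#' noise-dominated, while the envelope tracks activation dynamics.
#'
#' @param x numeric vector or samples-by-channels matrix.
#' @param rate sampling rate in Hz.
#' @param cutoff low-pass cutoff in Hz (default 10).
#' @param order filter order (default 4).
#' @param decimate keep every `decimate`-th sample (default 20, i.e.
#'   2 kHz -> 100 Hz).
#' @return The envelope, with attribute `rate` giving the decimated rate.
#' @export
emg_envelope <- function(x, rate, cutoff = 10, order = 4, decimate = 20) {
  if (cutoff >= rate / 2) stop("cutoff must be below Nyquist", call. = FALSE)
  flt <- signal::butter(order, cutoff / (rate / 2), type = "low")
  env1 <- function(v) {
    e <- signal::filtfilt(flt, abs(v))
    e[seq(1, length(e), by = decimate)]
  }
  out <- if (is.matrix(x)) {
    res <- apply(x, 2, env1)
    colnames(res) <- colnames(x)
    res
  } else {
    env1(x)
  }
  attr(out, "rate") <- rate / decimate
  out
}

#' Per-repetition activation-envelope series for one movement phase
#'
#' Extracts each node's activation envelope from the *continuous* filtered
#' recording (one [emg_envelope()] pass per channel, avoiding filter edge
#' transients inside short windows), then cuts the requested phase's
#' per-repetition windows on the decimated axis. Optionally the
#' protocol-locked mean activation profile across repetitions is removed
#' by ratio, leaving the stationary trial-to-trial dynamics that
#' cross-mapping operates on.
#'
#' @param rec a (filtered) `emg_recording`.
#' @param nodes channel labels to extract (default all).
#' @param phase movement phase, or `NULL` for whole repetitions (all
#'   phases; more data per repetition, the default choice of the
#'   pipeline's cross-mapping stage).
#' @param cutoff,decimate see [emg_envelope()].
#' @param detrend divide by the across-repetition mean profile and
#'   subtract 1 (default `TRUE`).
#' @return A named list (one entry per node) of per-repetition numeric
#'   envelope segments, suitable for [build_directed_network()].
#' @export
phase_envelopes <- function(rec, nodes = NULL, phase = "lift", cutoff = 10,
                            decimate = 20, detrend = TRUE) {
  stopifnot(inherits(rec, "emg_recording"))
  if (is.null(nodes)) nodes <- rec$channels
  ph <- if (is.null(phase)) {
    agg <- rec$phases
    do.call(rbind, lapply(split(agg, agg$rep), function(a) {
      data.frame(rep = a$rep[1], phase = "all", start = min(a$start),
                 end = max(a$end))
    }))
  } else {
    rec$phases[rec$phases$phase == phase, , drop = FALSE]
  }
  if (nrow(ph) == 0) stop(sprintf("no '%s' phase in recording", phase),
                          call. = FALSE)
  ph <- ph[order(ph$rep), , drop = FALSE]
  # decimated index j corresponds to original sample 1 + (j - 1) * decimate
  win <- lapply(seq_len(nrow(ph)), function(i) {
    j0 <- ceiling((ph$start[i] - 1) / decimate) + 1L
    j1 <- floor((ph$end[i] - 1) / decimate) + 1L
    j0:j1
  })
  stats::setNames(lapply(nodes, function(node) {
    full <- as.numeric(emg_envelope(rec$signals[, node], rate = rec$rate,
                                    cutoff = cutoff, decimate = decimate))
    env <- lapply(win, function(w) full[w])
    if (detrend && length(env) > 1) {
      len <- min(lengths(env))
      avg <- rowMeans(vapply(env, function(e) e[seq_len(len)],
                             numeric(len)))
      avg <- pmax(avg, .Machine$double.eps)
      env <- lapply(env, function(e) e[seq_len(len)] / avg - 1)
    }
    env
  }), nodes)
}

default_lib_sizes <- function(N, E) {
  lo <- max(2L * (E + 2L), 10L)
  sizes <- unique(round(seq(min(lo, N), N, length.out = 4)))
  sizes[sizes >= E + 3L]
}

#' Convergence of cross-map skill with library length
#'
#' Evaluates [cross_map_skill()] in both directions over an ascending grid
#' of library sizes. Convergent, increasing skill is the CCM signature of
#' causal coupling; the converged skill is the mean `r` at the largest
#' library. A Spearman rank correlation of skill against library size is
#' attached per direction as a monotone-trend diagnostic.
#'
#' @inheritParams cross_map_skill
#' @param lib_sizes ascending library-size grid; default four sizes up to
#'   all available points.
#' @param seed integer seed for the library draws.
#' @return A `ccm_curve`: `curve` (data frame: `lib_size`, `direction`
#'   (`"x_from_y"` or `"y_from_x"`), `r_mean`, `r_sd`), `mx_skill` and
#'   `my_skill` (converged skills; `mx_skill` estimates x from the
#'   y-manifold), `trend` (named Spearman rho per direction), `E`, `tau`.
#' @export
convergence_analysis <- function(x, y, E = 3, tau = 1, lib_sizes = NULL,
                                 repeats = 10, n_pred = NULL, theiler = NULL,
                                 weights = c("exponential", "as_printed"),
                                 tau_cap = 10, seed = 1) {
  weights <- match.arg(weights)
  if (is.null(tau)) {
    tau <- max(select_tau(if (is.list(x)) x[[1]] else x, tau_cap),
               select_tau(if (is.list(y)) y[[1]] else y, tau_cap))
  }
  if (is.null(theiler)) theiler <- (E - 1L) * tau
  emb <- embed_pair(x, y, E, tau, theiler)
  N <- nrow(emb$My)
  if (is.null(lib_sizes)) lib_sizes <- default_lib_sizes(N, E)
  lib_sizes <- sort(unique(pmin(lib_sizes, N)))
  if (length(lib_sizes) == 0 || max(lib_sizes) < E + 3L) {
    stop("no usable library sizes", call. = FALSE)
  }
  k <- E + 1L
  set.seed(seed)
  pred <- if (is.null(n_pred) || n_pred >= N) {
    seq_len(N)
  } else {
    sort(sample.int(N, n_pred))
  }
  uniform <- weights == "as_printed"
  rows <- list()
  for (dir in c("x_from_y", "y_from_x")) {
    M <- if (dir == "x_from_y") emb$My else emb$Mx
    vals <- if (dir == "x_from_y") emb$xv else emb$yv
    for (L in lib_sizes) {
      r <- vapply(seq_len(repeats), function(i) {
        lib <- sample.int(N, L)
        skill_once(M, vals, emb$times, lib, pred, k, theiler, uniform)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        lib_size = L, direction = dir, r_mean = mean(r), r_sd = sd(r)
      )
    }
  }
  curve <- do.call(rbind, rows)
  conv <- function(dir) {
    curve$r_mean[curve$direction == dir & curve$lib_size == max(lib_sizes)]
  }
  trend <- vapply(c("x_from_y", "y_from_x"), function(dir) {
    sub <- curve[curve$direction == dir, ]
    if (nrow(sub) < 2 || sd(sub$r_mean) == 0) {
      return(0)
    }
    cor(sub$lib_size, sub$r_mean, method = "spearman")
  }, numeric(1))
  structure(list(
    curve = curve, mx_skill = conv("x_from_y"), my_skill = conv("y_from_x"),
    trend = trend, E = E, tau = tau, repeats = repeats, seed = seed
  ), class = "ccm_curve")
}

#' @export
print.ccm_curve <- function(x, ...) {
  cat(sprintf(
    "<ccm_curve> E = %d, tau = %d; converged skills: x|My = %.3f, y|Mx = %.3f\n",
    x$E, x$tau, x$mx_skill, x$my_skill
  ))
  invisible(x)
}
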