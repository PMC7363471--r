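#' Classify a mixed-output trace as silent, spiking or seizing
#'
#' Interictal epileptiform discharges (spikes) appear in the mixed output as
#' millisecond-fast transients well above the band-limited ~10 Hz resting
#' activity, while ictal events are seconds-long trains of large discharges
#' with a deep negative deflection of the slow baseline (the epileptiform
#' `-x1` contribution). The classifier therefore (1) high-passes the trace
#' above the resting alpha band and thresholds at `k` robust standard
#' deviations (MAD), (2) merges suprathreshold samples into events, closing
#' gaps up to `gap_s`, (3) calls an event ictal when it lasts at least
#' `min_ictal_s` seconds *and* dips below the trace median by more than
#' three fast-scale MADs, and (4) counts the remaining suprathreshold
#' onsets as spikes with a refractory period.
#'
#' @param x numeric vector: mixed output of one region.
#' @param dt sample interval in seconds.
#' @param k threshold in robust SDs of the high-passed trace (default 6).
#' @param hp_hz high-pass cut-off in Hz (default 20, above the ~10 Hz
#'   resting rhythm).
#' @param refractory_s minimum separation of two spikes (default 0.2 s).
#' @param gap_s gap-closing window when merging discharges into candidate
#'   ictal events (default 1 s; discharges inside a seizure pause for
#'   fractions of a second).
#' @param min_ictal_s minimum ictal event duration (default 2 s).
#' @return A tibble with columns `class` (`"silent"`, `"spiking"` or
#'   `"seizing"`), `spike_rate` (events per minute, outside ictal spans),
#'   `n_spikes`, `n_seizures` and `ictal_s` (total ictal time).
#' @export
classify_trace <- function(x, dt, k = 6, hp_hz = 20, refractory_s = 0.2,
                           gap_s = 1, min_ictal_s = 2) {
  x <- as.numeric(x)
  n <- length(x)
  if (n * dt <= 60) abort("trace must be longer than 60 s for classification")
  fs <- 1 / dt
  if (hp_hz >= fs / 2) abort("sampling rate too low for the high-pass cut-off")
  bf <- signal::butter(3, hp_hz / (fs / 2), type = "high")
  hp <- as.numeric(signal::filtfilt(bf, x))
  s_hp <- stats::mad(hp)
  if (s_hp == 0) {
    return(tibble(class = "silent", spike_rate = 0, n_spikes = 0L,
                  n_seizures = 0L, ictal_s = 0))
  }
  above <- abs(hp) > k * s_hp

  # slow baseline and fast-scale MAD for the ictal-dip criterion
  bw <- round(2 / dt); if (bw %% 2 == 0) bw <- bw + 1
  baseline <- stats::runmed(x, bw)
  s_fast <- stats::mad(x - baseline)
  med <- stats::median(x)

  # candidate ictal events: suprathreshold runs merged across short pauses,
  # qualified by duration and a deep negative deflection
  ev <- .runs_with_gaps(above, round(gap_s / dt))
  ictal <- rep(FALSE, n)
  n_seiz <- 0L
  if (nrow(ev)) {
    for (r in seq_len(nrow(ev))) {
      i0 <- ev$start[r]; i1 <- ev$end[r]
      dur <- (i1 - i0 + 1) * dt
      dip <- stats::quantile(x[i0:i1], 0.1, names = FALSE)
      if (dur >= min_ictal_s && dip < med - 3 * s_fast) {
        ictal[i0:i1] <- TRUE
        n_seiz <- n_seiz + 1L
      }
    }
  }
  # spikes: unmerged suprathreshold onsets outside ictal spans
  spikes_at <- which(diff(c(FALSE, above & !ictal)) == 1)
  if (length(spikes_at) > 1) {
    keep <- c(TRUE, diff(spikes_at) * dt > refractory_s)
    spikes_at <- spikes_at[keep]
  }
  noningress <- (n - sum(ictal)) * dt / 60  # minutes outside ictal spans
  rate <- if (noningress > 0) length(spikes_at) / noningress else 0
  cls <- if (n_seiz > 0) "seizing" else if (length(spikes_at) > 0) "spiking" else "silent"
  tibble(class = cls, spike_rate = rate, n_spikes = length(spikes_at),
         n_seizures = n_seiz, ictal_s = sum(ictal) * dt)
}

# contiguous TRUE runs after closing gaps of at most `gap` samples
.runs_with_gaps <- function(flag, gap) {
  r <- rle(flag)
  if (gap > 0 && length(r$lengths) > 2) {
    short_gap <- !r$values & r$lengths <= gap
    # never close leading/trailing gaps
    short_gap[c(1, length(short_gap))] <- FALSE
    r$values[short_gap] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Locate a node bifurcation by bisection
#'
#' Finds the critical value of either the Hopf bifurcation parameter `a`
#' (damped vs self-sustained ~10 Hz oscillation; published value 1.74) or
#' the epileptogenicity `x0` (no autonomous seizure vs autonomous seizures;
#' published value -2.05) of the noise-free isolated node. Each candidate is
#' simulated deterministically from the computed interictal fixed point with
#' a small perturbation; for `a` the classifier compares the Hopf-pair
#' amplitude across two late windows (sustained if it neither decays nor
#' vanishes), for `x0` it detects an ictal transition (`x1 > 0`). The
#' critical values are deterministic properties, so no noise is used and no
#' seed is needed.
#'
#' @param scan `"a"` or `"x0"`.
#' @param range length-2 numeric bracketing the transition.
#' @param tol bisection tolerance (default 0.01).
#' @param duration simulated seconds per candidate (default 300 for `"a"`,
#'   150 for `"x0"`).
#' @param dt integration step in ms (default 0.1).
#' @return The critical value (bracket midpoint at tolerance), with the
#'   final bracket in `attr(, "bracket")`.
#' @export
#' @examples
#' \donttest{
#' find_bifurcation("a", c(1.5, 2.0), tol = 0.02)
#' }
find_bifurcation <- function(scan = c("a", "x0"), range, tol = 0.01,
                             duration = NULL, dt = 0.1) {
  scan <- match.arg(scan)
  if (length(range) != 2 || diff(range) <= 0)
    abort("range must be an increasing length-2 vector")
  if (is.null(duration)) duration <- if (scan == "a") 300 else 150

  supercritical <- function(val) {
    if (scan == "a") {
      pars <- node_parameters(x0 = -2.5, a = val)
      fp <- node_fixed_point(pars)
      init <- fp; init["x3"] <- init["x3"] + 0.1
      cfg <- integration_config(dt = dt, duration = duration, discard = 0,
                                noise_x2y2 = 0, noise_x3 = 0,
                                keep_every = 10, seed = 0)
      tr <- simulate_node(pars, cfg, init = init, store_states = TRUE)
      x3 <- tr$states[, 1, "x3"]
      idx <- findInterval(tr$time, c(duration * 0.2, duration * 0.6))
      amp1 <- diff(range(x3[idx == 1]))
      amp2 <- diff(range(x3[idx == 2]))
      amp2 > 1e-4 && amp2 > 0.8 * amp1
    } else {
      pars <- node_parameters(x0 = val, a = 1.5)
      fp <- node_fixed_point(pars)
      init <- fp; init["x1"] <- init["x1"] + 0.01
      cfg <- integration_config(dt = dt, duration = duration, discard = 0,
                                noise_x2y2 = 0, noise_x3 = 0,
                                keep_every = 10, seed = 0)
      tr <- simulate_node(pars, cfg, init = init, store_states = TRUE)
      any(tr$states[, 1, "x1"] > 0)
    }
  }

  lo <- range[1]; hi <- range[2]
  f_lo <- supercritical(lo); f_hi <- supercritical(hi)
  if (f_lo == f_hi)
    abort("no transition inside the scan range; widen the bracket")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (supercritical(mid) == f_lo) lo <- mid else hi <- mid
  }
  out <- (lo + hi) / 2
  attr(out, "bracket") <- c(lo, hi)
  out
}
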