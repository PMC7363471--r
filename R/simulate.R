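#' Network coupling parameters
#'
#' Two global coupling constants scale the connectome weights: `k_s` for the
#' slow permittivity pathway between Epileptor subpopulations (fixed at 0.1,
#' strong enough to carry seizure/spike spread) and `k_rs` for the fast
#' diffusive pathway between Hopf subpopulations (the free parameter swept
#' when fitting resting-state data; the fitted optimum for real connectomes
#' is of order 20).
#'
#' @param k_s permittivity coupling (default 0.1).
#' @param k_rs diffusive Hopf coupling (default 0).
#' @return A list of class `ii_coupling`.
#' @export
coupling_parameters <- function(k_s = 0.1, k_rs = 0) {
  if (k_s < 0 || k_rs < 0) abort("coupling constants must be non-negative")
  structure(list(k_s = k_s, k_rs = k_rs), class = "ii_coupling")
}

#' Integration configuration
#'
#' Settings of the stochastic Heun integration: step `dt` in milliseconds,
#' total simulated `duration` and initial `discard` in seconds, the additive
#' white-noise strengths on `x2`/`y2` and on `x3` (interpreted as diffusion
#' coefficients: each step receives a Gaussian increment of standard
#' deviation `sqrt(2 * strength * dt)`), the storage decimation
#' `keep_every` (every k-th step is retained, so the stored resolution is
#' `dt * keep_every`), and the integer `seed`. All randomness in a
#' simulation flows through this seed; per-node noise streams are derived
#' from it so results are reproducible bit for bit.
#'
#' @param dt integration step in ms (default 0.1).
#' @param duration total simulated time in s (default 1200, i.e. 20 min).
#' @param discard initial transient removed in s (default 20).
#' @param noise_x2y2 noise strength on `x2`, `y2` (default 0.00025).
#' @param noise_x3 noise strength on `x3` (default 0.02).
#' @param keep_every storage decimation factor (default 10).
#' @param seed integer RNG seed (default 1).
#' @return A list of class `ii_config`.
#' @export
integration_config <- function(dt = 0.1, duration = 1200, discard = 20,
                               noise_x2y2 = 0.00025, noise_x3 = 0.02,
                               keep_every = 10, seed = 1) {
  if (dt <= 0) abort("dt must be positive")
  if (discard >= duration) abort("discard must be smaller than duration")
  if (noise_x2y2 < 0 || noise_x3 < 0) abort("noise strengths must be non-negative")
  structure(list(dt = dt, duration = duration, discard = discard,
                 noise_x2y2 = noise_x2y2, noise_x3 = noise_x3,
                 keep_every = as.integer(keep_every),
                 seed = as.integer(seed)),
            class = "ii_config")
}

#' Network drift (reference implementation)
#'
#' Assembles the deterministic drift of every node, including the
#' permittivity coupling `k_s * sum_j C_ij (x1_j - x1_i)` into the slow
#' variable and the diffusive coupling `k_rs * sum_j C_ij (x3_j - x3_i)`
#' into the Hopf variable, with instantaneous transmission. This R-level
#' routine exists for transparency and testing; [simulate_network()] uses
#' the compiled equivalent.
#'
#' @param states 8 x n matrix of node states (rows in state order).
#' @param conn an [connectome()].
#' @param maps epileptogenicity map as returned by [build_epi_map()] (a
#'   tibble with columns `x0`, `a`, `p`, `b2`, one row per region).
#' @param coupling an [coupling_parameters()] object.
#' @return 8 x n matrix of derivatives.
#' @export
network_drift <- function(states, conn, maps, coupling = coupling_parameters()) {
  n <- nrow(conn)
  if (!is.matrix(states) || nrow(states) != 8 || ncol(states) != n)
    abort("states must be an 8 x n_regions matrix")
  if (nrow(maps) != n)
    abort("epileptogenicity map size does not match connectome")
  strength <- rowSums(conn)
  cz <- coupling$k_s * (as.numeric(conn %*% states[1, ]) - strength * states[1, ])
  cx <- coupling$k_rs * (as.numeric(conn %*% states[7, ]) - strength * states[7, ])
  out <- matrix(0, 8, n, dimnames = list(.state_names, rownames(conn)))
  for (i in seq_len(n)) {
    pars <- node_parameters(x0 = maps$x0[i], a = maps$a[i], p = maps$p[i],
                            b2 = maps$b2[i])
    out[, i] <- node_drift(states[, i], pars, coupling_z = cz[i],
                           coupling_x3 = cx[i])
  }
  out
}

#' One stochastic Heun step (reference implementation)
#'
#' Predictor-corrector Heun step for an additive-noise SDE: the same noise
#' increment `xi` enters the predictor and the corrected state, matching the
#' convention of the compiled integrator. Exposed for testing the scheme
#' against closed forms on simple drifts.
#'
#' @param x state vector.
#' @param drift_fn function of `x` returning the drift.
#' @param dt time step.
#' @param xi noise increment vector (same length as `x`); use zeros for a
#'   deterministic step.
#' @return The next state.
#' @export
heun_step <- function(x, drift_fn, dt, xi = numeric(length(x))) {
  if (dt <= 0) abort("dt must be positive")
  k1 <- drift_fn(x)
  xp <- x + dt * k1 + xi
  k2 <- drift_fn(xp)
  out <- x + dt / 2 * (k1 + k2) + xi
  if (!all(is.finite(out))) abort("non-finite state after Heun step")
  out
}

#' Simulate the coupled brain network
#'
#' Integrates the extended-Epileptor network with the stochastic Heun scheme
#' at step `config$dt` (ms), injecting additive white Gaussian noise into
#' `x2`, `y2` and `x3`. Initial conditions are drawn from a unit normal
#' centred on the interictal rest state (one draw per node from its own
#' seed-derived stream); the first `config$discard` seconds are removed. The
#' mixed output `u_i = p_i (x2 - x1) + (1 - p_i) x3` is stored at the
#' decimated resolution.
#'
#' @param conn an [connectome()].
#' @param map epileptogenicity map from [build_epi_map()], or `NULL` for the
#'   spike-free defaults.
#' @param coupling an [coupling_parameters()] object.
#' @param config an [integration_config()] object.
#' @param init optional 8 x n matrix of initial states (overrides the random
#'   draw; used by the deterministic bisection routines).
#' @param store_states also keep all eight state variables (memory-hungry
#'   for long runs; default `FALSE`).
#' @return An object of class `ii_trajectory`: list with `time` (seconds,
#'   starting at `config$discard`), `output` (time x region matrix), the
#'   `map`, `coupling`, `config`, and optionally `states`
#'   (time x region x variable array).
#' @export
#' @examples
#' conn <- synthetic_connectome(3, seed = 1)
#' traj <- simulate_network(conn, config = integration_config(duration = 22))
#' dim(traj$output)
simulate_network <- function(conn, map = NULL,
                             coupling = coupling_parameters(),
                             config = integration_config(),
                             init = NULL, store_states = FALSE) {
  stopifnot(inherits(conn, "ii_connectome"))
  n <- nrow(conn)
  if (is.null(map)) {
    map <- build_epi_map(tibble(region = rownames(conn), zone = "NIZ"),
                         scenario = "spike_free")
  }
  if (nrow(map) != n || !all(map$region == rownames(conn)))
    abort("epileptogenicity map does not match connectome regions")
  n_steps <- round(config$duration * 1000 / config$dt)
  discard_steps <- round(config$discard * 1000 / config$dt)
  res <- .ee_simulate_cpp(unclass(conn), map$x0, map$a, map$p, map$b2,
                          coupling$k_s, coupling$k_rs, config$dt,
                          as.integer(n_steps), config$keep_every,
                          as.integer(discard_steps), config$noise_x2y2,
                          config$noise_x3, as.double(config$seed), init,
                          store_states, 3.1, 0.45, 28571, 25, 0.01, 0.02, 0)
  dt_stored <- config$dt * config$keep_every / 1000
  nt <- nrow(res$output)
  colnames(res$output) <- rownames(conn)
  out <- list(time = config$discard + (seq_len(nt) - 1L) * dt_stored,
              output = res$output, dt = dt_stored, map = map,
              coupling = coupling, config = config)
  if (store_states) {
    st <- res$states
    dimnames(st) <- list(NULL, rownames(conn), .state_names)
    out$states <- st
  }
  structure(out, class = "ii_trajectory")
}

#' @export
print.ii_trajectory <- function(x, ...) {
  cat("<ii_trajectory> ", ncol(x$output), " regions, ",
      length(x$time), " samples at dt = ", x$dt * 1000, " ms (",
      format(x$time[1], digits = 4), "-",
      format(tail(x$time, 1), digits = 5), " s)\n", sep = "")
  invisible(x)
}

#' Simulate one isolated node
#'
#' Convenience wrapper around [simulate_network()] for a single uncoupled
#' region.
#'
#' @param params an [node_parameters()] object.
#' @param config an [integration_config()] object.
#' @inheritParams simulate_network
#' @return An `ii_trajectory` with one region.
#' @export
simulate_node <- function(params = node_parameters(),
                          config = integration_config(), init = NULL,
                          store_states = FALSE) {
  conn <- connectome(matrix(0, 1, 1), labels = "node", normalise = FALSE)
  map <- tibble(region = "node", zone = "NIZ", x0 = params$x0, a = params$a,
                p = params$p, b2 = params$b2)
  if (!is.null(init) && is.null(dim(init))) init <- matrix(init, 8, 1)
  simulate_network(conn, map, coupling_parameters(k_s = 0, k_rs = 0),
                   config, init = init, store_states = store_states)
}
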