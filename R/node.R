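#' Parameters of one extended-Epileptor node
#'
#' Each brain region is a hybrid neural mass: an Epileptor subpopulation
#' (variables `x1, y1, z, x2, y2, g`) generating epileptiform discharges and
#' seizures, plus a supercritical-Hopf oscillator pair (`x3, y3`) generating
#' physiological ~10 Hz resting activity. Three parameters are regionally
#' tunable: the epileptogenicity `x0` (the node seizes autonomously above
#' `x0_critic` of about -2.05), the Hopf bifurcation parameter `a` (damped
#' below, self-sustained oscillation above `a_critic = 1.74`), and the mixing
#' ratio `p` weighting epileptiform against healthy activity in the output.
#' `b2` scales the slow drive `g` onto the spike-generating second
#' population: lower `b2` means more frequent interictal spikes.
#'
#' The remaining constants are fixed at their published values:
#' `Iext1 = 3.1`, `Iext2 = 0.45`, `tau0 = 28571`, `tau2 = 25`,
#' `gamma = 0.01`, `d = 0.02`, `m = 0` (time unit: milliseconds).
#'
#' @param x0 epileptogenicity (default -2.5, deeply subcritical).
#' @param a Hopf bifurcation parameter (default 1.74, the critical point).
#' @param p epileptogenic mixing ratio in `[0, 1]` (default 0.1).
#' @param b2 spike-frequency parameter (default 4).
#' @param Iext1,Iext2,tau0,tau2,gamma,d,m fixed model constants.
#' @return A list of class `ii_node_parameters`.
#' @export
node_parameters <- function(x0 = -2.5, a = 1.74, p = 0.1, b2 = 4,
                            Iext1 = 3.1, Iext2 = 0.45, tau0 = 28571,
                            tau2 = 25, gamma = 0.01, d = 0.02, m = 0) {
  if (p < 0 || p > 1) abort("mixing ratio p must lie in [0, 1]")
  if (tau0 <= 0 || tau2 <= 0 || gamma <= 0 || d <= 0)
    abort("time constants tau0, tau2, gamma, d must be positive")
  structure(list(x0 = x0, a = a, p = p, b2 = b2, Iext1 = Iext1,
                 Iext2 = Iext2, tau0 = tau0, tau2 = tau2, gamma = gamma,
                 d = d, m = m),
            class = "ii_node_parameters")
}

.state_names <- c("x1", "y1", "z", "x2", "y2", "g", "x3", "y3")

#' Deterministic drift of one extended-Epileptor node
#'
#' Reference R implementation of the right-hand side of the eight node
#' equations, including the two coupling inputs: `coupling_z` enters the slow
#' permittivity equation (network permittivity pathway) and `coupling_x3` the
#' Hopf equation (diffusive pathway). The compiled integrator uses the same
#' expressions; this function is the transparent single-node surface used by
#' root-finding and tests.
#'
#' @param state named (or ordered) numeric vector
#'   `(x1, y1, z, x2, y2, g, x3, y3)`.
#' @param params an [node_parameters()] object.
#' @param coupling_z,coupling_x3 scalar coupling inputs (default 0).
#' @return Named numeric vector of derivatives (per millisecond).
#' @export
node_drift <- function(state, params = node_parameters(),
                       coupling_z = 0, coupling_x3 = 0) {
  state <- as.numeric(state)
  if (length(state) != 8) abort("state must have 8 components")
  if (!all(is.finite(state))) abort("non-finite state: numerical blow-up")
  d <- .ee_node_drift_cpp(state, params$x0, params$a, params$b2,
                          coupling_z, coupling_x3,
                          params$Iext1, params$Iext2, params$tau0,
                          params$tau2, params$gamma, params$d, params$m)
  setNames(as.numeric(d), .state_names)
}

# pure-R transcription of the node equations; kept separate from the
# compiled path so the two can be cross-checked
node_drift_r <- function(state, params = node_parameters(),
                         coupling_z = 0, coupling_x3 = 0) {
  s <- as.numeric(state)
  x1 <- s[1]; y1 <- s[2]; z <- s[3]; x2 <- s[4]; y2 <- s[5]
  g <- s[6]; x3 <- s[7]; y3 <- s[8]
  P <- params
  nonlin <- if (x1 < 0) -x1^3 + 3 * x1^2 else
    (P$m - x2 + 0.6 * (z - 4)^2) * x1
  f2 <- if (x2 < -0.25) 0 else 6 * (x2 + 0.25)
  setNames(c(
    y1 - z + P$Iext1 + nonlin,
    1 - 5 * x1^2 - y1,
    (4 * (x1 - P$x0) - z - coupling_z) / P$tau0,
    -y2 + x2 - x2^3 + P$Iext2 + P$b2 * g - 0.3 * (z - 3.5),
    (-y2 + f2) / P$tau2,
    -P$gamma * (g - 0.1 * x1),
    P$d * (y3 - x3^3 + 3 * x3^2 + coupling_x3),
    P$d * (P$a - 10 * x3 - y3)), .state_names)
}

#' Interictal fixed point of an isolated node
#'
#' Finds the rest state of the noise-free node by multivariate root-finding
#' on [node_drift()], started from the interictal anchor. In the subcritical
#' regime this is the stable equilibrium; above the seizure threshold the
#' root still exists but is unstable (the bisection routines exploit this by
#' perturbing it).
#'
#' @inheritParams node_drift
#' @param tol drift-norm tolerance (default 1e-12).
#' @return Named state vector at the fixed point.
#' @export
node_fixed_point <- function(params = node_parameters(), tol = 1e-12) {
  guess <- c(-1.6, -12, 3, -1, 0, -0.16, 0.1, params$a - 1)
  f <- function(s) node_drift_r(s, params)
  # scale the slow z-equation so the Newton steps see comparable magnitudes
  fs <- function(s) { d <- f(s); d[3] <- d[3] * params$tau0 / 4; d }
  sol <- pracma::fsolve(fs, guess, tol = tol)
  st <- setNames(as.numeric(sol$x), .state_names)
  if (sqrt(sum(node_drift_r(st, params)^2)) > 1e-8)
    abort("fixed-point search did not converge")
  st
}

#' Mixed output of a node
#'
#' The observable signal of a region combines the epileptiform ensemble
#' (`x2 - x1`, the standard Epileptor field-potential proxy) weighted by the
#' mixing ratio `p`, and the healthy Hopf activity `x3` weighted by `1 - p`:
#' `u = p (x2 - x1) + (1 - p) x3`.
#'
#' @param state node state vector (or matrix with 8 columns / array).
#' @param p mixing ratio in `[0, 1]`.
#' @return Scalar (or vector) output signal.
#' @export
mixed_output <- function(state, p) {
  if (any(p < 0 | p > 1)) abort("mixing ratio p must lie in [0, 1]")
  if (is.matrix(state)) {
    unname(p * (state[, 4] - state[, 1]) + (1 - p) * state[, 7])
  } else {
    unname(p * (state[4] - state[1]) + (1 - p) * state[7])
  }
}
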