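#' Balloon-Windkessel haemodynamic parameters
#'
#' Rate constants and resting quantities of the Friston haemodynamic model
#' that transduces neural activity into the BOLD signal: signal decay
#' `kappa` (1/s), flow autoregulation `gamma` (1/s), mean transit time `tau`
#' (s), vessel stiffness exponent `alpha`, resting oxygen extraction `rho`,
#' resting blood-volume fraction `V0`, and the BOLD observation weights
#' `k1 = 7 rho`, `k2 = 2`, `k3 = 2 rho - 0.2`. These standard published
#' values are frozen here as part of the reproducibility surface.
#'
#' @param kappa signal decay rate (default 0.65).
#' @param gamma autoregulation rate (default 0.41).
#' @param tau transit time (default 0.98).
#' @param alpha stiffness exponent (default 0.32).
#' @param rho resting oxygen extraction fraction (default 0.34).
#' @param V0 resting venous volume fraction (default 0.02).
#' @return A list of class `ii_hemo_parameters`.
#' @export
hemodynamic_parameters <- function(kappa = 0.65, gamma = 0.41, tau = 0.98,
                                   alpha = 0.32, rho = 0.34, V0 = 0.02) {
  vals <- c(kappa, gamma, tau, alpha, rho, V0)
  if (any(vals <= 0)) abort("all haemodynamic parameters must be positive")
  structure(list(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha,
                 rho = rho, V0 = V0, k1 = 7 * rho, k2 = 2,
                 k3 = 2 * rho - 0.2),
            class = "ii_hemo_parameters")
}

#' Balloon-Windkessel forward model
#'
#' Integrates the four haemodynamic state equations (vasodilatory signal,
#' inflow, venous volume, deoxyhaemoglobin) per region, driven by the neural
#' mixed output, and returns the BOLD signal in percent. The neural drive is
#' demeaned per region and scaled by `gain` before entering the flow-inducing
#' signal (the model expects a dimensionless perturbation around baseline;
#' too strong a drive pushes flow or volume negative, which is an error).
#'
#' @param neural time x region matrix of neural activity (e.g.
#'   `traj$output`), or an `ii_trajectory`.
#' @param dt sample interval of `neural` in seconds (taken from the
#'   trajectory if one is given).
#' @param params an [hemodynamic_parameters()] object.
#' @param gain scaling of the demeaned neural drive (default 0.1).
#' @return Time x region matrix of percent BOLD at the neural resolution.
#' @export
balloon_windkessel <- function(neural, dt = NULL,
                               params = hemodynamic_parameters(),
                               gain = 0.1) {
  if (inherits(neural, "ii_trajectory")) {
    if (is.null(dt)) dt <- neural$dt
    neural <- neural$output
  }
  if (is.null(dt)) abort("dt must be supplied when neural is a matrix")
  neural <- as.matrix(neural)
  if (!all(is.finite(neural))) abort("neural input contains non-finite values")
  u <- sweep(neural, 2, colMeans(neural)) * gain
  bold <- .balloon_windkessel_cpp(u, dt, params$kappa, params$gamma,
                                  params$tau, params$alpha, params$rho,
                                  params$V0, params$k1, params$k2, params$k3)
  colnames(bold) <- colnames(neural)
  attr(bold, "dt") <- dt
  bold
}

#' Post-process raw BOLD into fMRI-like series
#'
#' Replicates the conditions of empirical resting-state fMRI: the raw BOLD
#' signal is (1) anti-alias low-passed and downsampled to the repetition
#' time `tr` (default 3.6 s), (2) the global mean signal is regressed out of
#' each region, and (3) band-pass filtered to 0.01-0.1 Hz with a zero-phase
#' third-order Butterworth filter. Steps 2 and 3 can be toggled; the
#' default order (regression, then filter) follows the usual pipeline.
#'
#' @param bold time x region matrix of raw BOLD (e.g. from
#'   [balloon_windkessel()]).
#' @param dt input sample interval in seconds (defaults to
#'   `attr(bold, "dt")`).
#' @param tr output repetition time in seconds (default 3.6).
#' @param band band-pass edges in Hz (default `c(0.01, 0.1)`).
#' @param global_regress regress out the global mean (default `TRUE`).
#' @param bandpass apply the band-pass (default `TRUE`).
#' @return An object of class `ii_bold`: the region x time matrix is stored
#'   transposed as time x region with attributes `tr` and `flags`.
#' @export
bold_postprocess <- function(bold, dt = attr(bold, "dt"), tr = 3.6,
                             band = c(0.01, 0.1), global_regress = TRUE,
                             bandpass = TRUE) {
  bold <- as.matrix(bold)
  if (is.null(dt)) abort("dt must be supplied")
  if (nrow(bold) * dt < 3 * tr) abort("BOLD series too short to downsample")
  # anti-alias low-pass at the Nyquist of the target TR, then pick samples;
  # the downsampled series has floor(duration / tr) volumes
  n_out <- floor(nrow(bold) * dt / tr)
  dec <- max(1L, round(tr / dt))
  if (dec > 1) {
    ny_in <- 1 / (2 * dt)
    lp <- signal::butter(3, (1 / (2 * tr)) / ny_in, type = "low")
    bold <- apply(bold, 2, function(x) as.numeric(signal::filtfilt(lp, x)))
    bold <- bold[seq(1, nrow(bold), by = dec), , drop = FALSE]
  }
  bold <- bold[seq_len(min(n_out, nrow(bold))), , drop = FALSE]
  if (global_regress) bold <- regress_global_mean(bold)
  if (bandpass) {
    fs <- 1 / tr
    lo <- band[1] / (fs / 2); hi <- band[2] / (fs / 2)
    if (hi >= 1) abort("band edge exceeds the Nyquist frequency of the TR")
    if (nrow(bold) < 30) abort("series too short for stable band-pass filtering")
    bp <- signal::butter(3, c(lo, hi), type = "pass")
    bold <- apply(bold, 2, function(x) as.numeric(signal::filtfilt(bp, x)))
  }
  if (anyNA(bold)) abort("post-processed BOLD contains missing values")
  structure(bold, tr = tr,
            flags = list(global_mean_regressed = global_regress,
                         bandpassed = bandpass),
            class = c("ii_bold", "matrix", "array"))
}

# residual of each column after regressing on the global (row) mean
regress_global_mean <- function(m) {
  gm <- rowMeans(m)
  apply(m, 2, function(x) stats::residuals(stats::lm.fit(cbind(1, gm), x)))
}

#' @export
print.ii_bold <- function(x, ...) {
  cat("<ii_bold> ", ncol(x), " regions x ", nrow(x), " volumes at TR = ",
      attr(x, "tr"), " s\n", sep = "")
  invisible(x)
}

#' Full forward chain from neural activity to fMRI-like BOLD
#'
#' `simulate -> balloon_windkessel -> bold_postprocess` in one call.
#'
#' @param traj an `ii_trajectory`.
#' @param tr repetition time in seconds (default 3.6).
#' @param gain neural drive gain (default 0.1).
#' @param ... passed to [bold_postprocess()].
#' @return An `ii_bold`.
#' @export
neural_to_bold <- function(traj, tr = 3.6, gain = 0.1, ...) {
  raw <- balloon_windkessel(traj, gain = gain)
  bold_postprocess(raw, dt = traj$dt, tr = tr, ...)
}

#' Read / write BOLD series as CSV with a JSON sidecar
#'
#' The matrix is written as time x region CSV with a header of region
#' labels; the repetition time and processing flags go to a `.json` sidecar
#' next to it.
#'
#' @param bold an `ii_bold`.
#' @param path CSV path.
#' @return `read_bold()` returns an `ii_bold`; `write_bold()` returns
#'   `path` invisibly.
#' @export
write_bold <- function(bold, path) {
  utils::write.csv(as.data.frame(unclass(bold)), path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(tr = attr(bold, "tr"), flags = attr(bold, "flags")),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  side <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(tr = 3.6, flags = list())
  structure(m, tr = meta$tr, flags = as.list(meta$flags),
            class = c("ii_bold", "matrix", "array"))
}
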