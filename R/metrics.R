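#' Static Pearson correlation connectivity (sPCC)
#'
#' Pearson correlation between every pair of regional time series over the
#' whole window — the classic static functional-connectivity matrix.
#'
#' @param bold time x region matrix (or `ii_bold`).
#' @return A symmetric correlation matrix of class `ii_spcc` with unit
#'   diagonal. Zero-variance regions yield `NA` entries and a warning (never
#'   silent `NaN`).
#' @export
static_pcc <- function(bold) {
  m <- as.matrix(unclass(bold))
  if (nrow(m) < 3) abort("need at least 3 time points for correlation")
  v <- apply(m, 2, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  if (any(v == 0)) {
    warn("zero-variance region(s): corresponding sPCC entries flagged NA")
    r[v == 0, ] <- NA
    r[, v == 0] <- NA
  }
  diag(r) <- 1
  structure(r, class = c("ii_spcc", "matrix", "array"))
}

#' Compare two sPCC matrices
#'
#' Pearson correlation between the strictly-upper-triangle entries of the
#' simulated and reference matrices (the diagonal is excluded).
#'
#' @param sim,emp sPCC matrices of equal size.
#' @return Scalar correlation in `[-1, 1]`.
#' @export
compare_spcc <- function(sim, emp) {
  if (!all(dim(sim) == dim(emp))) abort("sPCC matrices differ in size")
  iu <- upper.tri(sim)
  stats::cor(sim[iu], emp[iu], use = "complete.obs")
}

#' Sliding-window functional connectivity dynamics (FCD)
#'
#' Splits the BOLD series into sliding windows of `window_s` seconds
#' advancing by `step_tr` volumes (window length in samples is
#' `ceiling(window_s / TR)`; only fully contained windows are used: a
#' 344-volume series at TR 3.6 s gives 328 windows), computes the windowed
#' sPCC per window, and correlates the upper triangles of every window pair
#' into a window x window FCD matrix.
#'
#' @param bold an `ii_bold` (or time x region matrix with a `tr` attribute).
#' @param window_s window length in seconds (default 60).
#' @param step_tr window increment in volumes (default 1).
#' @param tr repetition time (defaults to `attr(bold, "tr")`).
#' @return A symmetric matrix of class `ii_fcd` with unit diagonal;
#'   attribute `window_starts` holds the first volume of each window.
#' @export
sliding_window_fcd <- function(bold, window_s = 60, step_tr = 1,
                               tr = attr(bold, "tr")) {
  m <- as.matrix(unclass(bold))
  if (is.null(tr)) abort("tr must be supplied")
  wlen <- ceiling(window_s / tr)
  nt <- nrow(m)
  if (nt < wlen) abort("series shorter than one window")
  starts <- seq(1L, nt - wlen + 1L, by = step_tr)
  iu <- upper.tri(diag(ncol(m)))
  tri <- vapply(starts, function(s0) {
    r <- suppressWarnings(stats::cor(m[s0:(s0 + wlen - 1L), , drop = FALSE]))
    r[iu]
  }, numeric(sum(iu)))
  fcd <- stats::cor(tri)
  diag(fcd) <- 1
  structure(fcd, window_starts = starts, window_len = wlen,
            class = c("ii_fcd", "matrix", "array"))
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Supremum distance between the empirical cumulative distribution
#' functions of two samples (typically the upper-triangle values of two FCD
#' matrices). Computed directly from the pooled jump points, so tied values
#' are handled exactly.
#'
#' @param x,y non-empty numeric samples.
#' @return The K-S statistic in `[0, 1]`.
#' @export
ks_distance <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  pts <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(pts)
  Fy <- stats::ecdf(y)(pts)
  max(abs(Fx - Fy))
}

#' Upper-triangle values of an FCD (or sPCC) matrix
#'
#' Convenience accessor for distribution-level comparisons.
#'
#' @param m square matrix.
#' @param exclude_band optionally exclude pairs of windows closer than this
#'   many steps (overlapping-window band); default 0 = keep all.
#' @return Numeric vector of strictly-upper-triangle entries.
#' @export
upper_triangle <- function(m, exclude_band = 0) {
  m <- as.matrix(unclass(m))
  iu <- which(upper.tri(m), arr.ind = TRUE)
  if (exclude_band > 0) iu <- iu[iu[, 2] - iu[, 1] > exclude_band, , drop = FALSE]
  m[iu]
}

#' Instantaneous phase via the Hilbert transform
#'
#' The analytic signal `z(t) = s(t) + i H(s(t))` of each (demeaned) regional
#' series yields an instantaneous phase per region. The first and last 5%
#' of samples are trimmed to suppress transform edge effects.
#'
#' @param bold time x region matrix of band-limited, zero-mean signals.
#' @param trim fraction trimmed at each end (default 0.05).
#' @return Time x region matrix of phases in `(-pi, pi]`. Constant regions
#'   raise an error (their phase is undefined).
#' @export
instantaneous_phase <- function(bold, trim = 0.05) {
  m <- as.matrix(unclass(bold))
  if (any(apply(m, 2, stats::sd) == 0))
    abort("constant region signal: instantaneous phase undefined")
  ph <- apply(m, 2, function(x) {
    x <- x - mean(x)
    Arg(.analytic_signal(x))
  })
  nt <- nrow(ph)
  keep <- seq.int(floor(nt * trim) + 1L, nt - floor(nt * trim))
  ph[keep, , drop = FALSE]
}

# analytic signal z(t) = s(t) + i H(s(t)) via the frequency-domain
# construction: double positive frequencies, zero negative ones
.analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Kuramoto order parameter
#'
#' Modulus of the mean unit phasor across regions at each time point:
#' 0 for full desynchronisation, 1 for full phase synchrony.
#'
#' @param phases time x region matrix of phases (or a numeric vector of
#'   phases at a single time point).
#' @return Numeric vector `R(t)` in `[0, 1]`.
#' @export
kuramoto_order <- function(phases) {
  if (is.null(dim(phases))) phases <- matrix(phases, nrow = 1)
  if (ncol(phases) < 2) abort("need at least 2 regions for the order parameter")
  Mod(rowMeans(exp(1i * phases)))
}

#' Coherence and metastability
#'
#' Time-mean and time-standard-deviation of the Kuramoto order parameter:
#' global phase coherence, and metastability (variability of synchrony).
#'
#' @param R numeric series of order-parameter values.
#' @return A tibble with columns `coherence` and `metastability`.
#' @export
coherence_metastability <- function(R) {
  if (!length(R)) abort("order-parameter series is empty")
  tibble(coherence = mean(R),
         metastability = if (length(R) > 1) stats::sd(R) else 0)
}

#' Coarse-grain a series for multiscale entropy
#'
#' Non-overlapping block means of length `scale`; the output has
#' `floor(N / scale)` points. Scale 1 returns the original series.
#'
#' @param x numeric series.
#' @param scale positive integer scale factor.
#' @return The coarse-grained series.
#' @export
coarse_grain <- function(x, scale) {
  scale <- as.integer(scale)
  if (scale < 1) abort("scale must be a positive integer")
  n <- length(x)
  if (scale > n) abort("scale exceeds the series length")
  if (scale == 1L) return(x)
  nb <- n %/% scale
  colMeans(matrix(x[seq_len(nb * scale)], nrow = scale))
}

#' Sample entropy
#'
#' Negative natural log of the conditional probability that two sequences of
#' `m` consecutive points within tolerance `r` (Chebyshev distance,
#' self-matches excluded) remain within tolerance at length `m + 1`. The
#' tolerance defaults to `r_factor` times the SD of the series; pass `r`
#' explicitly to hold it fixed across coarse-grained scales.
#'
#' @param x numeric series (length >= 10^m recommended).
#' @param m embedding length (default 1).
#' @param r_factor tolerance as a fraction of `sd(x)` (default 0.35).
#' @param r absolute tolerance; overrides `r_factor`.
#' @return Sample entropy (>= 0), or `Inf` with attribute
#'   `degenerate = TRUE` when no template pair matches (e.g. constant
#'   series, whose SD-based tolerance is zero).
#' @export
sample_entropy <- function(x, m = 1, r_factor = 0.35, r = NULL) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < m + 2) abort("series too short for sample entropy")
  if (is.null(r)) r <- r_factor * stats::sd(x)
  if (r <= 0) {
    # constant series: the SD-based tolerance collapses to zero
    out <- NaN
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  cnt <- .sampen_counts_cpp(x, as.integer(m), r)
  A <- cnt[1]; B <- cnt[2]
  if (B == 0 || A == 0) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  -log(A / B)
}

#' Multiscale entropy profile
#'
#' Sample entropy of successively coarse-grained versions of each regional
#' series, scales 1..13 by default (3.6-46.8 s at TR 3.6 s). The tolerance
#' is `r_factor` times the SD of the *original* (scale-1) series, held fixed
#' across scales — the standard multiscale-entropy convention.
#'
#' @param bold time x region matrix (or `ii_bold`).
#' @param scales integer scales (default `1:13`).
#' @param m embedding length (default 1).
#' @param r_factor tolerance factor (default 0.35).
#' @return A region x scale matrix of class `ii_mse`. A scale leaving fewer
#'   than 10 coarse-grained points raises an error naming the scale.
#' @export
mse_profile <- function(bold, scales = 1:13, m = 1, r_factor = 0.35) {
  x <- as.matrix(unclass(bold))
  nt <- nrow(x)
  bad <- scales[nt %/% scales < 10]
  if (length(bad))
    abort(paste0("series too short for scale ", bad[1], " (",
                 nt %/% bad[1], " coarse-grained points; need >= 10)"))
  out <- matrix(NA_real_, ncol(x), length(scales),
                dimnames = list(colnames(x), paste0("scale", scales)))
  for (j in seq_len(ncol(x))) {
    r <- r_factor * stats::sd(x[, j])
    for (k in seq_along(scales)) {
      se <- sample_entropy(coarse_grain(x[, j], scales[k]), m = m, r = r)
      out[j, k] <- as.numeric(se)
    }
  }
  structure(out, scales = scales, class = c("ii_mse", "matrix", "array"))
}

#' Root-mean-square distance between two MSE profiles
#'
#' @param p1,p2 matrices of identical shape.
#' @return Scalar RMSD (>= 0); infinite (degenerate) entries are excluded
#'   pairwise with a warning.
#' @export
rmsd <- function(p1, p2) {
  p1 <- as.matrix(unclass(p1)); p2 <- as.matrix(unclass(p2))
  if (!all(dim(p1) == dim(p2))) abort("MSE profiles differ in shape")
  d <- p1 - p2
  if (any(!is.finite(d))) {
    warn("degenerate entropy entries excluded from RMSD")
    d <- d[is.finite(d)]
  }
  sqrt(mean(d^2))
}

#' Six-number fit summary between simulated and reference BOLD
#'
#' Computes the five resting-state comparison metrics for one parameter
#' point: `corr` (sPCC upper-triangle correlation), `ks` (K-S distance of
#' the FCD upper-triangle distributions), `d_coh` and `d_meta` (absolute
#' coherence and metastability differences of the Kuramoto order
#' parameter), and `rmsd_mse` (RMSD of the multiscale-entropy profiles).
#' The composite Global Similarity score is added across a sweep by
#' [global_similarity()].
#'
#' @param sim,ref `ii_bold` objects of identical dimensions.
#' @param window_s FCD window (default 60 s).
#' @param scales MSE scales (default `1:13`; shorten for short series).
#' @return A one-row tibble.
#' @export
fit_summary <- function(sim, ref, window_s = 60, scales = 1:13) {
  if (!all(dim(sim) == dim(ref))) abort("BOLD series differ in dimensions")
  sp_s <- static_pcc(sim); sp_r <- static_pcc(ref)
  fcd_s <- sliding_window_fcd(sim, window_s = window_s)
  fcd_r <- sliding_window_fcd(ref, window_s = window_s)
  cm_s <- coherence_metastability(kuramoto_order(instantaneous_phase(sim)))
  cm_r <- coherence_metastability(kuramoto_order(instantaneous_phase(ref)))
  tibble(
    corr = compare_spcc(sp_s, sp_r),
    ks = ks_distance(upper_triangle(fcd_s), upper_triangle(fcd_r)),
    d_coh = abs(cm_s$coherence - cm_r$coherence),
    d_meta = abs(cm_s$metastability - cm_r$metastability),
    rmsd_mse = rmsd(mse_profile(sim, scales = scales),
                    mse_profile(ref, scales = scales)))
}

#' Global Similarity over a parameter sweep
#'
#' Combines the five comparison metrics into one score per sweep point: the
#' raw score is `d_coh + d_meta + (1 - corr) + ks + rmsd_mse^2` (each term
#' oriented so that smaller means a better fit; the entropy distance enters
#' quadratically to give the complexity profile more weight), then min-max
#' normalised over the sweep to the interval `[1, 2]`. The model's optimal
#' working point is the sweep point where GS is minimal.
#'
#' @param fits a data frame with columns `corr`, `ks`, `d_coh`, `d_meta`,
#'   `rmsd_mse` (one row per sweep point, e.g. stacked [fit_summary()]
#'   rows).
#' @return The input tibble with columns `gs_raw` and `gs` added; the
#'   optimum row index is stored in `attr(, "optimum")`.
#' @export
global_similarity <- function(fits) {
  need <- c("corr", "ks", "d_coh", "d_meta", "rmsd_mse")
  if (!all(need %in% names(fits))) abort("fit table is missing metric columns")
  if (nrow(fits) < 2) abort("normalisation needs at least 2 sweep points")
  raw <- fits$d_coh + fits$d_meta + (1 - fits$corr) + fits$ks +
    fits$rmsd_mse^2
  rng <- range(raw, na.rm = TRUE)
  if (diff(rng) == 0) {
    warn("degenerate sweep: all raw scores equal; GS set to 1 everywhere")
    gs <- rep(1, length(raw))
  } else {
    gs <- 1 + (raw - rng[1]) / (rng[2] - rng[1])
  }
  out <- as_tibble(fits)
  out$gs_raw <- raw
  out$gs <- gs
  attr(out, "optimum") <- which.min(gs)
  out
}
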