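.zone_levels <- c("EZ_IZ1", "PZ_IZ2", "NIZ")

normalise_zone <- function(z) {
  z <- toupper(gsub("[/ .-]", "_", trimws(z)))
  z[z %in% c("EZ", "IZ1", "EZ_IZ1")] <- "EZ_IZ1"
  z[z %in% c("PZ", "IZ2", "PZ_IZ2")] <- "PZ_IZ2"
  if (!all(z %in% .zone_levels))
    abort(paste0("unknown zone label(s): ",
                 paste(unique(z[!z %in% .zone_levels]), collapse = ", ")))
  z
}

#' Read a zone-assignment file
#'
#' A CSV with columns `region,zone`, zones being `EZ_IZ1` (or `EZ`),
#' `PZ_IZ2` (or `PZ`) and `NIZ`.
#'
#' @param path CSV path.
#' @return A tibble with columns `region` and `zone`.
#' @export
read_zones <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("region", "zone") %in% names(df)))
    abort("zones file must have columns 'region' and 'zone'")
  tibble(region = df$region, zone = normalise_zone(df$zone))
}

#' Build an epileptogenicity map for a scenario
#'
#' Translates a zone assignment (epileptogenic zone / primary irritative
#' zone `EZ_IZ1`, propagation / secondary irritative zone `PZ_IZ2`,
#' non-involved zone `NIZ`) into per-region node parameters
#' `(x0, a, p, b2)`:
#'
#' * `spike_free`: the epileptogenic population is silent everywhere —
#'   `p = 0.1`, `x0 = -2.5`, homogeneous `a` (caller-set).
#' * `spiking`: the epileptogenic population dominates in the involved
#'   zones — `p` = 0.9 / 0.7 / 0.1 and `x0` = -2.07 / -2.25 / -2.55 for
#'   EZ / PZ / NIZ (the x0 defaults sit at, 0.2 below, and 0.5 below the
#'   autonomous-seizure threshold of -2.05); `a = 1.74` everywhere.
#' * `hyperexcitable`: spike-free `p`/`x0`, but the involved zones operate
#'   in the supercritical oscillatory regime (`a = a_hyper` > 1.74) while
#'   the NIZ stays at the critical point.
#'
#' The NIZ mixing ratio in the spiking scenario follows the spike-free
#' definition (`p = 0.1`); all values can be overridden per zone.
#'
#' @param zones tibble with columns `region`, `zone` (see [read_zones()]).
#' @param scenario `"spike_free"`, `"spiking"` or `"hyperexcitable"`.
#' @param a homogeneous Hopf parameter of the scenario baseline
#'   (default 1.74).
#' @param a_hyper supercritical value for the involved zones in the
#'   hyperexcitable scenario (default 1.9).
#' @param b2 spike-frequency parameter (default 4).
#' @param p_zone,x0_zone optional named vectors (names in
#'   `EZ_IZ1, PZ_IZ2, NIZ`) overriding the scenario defaults.
#' @return A tibble of class `ii_map` with columns `region`, `zone`, `x0`,
#'   `a`, `p`, `b2`.
#' @export
build_epi_map <- function(zones,
                          scenario = c("spike_free", "spiking",
                                       "hyperexcitable"),
                          a = 1.74, a_hyper = 1.9, b2 = 4,
                          p_zone = NULL, x0_zone = NULL) {
  scenario <- match.arg(scenario)
  zones <- as_tibble(zones)
  if (!all(c("region", "zone") %in% names(zones)))
    abort("zones must have columns 'region' and 'zone'")
  zn <- normalise_zone(zones$zone)
  defaults <- switch(scenario,
    spike_free = list(
      p = c(EZ_IZ1 = 0.1, PZ_IZ2 = 0.1, NIZ = 0.1),
      x0 = c(EZ_IZ1 = -2.5, PZ_IZ2 = -2.5, NIZ = -2.5),
      a = c(EZ_IZ1 = a, PZ_IZ2 = a, NIZ = a)),
    spiking = list(
      p = c(EZ_IZ1 = 0.9, PZ_IZ2 = 0.7, NIZ = 0.1),
      x0 = c(EZ_IZ1 = -2.07, PZ_IZ2 = -2.25, NIZ = -2.55),
      a = c(EZ_IZ1 = a, PZ_IZ2 = a, NIZ = a)),
    hyperexcitable = list(
      p = c(EZ_IZ1 = 0.1, PZ_IZ2 = 0.1, NIZ = 0.1),
      x0 = c(EZ_IZ1 = -2.5, PZ_IZ2 = -2.5, NIZ = -2.5),
      a = c(EZ_IZ1 = a_hyper, PZ_IZ2 = a_hyper, NIZ = 1.74)))
  pv <- defaults$p; xv <- defaults$x0; av <- defaults$a
  if (!is.null(p_zone)) pv[names(p_zone)] <- p_zone
  if (!is.null(x0_zone)) xv[names(x0_zone)] <- x0_zone
  out <- tibble(region = zones$region, zone = zn,
                x0 = unname(xv[zn]), a = unname(av[zn]),
                p = unname(pv[zn]), b2 = b2)
  if (any(out$p < 0 | out$p > 1)) abort("mixing ratios must lie in [0, 1]")
  class(out) <- c("ii_map", class(out))
  out
}

#' Pseudo-empirical BOLD at known parameters
#'
#' Ground-truth generator for parameter-recovery experiments: runs the full
#' forward chain (network simulation in the spike-free scenario, the
#' Balloon-Windkessel model, fMRI-like post-processing) at a known
#' `(a, k_rs)` so the result can serve as a reference target whose
#' generating parameters are recorded.
#'
#' @param conn an [connectome()].
#' @param a generating Hopf parameter.
#' @param k_rs generating diffusive coupling.
#' @param seed RNG seed of the generating run.
#' @param config an [integration_config()] (its seed is replaced by `seed`).
#' @param tr repetition time (default 3.6 s).
#' @param ... passed to [neural_to_bold()].
#' @return An `ii_bold` with attribute `truth = list(a, k_rs, seed)`.
#' @export
pseudo_empirical_bold <- function(conn, a, k_rs, seed,
                                  config = integration_config(), tr = 3.6,
                                  ...) {
  config$seed <- as.integer(seed)
  map <- build_epi_map(tibble(region = rownames(conn), zone = "NIZ"),
                       "spike_free", a = a)
  traj <- simulate_network(conn, map, coupling_parameters(k_rs = k_rs),
                           config)
  bold <- neural_to_bold(traj, tr = tr, ...)
  attr(bold, "truth") <- list(a = a, k_rs = k_rs, seed = seed)
  bold
}

#' Working-point sweep over (a, K_rs)
#'
#' For every grid cell, simulates the spike-free scenario with the
#' homogeneous Hopf parameter `a` and coupling `k_rs`, forwards the neural
#' activity to fMRI-like BOLD, and scores it against the reference BOLD
#' with the five comparison metrics; the Global Similarity score is then
#' normalised over the sweep and its argmin is the fitted working point.
#' Each cell uses its own seed (`config$seed + cell index`) and a failed
#' cell (numerical blow-up) is recorded, never fatal.
#'
#' @param conn an [connectome()].
#' @param ref_bold reference `ii_bold` (empirical or
#'   [pseudo_empirical_bold()]).
#' @param a_grid,krs_grid numeric grids.
#' @param config an [integration_config()]; `config$seed` is the sweep base
#'   seed.
#' @param window_s,scales passed to [fit_summary()].
#' @param tr repetition time (default 3.6).
#' @param gain neural-to-BOLD gain (default 0.1).
#' @param global_regress regress the global mean out of the simulated BOLD
#'   (default `TRUE`; set `FALSE` to match a reference that was not
#'   global-regressed — on small symmetric toy networks the regression
#'   removes most of the coupling-induced synchrony signal).
#' @return A tibble of class `ii_sweep` (one row per cell: `a`, `k_rs`,
#'   `seed`, `failed`, metrics, `gs`), with the optimum cell in
#'   `attr(, "optimum")`.
#' @export
working_point_sweep <- function(conn, ref_bold, a_grid, krs_grid,
                                config = integration_config(),
                                window_s = 60, scales = 1:13, tr = 3.6,
                                gain = 0.1, global_regress = TRUE) {
  grid <- expand.grid(a = a_grid, k_rs = krs_grid, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$seed <- config$seed + i
    res <- tryCatch({
      map <- build_epi_map(tibble(region = rownames(conn), zone = "NIZ"),
                           "spike_free", a = grid$a[i])
      traj <- simulate_network(conn, map,
                               coupling_parameters(k_rs = grid$k_rs[i]), cfg)
      sim <- neural_to_bold(traj, tr = tr, gain = gain,
                            global_regress = global_regress)
      fit_summary(sim, ref_bold, window_s = window_s, scales = scales)
    }, error = function(e) {
      warn(paste0("sweep cell (a=", grid$a[i], ", k_rs=", grid$k_rs[i],
                  ") failed: ", conditionMessage(e)))
      tibble(corr = NA_real_, ks = NA_real_, d_coh = NA_real_,
             d_meta = NA_real_, rmsd_mse = NA_real_)
    })
    rows[[i]] <- mutate(res, a = grid$a[i], k_rs = grid$k_rs[i],
                        seed = cfg$seed, failed = anyNA(res))
  }
  out <- bind_rows(rows)
  ok <- !out$failed
  gs <- rep(NA_real_, nrow(out)); gs_raw <- gs
  if (sum(ok) >= 2) {
    g <- global_similarity(out[ok, ])
    gs[ok] <- g$gs; gs_raw[ok] <- g$gs_raw
  } else if (sum(ok) == 1) {
    # a single valid cell is trivially the optimum
    gs[ok] <- 1
    gs_raw[ok] <- out$d_coh[ok] + out$d_meta[ok] + (1 - out$corr[ok]) +
      out$ks[ok] + out$rmsd_mse[ok]^2
  }
  out$gs_raw <- gs_raw
  out$gs <- gs
  out <- out[, c("a", "k_rs", "seed", "failed", "corr", "ks", "d_coh",
                 "d_meta", "rmsd_mse", "gs_raw", "gs")]
  opt <- if (any(is.finite(gs))) which.min(gs) else NA_integer_
  attr(out, "optimum") <- opt
  attr(out, "sweep_type") <- "working_point"
  class(out) <- c("ii_sweep", class(out))
  out
}

# shared engine for the two one-region perturbation sweeps
.roi_sweep <- function(conn, rois, values, value_name, make_map, config,
                       coupling, window_s, scales, tr, gain,
                       control_map, spike_rate = FALSE) {
  control_traj <- simulate_network(conn, control_map, coupling, config)
  control_bold <- neural_to_bold(control_traj, tr = tr, gain = gain)
  sp_ctrl <- static_pcc(control_bold)
  grid <- expand.grid(roi = rois, value = values, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    roi <- grid$roi[i]; val <- grid$value[i]
    rows[[i]] <- tryCatch({
      map <- make_map(roi, val)
      traj <- simulate_network(conn, map, coupling, config)
      bold <- neural_to_bold(traj, tr = tr, gain = gain)
      fit <- fit_summary(bold, control_bold, window_s = window_s,
                         scales = scales)
      sp <- static_pcc(bold)
      idx <- which(rownames(conn) == roi)
      cmp <- compare_connectivity(sp[idx, -idx], sp_ctrl[idx, -idx])
      rate <- NA_real_
      if (spike_rate) {
        cl <- classify_trace(traj$output[, idx], traj$dt)
        rate <- cl$spike_rate
      }
      mutate(fit, roi = roi, !!value_name := val, seed = config$seed,
             failed = FALSE, spike_rate = rate,
             roi_spcc_mean = mean(sp[idx, -idx]),
             roi_spcc_mean_control = mean(sp_ctrl[idx, -idx]),
             z = cmp$z, p_value = cmp$p_value, direction = cmp$direction)
    }, error = function(e) {
      warn(paste0("sweep cell (", roi, ", ", value_name, "=", val,
                  ") failed: ", conditionMessage(e)))
      tibble(corr = NA_real_, ks = NA_real_, d_coh = NA_real_,
             d_meta = NA_real_, rmsd_mse = NA_real_, roi = roi,
             !!value_name := val, seed = config$seed, failed = TRUE,
             spike_rate = NA_real_, roi_spcc_mean = NA_real_,
             roi_spcc_mean_control = NA_real_, z = NA_real_,
             p_value = NA_real_, direction = NA_real_)
    })
  }
  out <- bind_rows(rows)
  front <- c("roi", value_name, "seed", "failed")
  out <- out[, c(front, setdiff(names(out), front))]
  class(out) <- c("ii_sweep", class(out))
  out
}

#' Interictal-spike sweep over (ROI, b2)
#'
#' Turns one region at a time into a spiking region (`p = 0.9`,
#' `x0 = -2.07`) with spike frequency set by `b2`, simulates with the same
#' seed as the spike-free control, and records the change-versus-control
#' metrics, the region's spike rate, its mean static connectivity to the
#' rest of the network, and the rank-sum comparison of the two connectivity
#' samples. ROI lists are conventionally ordered by ascending structural
#' node strength (see [node_strength()]).
#'
#' @param conn an [connectome()].
#' @param rois character vector of region names to perturb.
#' @param b2_grid values of the spike-frequency parameter (lower = more
#'   spikes).
#' @param config an [integration_config()]; the control and every condition
#'   share `config$seed`, so differences reflect the manipulation only.
#' @param coupling an [coupling_parameters()] object.
#' @param a homogeneous Hopf parameter (default 1.74).
#' @param window_s,scales,tr,gain forward-chain settings as in
#'   [working_point_sweep()].
#' @return An `ii_sweep` tibble, one row per (ROI, b2) cell.
#' @export
spiking_sweep <- function(conn, rois, b2_grid,
                          config = integration_config(),
                          coupling = coupling_parameters(k_rs = 20),
                          a = 1.74, window_s = 60, scales = 1:13, tr = 3.6,
                          gain = 0.1) {
  zones0 <- tibble(region = rownames(conn), zone = "NIZ")
  control_map <- build_epi_map(zones0, "spike_free", a = a)
  make_map <- function(roi, b2val) {
    m <- control_map
    i <- which(m$region == roi)
    if (!length(i)) abort(paste0("ROI not in connectome: ", roi))
    m$zone[i] <- "EZ_IZ1"; m$p[i] <- 0.9; m$x0[i] <- -2.07
    m$b2 <- ifelse(seq_len(nrow(m)) == i, b2val, m$b2)
    m
  }
  out <- .roi_sweep(conn, rois, b2_grid, "b2", make_map, config, coupling,
                    window_s, scales, tr, gain, control_map,
                    spike_rate = TRUE)
  attr(out, "sweep_type") <- "spiking"
  out
}

#' Hyperexcitability sweep over (ROI, a)
#'
#' Pushes one region at a time into the supercritical oscillatory regime
#' (`a_roi` above the critical 1.74, everything else unchanged from the
#' spike-free control at `a = 1.74`) and records the same change-versus-
#' control measures as [spiking_sweep()].
#'
#' @inheritParams spiking_sweep
#' @param a_grid supercritical values for the perturbed region.
#' @return An `ii_sweep` tibble, one row per (ROI, a) cell.
#' @export
hyperexcitability_sweep <- function(conn, rois, a_grid,
                                    config = integration_config(),
                                    coupling = coupling_parameters(k_rs = 20),
                                    window_s = 60, scales = 1:13, tr = 3.6,
                                    gain = 0.1) {
  zones0 <- tibble(region = rownames(conn), zone = "NIZ")
  control_map <- build_epi_map(zones0, "spike_free", a = 1.74)
  make_map <- function(roi, aval) {
    m <- control_map
    i <- which(m$region == roi)
    if (!length(i)) abort(paste0("ROI not in connectome: ", roi))
    m$a[i] <- aval
    m
  }
  out <- .roi_sweep(conn, rois, a_grid, "a_roi", make_map, config, coupling,
                    window_s, scales, tr, gain, control_map,
                    spike_rate = FALSE)
  attr(out, "sweep_type") <- "hyperexcitability"
  out
}

#' Rank-sum comparison of two connectivity samples
#'
#' Two-tailed Wilcoxon rank-sum (Mann-Whitney) test on two samples of
#' connectivity values (e.g. one region's correlations to the rest of the
#' network under condition vs control), via the normal approximation with
#' tie correction. Significance at p < 0.05 corresponds to |z| > 1.96; the
#' direction is the sign of the median difference (condition minus
#' control).
#'
#' @param cond,ctrl numeric samples, each with at least 2 values (with a
#'   single pair — e.g. a two-region involved zone — the comparison is not
#'   defined and an error is raised).
#' @return A tibble with `z`, `p_value`, `significant`, `direction`.
#' @export
compare_connectivity <- function(cond, ctrl) {
  cond <- cond[is.finite(cond)]; ctrl <- ctrl[is.finite(ctrl)]
  n1 <- length(cond); n2 <- length(ctrl)
  if (n1 < 2 || n2 < 2)
    abort("each sample needs at least 2 values for a rank-sum comparison")
  rk <- rank(c(cond, ctrl))
  W <- sum(rk[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  ties <- table(rk)
  sig2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sig2 <= 0) {
    z <- 0
  } else {
    z <- (W - mu) / sqrt(sig2)
  }
  p <- 2 * stats::pnorm(-abs(z))
  tibble(z = z, p_value = p, significant = abs(z) > 1.96,
         direction = sign(stats::median(cond) - stats::median(ctrl)))
}
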