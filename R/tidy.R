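#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulated trajectory
#'
#' @param x an `ii_trajectory`.
#' @param ... unused.
#' @return A long tibble with columns `time`, `region`, `output`.
#' @export
tidy.ii_trajectory <- function(x, ...) {
  df <- as_tibble(as.data.frame(x$output))
  df$time <- x$time
  tidyr::pivot_longer(df, -"time", names_to = "region",
                      values_to = "output")
}

#' Tidy a square connectivity-type matrix
#'
#' Works for `ii_spcc`, `ii_fcd` and `ii_connectome` objects.
#'
#' @param x a square matrix object.
#' @param ... unused.
#' @return A long tibble `row`, `col`, `value`.
#' @export
tidy.ii_spcc <- function(x, ...) .tidy_square(x)
#' @export
tidy.ii_fcd <- function(x, ...) .tidy_square(x)
#' @export
tidy.ii_connectome <- function(x, ...) .tidy_square(x)
#' @export
tidy.ii_mse <- function(x, ...) {
  m <- as.matrix(unclass(x))
  df <- as_tibble(as.data.frame(m), rownames = "region")
  tidyr::pivot_longer(df, -"region", names_to = "scale",
                      values_to = "sampen") |>
    mutate(scale = as.integer(sub("scale", "", .data$scale)))
}

.tidy_square <- function(x) {
  m <- as.matrix(unclass(x))
  rn <- rownames(m) %||% as.character(seq_len(nrow(m)))
  cn <- colnames(m) %||% as.character(seq_len(ncol(m)))
  tibble(row = rep(rn, times = ncol(m)),
         col = rep(cn, each = nrow(m)),
         value = as.vector(m))
}

#' One-row summary of a parameter sweep
#'
#' @param x an `ii_sweep`.
#' @param ... unused.
#' @return A one-row tibble: number of cells, failures, and (for a
#'   working-point sweep) the optimum `a`, `k_rs` and minimal GS.
#' @export
glance.ii_sweep <- function(x, ...) {
  out <- tibble(n_cells = nrow(x), n_failed = sum(x$failed),
                sweep_type = attr(x, "sweep_type") %||% NA_character_)
  opt <- attr(x, "optimum")
  if (!is.null(opt) && length(opt) == 1 && is.finite(opt)) {
    out$a_opt <- x$a[opt]
    out$k_rs_opt <- x$k_rs[opt]
    out$gs_min <- x$gs[opt]
  }
  out
}

#' Heatmap of a connectivity-type matrix
#'
#' @param object an `ii_spcc`, `ii_fcd` or `ii_connectome`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ii_spcc <- function(object, ...) {
  .plot_square(object, "sPCC", limits = c(-1, 1))
}
#' @export
autoplot.ii_fcd <- function(object, ...) {
  .plot_square(object, "FCD", limits = c(-1, 1))
}
#' @export
autoplot.ii_connectome <- function(object, ...) {
  .plot_square(object, "weight", limits = c(0, 1))
}

.plot_square <- function(object, fill_name, limits) {
  df <- .tidy_square(object)
  rn <- unique(df$row)
  df$row <- factor(df$row, levels = rev(rn))
  df$col <- factor(df$col, levels = rn)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = limits, name = fill_name) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot simulated traces
#'
#' @param traj an `ii_trajectory`.
#' @param regions optional subset of region names.
#' @param window optional time window `c(from, to)` in seconds.
#' @return A ggplot object with one facet per region.
#' @export
plot_traces <- function(traj, regions = NULL, window = NULL) {
  df <- tidy.ii_trajectory(traj)
  if (!is.null(regions)) df <- filter(df, .data$region %in% regions)
  if (!is.null(window))
    df <- filter(df, .data$time >= window[1], .data$time <= window[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$output)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$region)) +
    ggplot2::labs(x = "time (s)", y = "mixed output") +
    ggplot2::theme_minimal()
}

#' Global-Similarity landscape of a working-point sweep
#'
#' @param sweep an `ii_sweep` from [working_point_sweep()].
#' @param metric column to plot (default `"gs"`).
#' @return A ggplot heat map over `(k_rs, a)` with the optimum marked.
#' @export
plot_gs_landscape <- function(sweep, metric = "gs") {
  stopifnot(metric %in% names(sweep))
  gg <- ggplot2::ggplot(sweep, ggplot2::aes(x = .data$k_rs, y = .data$a,
                                            fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = metric, direction = -1) +
    ggplot2::labs(x = expression(K[rs]), y = "a") +
    ggplot2::theme_minimal()
  opt <- attr(sweep, "optimum")
  if (!is.null(opt) && is.finite(opt))
    gg <- gg + ggplot2::annotate("point", x = sweep$k_rs[opt],
                                 y = sweep$a[opt], shape = 8, size = 3)
  gg
}
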