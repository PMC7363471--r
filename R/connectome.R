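#' Construct and validate a structural connectome
#'
#' A connectome is a symmetric, non-negative region-by-region weight matrix
#' with a zero diagonal (a region's self-connection is absorbed into its
#' neural-mass model), normalised so that the largest weight equals one.
#' Weights play the role of streamline counts from tractography.
#'
#' @param C square numeric matrix of connection weights.
#' @param labels character vector of region names; defaults to the matrix
#'   dimnames or `"R1"..."Rn"`.
#' @param normalise divide by the maximum weight so `max(C) == 1`
#'   (default `TRUE`).
#' @param symmetry_tol relative tolerance beyond which asymmetry is an error
#'   rather than noise (default `1e-8`).
#'
#' @return An object of class `ii_connectome`: the weight matrix with region
#'   labels as dimnames.
#' @export
#' @examples
#' conn <- connectome(matrix(c(0, 2, 2, 0), 2), labels = c("A", "B"))
#' max(conn) == 1
connectome <- function(C, labels = NULL, normalise = TRUE,
                       symmetry_tol = 1e-8) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) abort("connectome matrix must be square")
  if (!is.numeric(C) || anyNA(C)) abort("connectome weights must be numeric and non-missing")
  if (any(C < 0)) abort("connectome weights must be non-negative")
  scale <- max(abs(C))
  if (scale > 0 && max(abs(C - t(C))) > symmetry_tol * scale)
    abort("connectome matrix is asymmetric beyond tolerance")
  C <- (C + t(C)) / 2
  if (any(diag(C) != 0)) {
    warn("non-zero diagonal in connectome; self-connections set to 0")
    diag(C) <- 0
  }
  if (normalise && max(C) > 0) C <- C / max(C)
  if (is.null(labels)) labels <- rownames(C) %||% paste0("R", seq_len(nrow(C)))
  if (length(labels) != nrow(C))
    abort("number of labels does not match connectome size")
  dimnames(C) <- list(labels, labels)
  structure(C, class = c("ii_connectome", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ii_connectome <- function(x, ...) {
  cat("<ii_connectome> ", nrow(x), " regions, ",
      sum(x[upper.tri(x)] > 0), " edges, max weight ",
      format(max(x), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Read / write a connectome as CSV
#'
#' The on-disk format is a plain comma-separated square matrix with a header
#' row of region labels (an optional separate one-column label file overrides
#' the header). Reading validates, symmetrises within tolerance, zeroes the
#' diagonal (with a warning if it was non-zero) and normalises to unit
#' maximum; `write_connectome()` and `read_connectome()` round-trip exactly.
#'
#' @param path CSV file with the square weight matrix.
#' @param labels_path optional one-column file (no header) of region labels.
#' @param ... passed on to [connectome()].
#' @return `read_connectome()` returns an `ii_connectome`;
#'   `write_connectome()` returns `path` invisibly.
#' @export
read_connectome <- function(path, labels_path = NULL, ...) {
  df <- utils::read.csv(path, check.names = FALSE)
  C <- as.matrix(df)
  labels <- colnames(df)
  if (!is.null(labels_path)) {
    labels <- readLines(labels_path)
    labels <- labels[nzchar(trimws(labels))]
    if (length(labels) != nrow(C))
      abort("label file length does not match connectome size")
  }
  connectome(C, labels = labels, ...)
}

#' @rdname read_connectome
#' @param conn an `ii_connectome`.
#' @export
write_connectome <- function(conn, path, labels_path = NULL) {
  df <- as.data.frame(unclass(conn))
  colnames(df) <- rownames(conn)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(labels_path)) writeLines(rownames(conn), labels_path)
  invisible(path)
}

#' Generate a synthetic streamline-count-like connectome
#'
#' Emulates the statistics of DTI tractography weight matrices: symmetric,
#' zero diagonal, non-negative, heavy-tailed (log-normal) weights normalised
#' to unit maximum. Useful wherever a structural matrix is needed but no
#' subject data are available.
#'
#' @param n_regions number of regions (>= 2).
#' @param density fraction of off-diagonal pairs with a non-zero weight
#'   (default 1, i.e. fully connected; tractography matrices are dense).
#' @param sdlog log-normal shape parameter of the weights (default 1;
#'   larger values give heavier tails).
#' @param labels optional region names.
#' @param seed integer seed; the same seed always yields the same matrix.
#' @return An `ii_connectome`.
#' @export
#' @examples
#' conn <- synthetic_connectome(6, seed = 1)
synthetic_connectome <- function(n_regions, density = 1, sdlog = 1,
                                 labels = NULL, seed = 1) {
  if (n_regions < 2) abort("n_regions must be at least 2")
  if (density <= 0 || density > 1) abort("density must be in (0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- n_regions
  C <- matrix(0, n, n)
  iu <- which(upper.tri(C))
  w <- stats::rlnorm(length(iu), meanlog = 0, sdlog = sdlog)
  if (density < 1) {
    keep <- stats::runif(length(iu)) < density
    # keep a spanning path so no region is isolated
    w[!keep] <- 0
  }
  C[iu] <- w
  C <- C + t(C)
  if (any(rowSums(C) == 0)) {
    isolated <- which(rowSums(C) == 0)
    for (i in isolated) {
      j <- if (i == 1) 2 else i - 1
      C[i, j] <- C[j, i] <- stats::rlnorm(1, 0, sdlog)
    }
  }
  connectome(C, labels = labels)
}

# save/restore the global RNG state so explicitly seeded generators do not
# disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Node strength and total streamline count
#'
#' Row sums of the connectome (node strength) plus the total sum of weights,
#' the two graph summaries used to relate a region's structural embedding to
#' its dynamical influence.
#'
#' @param conn an `ii_connectome`.
#' @return A tibble with columns `region` and `strength`, ordered as the
#'   connectome, with the scalar total in `attr(, "total_streamlines")`.
#' @export
node_strength <- function(conn) {
  stopifnot(inherits(conn, "ii_connectome"))
  out <- tibble(region = rownames(conn), strength = unname(rowSums(conn)))
  attr(out, "total_streamlines") <- sum(conn) / 2
  out
}

#' Desikan-Killiany parcellation labels
#'
#' The packaged 84-region parcellation: 35 cortical labels per hemisphere
#' (the FreeSurfer Desikan-Killiany gyral atlas including the insula, plus
#' the pericallosal label retained by pipelines that keep it) and 7
#' subcortical structures per hemisphere. Label-to-abbreviation mapping is
#' best-effort where published abbreviation tables are incomplete.
#'
#' @return A tibble with columns `label` (e.g. `"lh.SFG"`), `hemisphere`
#'   (`"lh"`/`"rh"`), `abbrev`, `name` and `class`
#'   (`"cortical"`/`"subcortical"`).
#' @export
dk_labels <- function() {
  cortical <- c(
    BSTS = "Banks of the Superior Temporal Sulcus",
    CACG = "Caudal Anterior Cingulate Gyrus",
    CMFG = "Caudal Middle Frontal Gyrus",
    CC   = "Pericallosal",
    Cun  = "Cuneus",
    EntC = "Entorhinal Cortex",
    FuG  = "Fusiform Gyrus",
    IPC  = "Inferior Parietal Cortex",
    ITG  = "Inferior Temporal Gyrus",
    IstC = "Isthmus Cingulate",
    LOCC = "Lateral Occipital Cortex",
    LOFC = "Lateral Orbito-Frontal Cortex",
    LgG  = "Lingual Gyrus",
    MOFC = "Medial Orbito-Frontal Cortex",
    MTG  = "Middle Temporal Gyrus",
    PHiG = "ParaHippocampal Gyrus",
    PaC  = "Paracentral Lobule",
    Pop  = "Pars Opercularis",
    POr  = "Pars Orbitalis",
    PTr  = "Pars Triangularis",
    PC   = "Pericalcarine",
    PoG  = "PostCentral Gyrus",
    PCG  = "Posterior Cingulate Gyrus",
    PrG  = "Precentral Gyrus",
    PCunC = "PreCuneus Cortex",
    RACG = "Rostral Anterior Cingulate Gyrus",
    RMFG = "Rostral Middle Frontal Gyrus",
    SFG  = "Superior Frontal Gyrus",
    SPC  = "Superior Parietal Cortex",
    STG  = "Superior Temporal Gyrus",
    SMG  = "SupraMarginal Gyrus",
    FP   = "Frontal Pole",
    TmP  = "Temporal Pole",
    TrT  = "Transverse Temporal Gyrus",
    Ins  = "Insula")
  subcortical <- c(
    Th  = "Thalamus",
    Cd  = "Caudate",
    Pu  = "Putamen",
    Pal = "Pallidum",
    Hi  = "Hippocampus",
    Amg = "Amygdala",
    Acb = "Accumbens Area")
  build <- function(hemi) {
    bind_rows(
      tibble(hemisphere = hemi, abbrev = names(cortical),
             name = unname(cortical), class = "cortical"),
      tibble(hemisphere = hemi, abbrev = names(subcortical),
             name = unname(subcortical), class = "subcortical"))
  }
  out <- bind_rows(build("lh"), build("rh"))
  out$label <- paste0(out$hemisphere, ".", out$abbrev)
  out[, c("label", "hemisphere", "abbrev", "name", "class")]
}

#' Resolve zone abbreviations against the packaged parcellation
#'
#' Zone tables name regions as e.g. `"rLOFC"` or `"lHi"` (hemisphere prefix
#' plus abbreviation). This helper maps them to the packaged labels.
#'
#' @param x character vector of abbreviated region names.
#' @return Character vector of packaged labels; unresolvable entries raise an
#'   error naming them.
#' @export
resolve_dk_regions <- function(x) {
  labs <- dk_labels()
  hemi <- ifelse(substr(x, 1, 1) == "r", "rh",
                 ifelse(substr(x, 1, 1) == "l", "lh", NA))
  ab <- substr(x, 2, nchar(x))
  out <- character(length(x))
  for (i in seq_along(x)) {
    hit <- which(labs$hemisphere == hemi[i] & labs$abbrev == ab[i])
    if (is.na(hemi[i]) || length(hit) != 1)
      abort(paste0("cannot resolve region name: ", x[i]))
    out[i] <- labs$label[hit]
  }
  out
}
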