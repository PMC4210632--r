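#' Floor channel intensities at 1
#'
#' Background-subtracted intensities at or below 1 are set to 1 so that log
#' ratios stay finite; everything else is unchanged.
#'
#' @param raw A `RawIntensityData`.
#' @return The `RawIntensityData` with both channels floored.
#' @export
floor_intensities <- function(raw) {
  stopifnot(inherits(raw, "RawIntensityData"))
  raw$sample[raw$sample < 1] <- 1
  raw$reference[raw$reference < 1] <- 1
  raw
}

# Per-array lowess normalisation in M/A coordinates. Returns the matrix of
# normalised M values. span/iter are the lowess smoother span and robustness
# iterations.
ma_lowess <- function(sample_ch, reference_ch, span = 0.3, iter = 3L,
                      normalize = TRUE) {
  M <- log2(sample_ch / reference_ch)
  if (!normalize) return(M)
  A <- 0.5 * log2(sample_ch * reference_ch)
  for (j in seq_len(ncol(M))) {
    ok <- is.finite(M[, j]) & is.finite(A[, j])
    if (sum(ok) < 30) {
      stop("insufficient data: array '", colnames(M)[j], "' has fewer than 30 ",
           "finite (M, A) pairs", call. = FALSE)
    }
    fit <- stats::lowess(A[ok, j], M[ok, j], f = span, iter = iter)
    M[ok, j] <- M[ok, j] -
      stats::approx(fit$x, fit$y, xout = A[ok, j], rule = 2, ties = mean)$y
  }
  M
}

#' Lowess-normalise two-channel intensities
#'
#' Computes per-array M = log2(sample/reference) and A = mean log2 intensity
#' and subtracts a lowess fit of M on A, removing smooth intensity-dependent
#' dye bias. Arrays are normalised independently.
#'
#' @param raw A `RawIntensityData` (intensities should already be floored).
#' @param span Lowess smoother span (fraction of points).
#' @param iter Lowess robustness iterations.
#' @return Matrix of normalised log2 ratios, probe x array.
#' @export
lowess_normalize <- function(raw, span = 0.3, iter = 3L) {
  stopifnot(inherits(raw, "RawIntensityData"))
  ma_lowess(raw$sample, raw$reference, span = span, iter = iter)
}

#' Retain probes detected in enough arrays of enough groups
#'
#' A probe is retained if, in at least `min_groups` experimental groups, it is
#' flagged "positive and significant" on at least `ceiling(fraction * n_g)` of
#' that group's arrays (n_g counted after any array exclusions, i.e. over the
#' columns actually present in `flags`).
#'
#' @param flags Logical probe x array matrix of detection flags; column names
#'   must be array ids from `design`.
#' @param design An `sc_design` (possibly with rows for excluded arrays; only
#'   columns of `flags` are used).
#' @param fraction Required flagged fraction within a group (0 < fraction <= 1).
#' @param min_groups Minimum number of groups meeting the fraction.
#' @return Character vector of retained probe ids.
#' @export
filter_probes <- function(flags, design, fraction = 0.75, min_groups = 2L) {
  stopifnot(fraction > 0, fraction <= 1, min_groups >= 1)
  if (is.null(colnames(flags)) || !all(colnames(flags) %in% design$array_id)) {
    stop("dimension error: 'flags' columns must be named with array ids ",
         "present in 'design'", call. = FALSE)
  }
  grp <- paste(design$cross, design$stage)[match(colnames(flags), design$array_id)]
  per_group <- vapply(unique(grp), function(g) {
    cols <- which(grp == g)
    need <- ceiling(fraction * length(cols))
    rowSums(flags[, cols, drop = FALSE]) >= need
  }, logical(nrow(flags)))
  if (is.null(dim(per_group))) per_group <- matrix(per_group, nrow = nrow(flags))
  keep <- rowSums(per_group) >= min_groups
  rownames(flags)[keep]
}

#' Flag outlier arrays in principal-component space
#'
#' Projects arrays onto the first two principal components of the expression
#' matrix and flags arrays whose robust distance from the centre (per-axis
#' median/MAD standardisation) exceeds `threshold_sd`. Arrays are only
#' flagged, never dropped; exclusion is the analyst's decision.
#'
#' @param expr An `ExpressionMatrix` or a numeric probe x array matrix.
#' @param threshold_sd Distance threshold in robust SD units.
#' @return Character vector of flagged array ids (possibly empty).
#' @export
detect_outlier_arrays <- function(expr, threshold_sd = 3) {
  values <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  if (ncol(values) < 3) {
    stop("insufficient data: need at least 3 arrays for the outlier screen",
         call. = FALSE)
  }
  pc <- stats::prcomp(t(values), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  z <- apply(scores, 2, function(s) {
    sc <- stats::mad(s)
    if (sc == 0) sc <- stats::sd(s)
    if (is.na(sc) || sc == 0) return(rep(0, length(s)))
    (s - stats::median(s)) / sc
  })
  if (is.null(dim(z))) z <- matrix(z, nrow = nrow(scores))
  d <- sqrt(rowSums(z^2))
  colnames(values)[d > threshold_sd]
}

#' Quality-filter and normalise raw two-channel data
#'
#' The full preprocessing chain: optional array exclusion, intensity flooring,
#' per-array lowess normalisation of the log ratios, and the probe-retention
#' rule of [filter_probes()].
#'
#' @param raw A `RawIntensityData`.
#' @param fraction,min_groups Probe-retention rule (see [filter_probes()]).
#' @param span,iter Lowess parameters (see [lowess_normalize()]).
#' @param exclude_arrays Character vector of array ids to drop before
#'   anything else (e.g. arrays failing the PCA screen), or a named character
#'   vector whose names are array ids and values are reason codes.
#' @param normalize If `FALSE`, skip the lowess step and keep raw log2 ratios
#'   (useful for noiseless round-trip checks).
#' @return An object of class `ExpressionMatrix`: list with `values`
#'   (retained probe x array normalised log2 ratios), `samples` (array id,
#'   cross, stage), `retained_probes`, `excluded_arrays` (data frame with
#'   reason codes) and `n_input_probes`.
#' @export
qc_normalize <- function(raw, fraction = 0.75, min_groups = 2L,
                         span = 0.3, iter = 3L, exclude_arrays = NULL,
                         normalize = TRUE) {
  stopifnot(inherits(raw, "RawIntensityData"))
  excl <- data.frame(array_id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  if (length(exclude_arrays)) {
    ids <- if (is.null(names(exclude_arrays))) exclude_arrays else names(exclude_arrays)
    reasons <- if (is.null(names(exclude_arrays))) rep("excluded", length(ids)) else
      unname(exclude_arrays)
    miss <- setdiff(ids, colnames(raw$sample))
    if (length(miss)) {
      stop("unknown array id(s) in 'exclude_arrays': ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    keep <- setdiff(colnames(raw$sample), ids)
    raw$sample <- raw$sample[, keep, drop = FALSE]
    raw$reference <- raw$reference[, keep, drop = FALSE]
    raw$flags <- raw$flags[, keep, drop = FALSE]
    excl <- data.frame(array_id = ids, reason = reasons, stringsAsFactors = FALSE)
  }
  raw <- floor_intensities(raw)
  M <- ma_lowess(raw$sample, raw$reference, span = span, iter = iter,
                 normalize = normalize)
  kept <- filter_probes(raw$flags, raw$design, fraction = fraction,
                        min_groups = min_groups)
  samples <- raw$design[match(colnames(M), raw$design$array_id),
                        c("array_id", "cross", "stage")]
  rownames(samples) <- NULL
  structure(list(values = M[kept, , drop = FALSE],
                 samples = samples,
                 retained_probes = kept,
                 excluded_arrays = excl,
                 n_input_probes = nrow(M)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "of", x$n_input_probes,
      "probes retained,", ncol(x$values), "arrays",
      if (nrow(x$excluded_arrays)) paste0("(", nrow(x$excluded_arrays),
                                          " array(s) excluded)") else "", "\n")
  invisible(x)
}

# arrays (column indices of expr$values) belonging to one cross at one stage
arrays_of <- function(expr, cross, stage) {
  which(expr$samples$cross == cross & expr$samples$stage == stage)
}
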