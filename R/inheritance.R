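#' Per-probe cross means at one stage
#'
#' @param expr An `ExpressionMatrix`.
#' @param stage `"sac"` or `"feeding"`.
#' @param probe_ids Optional subset of retained probes (default all).
#' @return Data frame with `probe_id`, `stage`, `W`, `H`, `D` (mean
#'   normalised log2 expression in the wild, hybrid and domesticated cross).
#' @export
cross_means <- function(expr, stage, probe_ids = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"), stage %in% sc_stages)
  if (is.null(probe_ids)) probe_ids <- rownames(expr$values)
  miss <- setdiff(probe_ids, rownames(expr$values))
  if (length(miss)) {
    stop("unknown probe id(s): ", paste(utils::head(miss, 3), collapse = ", "),
         call. = FALSE)
  }
  v <- expr$values[probe_ids, , drop = FALSE]
  gm <- function(cross) rowMeans(v[, arrays_of(expr, cross, stage), drop = FALSE])
  data.frame(probe_id = probe_ids, stage = stage,
             W = gm("wild"), H = gm("hybrid"), D = gm("domesticated"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Additivity and dominance parameters per gene
#'
#' alpha = (W - D) / 2 measures the parental divergence (additivity
#' parameter); delta = (W + D) / 2 - H is the dominance deviation of the
#' hybrid from the parental midpoint. Their ratio delta/alpha locates the
#' hybrid between (or beyond) the parents; it is undefined when alpha = 0.
#'
#' @param means Data frame with columns `W`, `H`, `D` (id columns are carried
#'   through), e.g. from [cross_means()].
#' @return The input with `alpha`, `delta`, `ratio` and `ratio_defined`
#'   appended.
#' @examples
#' compute_alpha_delta(data.frame(W = 10, H = 8, D = 6))  # alpha 2, delta 0
#' @export
compute_alpha_delta <- function(means) {
  stopifnot(all(c("W", "H", "D") %in% names(means)))
  means$alpha <- (means$W - means$D) / 2
  means$delta <- (means$W + means$D) / 2 - means$H
  means$ratio_defined <- means$alpha != 0
  means$ratio <- ifelse(means$ratio_defined, means$delta / means$alpha, NA_real_)
  means
}

#' Classify the inheritance mode from delta/alpha
#'
#' Halved-interval convention: additive for delta/alpha in \[-0.5, 0.5),
#' maternal/domesticated dominant in \[0.5, 1.5), paternal/wild dominant in
#' \[-1.5, -0.5), overdominant outside \[-1.5, 1.5). Intervals are closed at
#' the lower bound and open at the upper bound; boundary ratios have
#' probability zero on continuous data. When alpha = 0 the ratio is
#' undefined: delta = 0 is classified additive and delta != 0 overdominant
#' (the hybrid leaves the degenerate parental range).
#'
#' @param records A data frame from [compute_alpha_delta()] (gets a `mode`
#'   column appended), or a numeric vector of ratios.
#' @return The augmented data frame, or a character vector of modes.
#' @examples
#' classify_mode(c(0, 1.2, -2))
#' @export
classify_mode <- function(records) {
  classify <- function(ratio, alpha, delta) {
    ifelse(!is.na(alpha) & alpha == 0,
           ifelse(delta == 0, "additive", "overdominant"),
           ifelse(ratio >= -0.5 & ratio < 0.5, "additive",
                  ifelse(ratio >= 0.5 & ratio < 1.5, "maternal_dominant",
                         ifelse(ratio >= -1.5 & ratio < -0.5,
                                "paternal_dominant", "overdominant"))))
  }
  if (is.numeric(records)) {
    return(classify(records, rep(1, length(records)), rep(0, length(records))))
  }
  stopifnot(all(c("alpha", "delta", "ratio") %in% names(records)))
  records$mode <- classify(records$ratio, records$alpha, records$delta)
  records
}

#' Summarise inheritance-mode proportions
#'
#' Per stage, the count and fraction of each mode, plus (as attribute
#' `overdominant_split`) the maternal:paternal split of the overdominant
#' records by the sign of delta/alpha (positive: hybrid beyond the
#' domesticated dam; negative: beyond the wild sire).
#'
#' @param records Classified records (data frame with `mode`, optionally
#'   `stage` and `ratio`).
#' @return Data frame with `stage`, `mode`, `n`, `fraction`, `percent`;
#'   fractions sum to 1 per stage.
#' @export
summarize_proportions <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("empty summary: no records to summarise", call. = FALSE)
  }
  stopifnot("mode" %in% names(records))
  if (is.null(records$stage)) records$stage <- "all"
  out <- do.call(rbind, lapply(split(records, records$stage), function(r) {
    n <- table(factor(r$mode, levels = sc_modes))
    data.frame(stage = r$stage[1], mode = sc_modes, n = as.integer(n),
               fraction = as.numeric(n) / nrow(r),
               percent = 100 * as.numeric(n) / nrow(r),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  if (!is.null(records$ratio)) {
    od <- records[records$mode == "overdominant", , drop = FALSE]
    split_df <- do.call(rbind, lapply(split(od, od$stage), function(r) {
      data.frame(stage = r$stage[1],
                 maternal = sum(r$ratio > 0, na.rm = TRUE),
                 paternal = sum(r$ratio < 0, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
    rownames(split_df) <- NULL
    attr(out, "overdominant_split") <- split_df
  }
  out
}

#' Replicate-level alpha and delta/alpha table for scatter plotting
#'
#' Point estimates of alpha and delta/alpha from the full group means plus
#' per-axis SDs computed by recomputing both quantities on matched replicate
#' arrays (replicate r of each cross, r = 1..min group size). Rows whose
#' |ratio| exceeds `plot_limit` (or whose ratio is undefined) are flagged
#' `excluded_from_plot` but kept in the table.
#'
#' @param expr An `ExpressionMatrix`.
#' @param stage `"sac"` or `"feeding"`.
#' @param probe_ids Probes (typically the ANOVA-significant unique-gene
#'   probes) to tabulate; default all retained probes.
#' @param plot_limit Absolute delta/alpha beyond which a row is flagged
#'   (default 5).
#' @return Data frame with `probe_id`, `alpha`, `delta`, `ratio`, `sd_alpha`,
#'   `sd_ratio`, `excluded_from_plot`.
#' @export
export_fig4_table <- function(expr, stage, probe_ids = NULL, plot_limit = 5) {
  rec <- compute_alpha_delta(cross_means(expr, stage, probe_ids))
  iw <- arrays_of(expr, "wild", stage)
  ih <- arrays_of(expr, "hybrid", stage)
  id <- arrays_of(expr, "domesticated", stage)
  nrep <- min(length(iw), length(ih), length(id))
  v <- expr$values[rec$probe_id, , drop = FALSE]
  alpha_r <- (v[, iw[seq_len(nrep)], drop = FALSE] -
                v[, id[seq_len(nrep)], drop = FALSE]) / 2
  delta_r <- (v[, iw[seq_len(nrep)], drop = FALSE] +
                v[, id[seq_len(nrep)], drop = FALSE]) / 2 -
    v[, ih[seq_len(nrep)], drop = FALSE]
  ratio_r <- delta_r / alpha_r
  ratio_r[!is.finite(ratio_r)] <- NA_real_
  row_sd <- function(m) apply(m, 1, stats::sd, na.rm = TRUE)
  data.frame(probe_id = rec$probe_id,
             alpha = rec$alpha, delta = rec$delta, ratio = rec$ratio,
             sd_alpha = row_sd(alpha_r), sd_ratio = row_sd(ratio_r),
             excluded_from_plot = !rec$ratio_defined |
               abs(rec$ratio) > plot_limit,
             stringsAsFactors = FALSE, row.names = NULL)
}
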