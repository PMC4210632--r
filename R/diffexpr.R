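# Row-wise Welch two-sample t-test on matrices (one row per probe).
# Degenerate rows (both sample variances zero) get p = 1 when the means are
# equal and p = 0 otherwise, by convention.
row_welch_t <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  deg <- se2 == 0
  if (any(deg)) {
    same <- deg & (mx == my)
    t[same] <- 0; p[same] <- 1
    diff <- deg & (mx != my)
    t[diff] <- sign(mx[diff] - my[diff]) * Inf
    p[diff] <- 0
  }
  list(t = t, df = df, p = p, mean_a = mx, mean_b = my)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided unpaired t-test with the Welch-Satterthwaite degrees of freedom,
#' as used for all pairwise cross comparisons. Wraps [stats::t.test()] and
#' adds the degenerate-data convention: when both samples have zero variance,
#' p is 1 for equal means and 0 otherwise.
#'
#' @param a,b Numeric vectors of log2 expression values (each n >= 2).
#' @return List with `t`, `df` and `p`.
#' @examples
#' welch_t(c(1, 2, 3, 4, 5, 6), c(3, 4, 5, 6, 7, 8))
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("insufficient replicates: each sample needs n >= 2", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Signed linear fold change from log2 group means
#'
#' The linear ratio `r = 2^(mean_a - mean_b)`; ratios below 1 are reported as
#' `-1/r` so that down-regulation is expressed on the same scale as
#' up-regulation (a ratio of 0.5 becomes -2).
#'
#' @param mean_a,mean_b Log2 group means (vectorised).
#' @return Signed fold change(s); |value| >= 1 always, negative meaning lower
#'   in the first-listed group.
#' @examples
#' signed_fold_change(1, 0)   #  2
#' signed_fold_change(0, 1)   # -2
#' @export
signed_fold_change <- function(mean_a, mean_b) {
  r <- 2^(mean_a - mean_b)
  ifelse(r >= 1, r, -1 / r)
}

#' Pairwise Welch t-test differential expression between crosses
#'
#' For one life stage, tests every retained probe in the three cross
#' comparisons (wild vs domesticated, wild vs hybrid, hybrid vs domesticated).
#' The strict criterion (p <= `p_strict` and |fold change| >= `fc_strict`,
#' no multiple-testing correction) defines the Venn-diagram lists; the lenient
#' criterion (p <= `p_lenient`, no fold-change gate) feeds the pathway
#' analysis. Fold changes are computed from log2-scale group means.
#'
#' @param expr An `ExpressionMatrix`.
#' @param stage `"sac"` or `"feeding"`.
#' @param p_strict,fc_strict,p_lenient Thresholds (defaults 0.01, 1.3, 0.05).
#' @return Named list of three data frames (one per comparison) with columns
#'   `probe_id`, `comparison`, `mean_a`, `mean_b`, `p_value`, `fold_change`,
#'   `passes_strict`, `passes_lenient`.
#' @export
pairwise_de <- function(expr, stage, p_strict = 0.01, fc_strict = 1.3,
                        p_lenient = 0.05) {
  stopifnot(inherits(expr, "ExpressionMatrix"), stage %in% sc_stages)
  comps <- list(c("wild", "domesticated"), c("wild", "hybrid"),
                c("hybrid", "domesticated"))
  out <- lapply(comps, function(cp) {
    ia <- arrays_of(expr, cp[1], stage)
    ib <- arrays_of(expr, cp[2], stage)
    if (length(ia) < 2 || length(ib) < 2) {
      stop("design error: group '", cp[which(c(length(ia), length(ib)) < 2)[1]],
           "' has fewer than 2 arrays at stage '", stage, "'", call. = FALSE)
    }
    w <- row_welch_t(expr$values[, ia, drop = FALSE],
                     expr$values[, ib, drop = FALSE])
    fc <- signed_fold_change(w$mean_a, w$mean_b)
    data.frame(probe_id = rownames(expr$values),
               comparison = paste0(cp[1], "_vs_", cp[2]),
               mean_a = w$mean_a, mean_b = w$mean_b,
               p_value = w$p, fold_change = fc,
               passes_strict = w$p <= p_strict & abs(fc) >= fc_strict,
               passes_lenient = w$p <= p_lenient,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(out) <- vapply(comps, function(cp) paste0(cp[1], "_vs_", cp[2]), "")
  out
}

#' Partition three id lists into the seven Venn regions
#'
#' @param a,b,c Character vectors (duplicates ignored).
#' @return List with `regions` (named list of the 7 disjoint id sets:
#'   `a_only`, `b_only`, `c_only`, `ab`, `ac`, `bc`, `abc`) and `sizes`.
#' @export
venn_partition <- function(a, b, c) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  abc <- intersect(intersect(a, b), c)
  regions <- list(
    a_only = setdiff(a, union(b, c)),
    b_only = setdiff(b, union(a, c)),
    c_only = setdiff(c, union(a, b)),
    ab = setdiff(intersect(a, b), c),
    ac = setdiff(intersect(a, c), b),
    bc = setdiff(intersect(b, c), a),
    abc = abc
  )
  list(regions = regions, sizes = lengths(regions))
}

#' Combine per-stage differential-expression lists by set union
#'
#' @param lists_a,lists_b Named lists of probe-id vectors, one element per
#'   comparison (names must match).
#' @return Named list of unions, per comparison.
#' @export
union_across_stages <- function(lists_a, lists_b) {
  stopifnot(setequal(names(lists_a), names(lists_b)))
  out <- lapply(names(lists_a), function(nm) union(lists_a[[nm]], lists_b[[nm]]))
  names(out) <- names(lists_a)
  out
}

# Row-wise Welch one-way ANOVA (unequal variances) over k groups, same
# statistic as stats::oneway.test(var.equal = FALSE). 'groups' is a factor
# over the columns of 'mat'. Rows where some group has zero variance get
# p = 1 if all group means are equal, else p = 0.
row_welch_anova <- function(mat, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  idx <- split(seq_len(ncol(mat)), groups)
  n <- vapply(idx, length, 1L)
  m <- vapply(idx, function(i) rowMeans(mat[, i, drop = FALSE]), numeric(nrow(mat)))
  if (is.null(dim(m))) m <- matrix(m, 1, dimnames = list(NULL, names(idx)))
  v <- vapply(seq_len(k), function(j) {
    i <- idx[[j]]
    rowSums((mat[, i, drop = FALSE] - m[, j])^2) / (n[j] - 1)
  }, numeric(nrow(mat)))
  if (is.null(dim(v))) v <- matrix(v, 1)
  w <- sweep(1 / v, 2, n, "*")            # n_j / v_j
  sw <- rowSums(w)
  mw <- rowSums(w * m) / sw
  tmp <- rowSums(sweep((1 - w / sw)^2, 2, n - 1, "/")) / (k^2 - 1)
  stat <- rowSums(w * (m - mw)^2) / ((k - 1) * (1 + 2 * (k - 2) * tmp))
  df2 <- 1 / (3 * tmp)
  p <- stats::pf(stat, k - 1, df2, lower.tail = FALSE)
  deg <- apply(v == 0, 1, any)
  if (any(deg)) {
    rng <- apply(m[deg, , drop = FALSE], 1, function(x) max(x) - min(x))
    p[deg] <- ifelse(rng == 0, 1, 0)
    stat[deg] <- ifelse(rng == 0, 0, Inf)
  }
  list(stat = stat, p = p, means = m)
}

#' Welch one-way ANOVA across the three crosses
#'
#' Per retained probe, the unequal-variance one-way ANOVA of expression across
#' wild, hybrid and domesticated at one stage (the gene-selection statistic
#' for the inheritance analysis). Single rows reproduce
#' [stats::oneway.test()].
#'
#' @param expr An `ExpressionMatrix`.
#' @param stage `"sac"` or `"feeding"`.
#' @return Data frame with `probe_id`, `p_value` and the three group means
#'   (`mean_wild`, `mean_hybrid`, `mean_domesticated`).
#' @export
welch_anova <- function(expr, stage) {
  stopifnot(inherits(expr, "ExpressionMatrix"), stage %in% sc_stages)
  cols <- which(expr$samples$stage == stage)
  groups <- expr$samples$cross[cols]
  if (any(table(factor(groups, levels = sc_crosses)) < 2)) {
    stop("insufficient replicates: every cross needs n >= 2 at stage '",
         stage, "'", call. = FALSE)
  }
  res <- row_welch_anova(expr$values[, cols, drop = FALSE],
                         factor(groups, levels = sc_crosses))
  data.frame(probe_id = rownames(expr$values),
             p_value = res$p,
             mean_wild = res$means[, "wild"],
             mean_hybrid = res$means[, "hybrid"],
             mean_domesticated = res$means[, "domesticated"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up FDR
#'
#' @param p Vector of p-values.
#' @param q_cut FDR level for the pass flags (default 0.10).
#' @return List with `q` (BH-adjusted q-values, via [stats::p.adjust()]) and
#'   `pass` (q <= `q_cut`).
#' @export
bh_fdr <- function(p, q_cut = 0.10) {
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, pass = q <= q_cut)
}

#' Collapse probe-level results to unique annotated genes
#'
#' Drops probes without annotation, then keeps, per gene, the probe with the
#' smallest p-value (ties broken by probe id, lexicographically).
#'
#' @param results Data frame with at least `probe_id` and `p_value` (extra
#'   columns are carried through).
#' @param annotation Data frame with `probe_id`, `gene_id`, `annotated`.
#' @return One row per unique annotated gene, with `gene_id` first.
#' @export
dedupe_unique_genes <- function(results, annotation) {
  stopifnot(all(c("probe_id", "p_value") %in% names(results)),
            all(c("probe_id", "gene_id", "annotated") %in% names(annotation)))
  m <- merge(results, annotation[, c("probe_id", "gene_id", "annotated")],
             by = "probe_id")
  m <- m[m$annotated, , drop = FALSE]
  m <- m[order(m$gene_id, m$p_value, m$probe_id), , drop = FALSE]
  m <- m[!duplicated(m$gene_id), , drop = FALSE]
  m$annotated <- NULL
  rownames(m) <- NULL
  m[, c("gene_id", setdiff(names(m), "gene_id"))]
}
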