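#' Per-gene contrast matrix between a treatment and a control cross
#'
#' Builds the one-on-one comparison scheme used by the directional set test:
#' for every (treatment array, control array) pair at one stage, the per-gene
#' log2 expression difference. With n vs m arrays this yields n x m pair
#' columns. If a probe-to-gene annotation is supplied, probes are first
#' collapsed to unique annotated genes, keeping the most significant probe per
#' gene (Welch t of treatment vs control by default).
#'
#' @param expr An `ExpressionMatrix`.
#' @param stage `"sac"` or `"feeding"`.
#' @param treat,control Cross labels (default domesticated vs wild, the wild
#'   fish being the control).
#' @param annotation Optional data frame with `probe_id`, `gene_id`,
#'   `annotated` for probe-to-gene collapsing.
#' @param probe_p Optional per-probe p-values (named by probe id) used for the
#'   collapsing; defaults to the treat-vs-control Welch t p-value.
#' @return Numeric gene x pair-column matrix of log2 differences, with
#'   attribute `pairs` (data frame of treat/control array ids per column).
#' @export
per_gene_contrast_stats <- function(expr, stage, treat = "domesticated",
                                    control = "wild", annotation = NULL,
                                    probe_p = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"), stage %in% sc_stages)
  it <- arrays_of(expr, treat, stage)
  ic <- arrays_of(expr, control, stage)
  if (!length(it) || !length(ic)) {
    stop("design error: treatment or control group missing at stage '",
         stage, "'", call. = FALSE)
  }
  values <- expr$values
  if (!is.null(annotation)) {
    if (is.null(probe_p)) {
      if (length(it) < 2 || length(ic) < 2) {
        stop("design error: n >= 2 per group needed to rank probes", call. = FALSE)
      }
      w <- row_welch_t(values[, it, drop = FALSE], values[, ic, drop = FALSE])
      probe_p <- stats::setNames(w$p, rownames(values))
    }
    res <- data.frame(probe_id = rownames(values),
                      p_value = unname(probe_p[rownames(values)]),
                      stringsAsFactors = FALSE)
    uni <- dedupe_unique_genes(res, annotation)
    values <- values[uni$probe_id, , drop = FALSE]
    rownames(values) <- uni$gene_id
  }
  pairs <- expand.grid(control = ic, treat = it,
                       KEEP.OUT.ATTRS = FALSE)[, c("treat", "control")]
  contrasts <- values[, pairs$treat, drop = FALSE] -
    values[, pairs$control, drop = FALSE]
  pair_df <- data.frame(treat = expr$samples$array_id[pairs$treat],
                        control = expr$samples$array_id[pairs$control],
                        stringsAsFactors = FALSE)
  colnames(contrasts) <- paste0(pair_df$treat, ".vs.", pair_df$control)
  attr(contrasts, "pairs") <- pair_df
  contrasts
}

# Stouffer variance for k pair columns: columns sharing a treatment or a
# control array share that array's whole measurement, so their set-level
# statistics have correlation exactly 1/2; Var(sum z) = k + 0.5 * S where S
# is the number of ordered column pairs sharing an array.
stouffer_variance <- function(pairs, k = nrow(pairs)) {
  if (is.null(pairs)) return(k)
  shared <- outer(pairs$treat, pairs$treat, "==") |
    outer(pairs$control, pairs$control, "==")
  diag(shared) <- FALSE
  k + 0.5 * sum(shared)
}

#' Directional gene-set perturbation test (GAGE style)
#'
#' For each pair column of the contrast matrix, the genes of a set are
#' compared with all background genes by a two-sample Welch t-test (one-tailed
#' for directions `up` and `down`; on |contrast| for `two_way`). The
#' per-column p-values are combined with a Stouffer sum whose variance is
#' adjusted for the dependence between pair columns that share an array (see
#' the methods vignette), and BH q-values are computed across sets within each
#' direction.
#'
#' @param contrasts Gene x pair-column matrix from
#'   [per_gene_contrast_stats()].
#' @param sets Named list of gene-id vectors.
#' @param directions Subset of `c("up", "down", "two_way")`.
#' @param min_size Minimum number of measured genes for a set to be tested
#'   (smaller sets are skipped and recorded in the `skipped` attribute).
#' @param q_cut FDR level for the `significant` flag (default 0.1).
#' @param set_groups Optional named character vector mapping set ids to
#'   functional groups.
#' @param exclude_group Optional functional group label(s) whose sets are
#'   excluded from testing altogether (e.g. `"Human Diseases"`).
#' @return Data frame with one row per tested set and direction: `set_id`,
#'   `functional_group`, `direction`, `p_value`, `bh_q`, `set_size`,
#'   `significant`; attribute `skipped` lists sets below `min_size`.
#' @export
gage_set_test <- function(contrasts, sets,
                          directions = c("up", "down", "two_way"),
                          min_size = 10, q_cut = 0.1,
                          set_groups = NULL, exclude_group = NULL) {
  directions <- match.arg(directions, several.ok = TRUE)
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (!is.null(exclude_group) && !is.null(set_groups)) {
    drop <- names(set_groups)[set_groups %in% exclude_group]
    sets <- sets[setdiff(names(sets), drop)]
  }
  measured <- rownames(contrasts)
  members <- lapply(sets, function(g) which(measured %in% g))
  sizes <- lengths(members)
  skipped <- names(sets)[sizes < min_size]
  keep <- sizes >= min_size
  members <- members[keep]
  sizes <- sizes[keep]
  if (!length(members)) {
    out <- data.frame(set_id = character(), functional_group = character(),
                      direction = character(), p_value = numeric(),
                      bh_q = numeric(), set_size = integer(),
                      significant = logical(), stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    return(out)
  }
  k <- ncol(contrasts)
  var_z <- stouffer_variance(attr(contrasts, "pairs"), k)
  n_all <- nrow(contrasts)

  column_p <- function(X, lower_tail) {
    # per-set, per-column Welch t of set genes vs background genes
    tot_s <- colSums(X); tot_q <- colSums(X^2)
    vapply(members, function(idx) {
      ns <- length(idx); nb <- n_all - ns
      ss <- colSums(X[idx, , drop = FALSE])
      sq <- colSums(X[idx, , drop = FALSE]^2)
      ms <- ss / ns
      mb <- (tot_s - ss) / nb
      vs <- pmax(sq - ns * ms^2, 0) / (ns - 1)
      vb <- pmax(tot_q - sq - nb * mb^2, 0) / (nb - 1)
      se2 <- vs / ns + vb / nb
      tt <- (ms - mb) / sqrt(se2)
      df <- se2^2 / ((vs / ns)^2 / (ns - 1) + (vb / nb)^2 / (nb - 1))
      stats::pt(tt, df, lower.tail = lower_tail)
    }, numeric(k))
  }

  one_direction <- function(dir) {
    p_cols <- switch(dir,
                     up = column_p(contrasts, lower_tail = FALSE),
                     down = column_p(contrasts, lower_tail = TRUE),
                     two_way = column_p(abs(contrasts), lower_tail = FALSE))
    if (is.null(dim(p_cols))) p_cols <- matrix(p_cols, nrow = k)
    p_cols <- pmin(pmax(p_cols, 1e-15), 1 - 1e-15)
    z <- stats::qnorm(p_cols, lower.tail = FALSE)
    S <- colSums(z)
    # empirical-null standardisation across sets when there are enough of
    # them (robust to a minority of truly perturbed sets); otherwise the
    # structural array-sharing variance
    scale_emp <- if (length(S) >= 30) stats::mad(S) else 0
    Z <- if (scale_emp > 0) (S - stats::median(S)) / scale_emp else
      S / sqrt(var_z)
    p <- stats::pnorm(Z, lower.tail = FALSE)
    q <- stats::p.adjust(p, method = "BH")
    data.frame(set_id = names(members),
               functional_group = if (is.null(set_groups)) NA_character_ else
                 unname(set_groups[names(members)]),
               direction = dir, p_value = p, bh_q = q,
               set_size = as.integer(sizes), significant = q <= q_cut,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, lapply(directions, one_direction))
  attr(out, "skipped") <- skipped
  out
}

#' Group significant sets into non-redundant clusters
#'
#' Greedy redundancy grouping: two significant sets are linked when they share
#' at least `overlap_fraction` of the smaller set's genes; groups are the
#' connected components of that link graph (transitive closure) and each group
#' is represented by its smallest-p set.
#'
#' @param results A [gage_set_test()] result (rows with `significant = TRUE`
#'   are grouped; a set significant in several directions is grouped once, at
#'   its smallest p).
#' @param sets Named list of gene-id vectors.
#' @param overlap_fraction Overlap threshold on the smaller set (default 0.5).
#' @return Data frame with `set_id`, `group`, `p_value`, `representative`.
#' @export
nonredundant_sets <- function(results, sets, overlap_fraction = 0.5) {
  sig <- results[results$significant, , drop = FALSE]
  if (!nrow(sig)) {
    return(data.frame(set_id = character(), group = integer(),
                      p_value = numeric(), representative = logical(),
                      stringsAsFactors = FALSE))
  }
  sig <- sig[order(sig$set_id, sig$p_value), , drop = FALSE]
  sig <- sig[!duplicated(sig$set_id), , drop = FALSE]
  ids <- sig$set_id
  n <- length(ids)
  adj <- diag(TRUE, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        gi <- unique(sets[[ids[i]]]); gj <- unique(sets[[ids[j]]])
        ov <- length(intersect(gi, gj)) / min(length(gi), length(gj))
        adj[i, j] <- adj[j, i] <- ov >= overlap_fraction
      }
    }
  }
  comp <- rep(NA_integer_, n)
  g <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    g <- g + 1L
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- g
      frontier <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
    }
  }
  out <- data.frame(set_id = ids, group = comp, p_value = sig$p_value,
                    stringsAsFactors = FALSE)
  out <- out[order(out$group, out$p_value, out$set_id), ]
  # one representative per group: smallest p, ties broken by set id
  out$representative <- FALSE
  out$representative[!duplicated(out$group)] <- TRUE
  rownames(out) <- NULL
  out
}

#' Genes of significant sets that change beyond the overall noise level
#'
#' A gene is "essential" when it belongs to at least one significant set and
#' its mean contrast deviates from the grand mean of all genes' mean contrasts
#' by more than `sd_mult` standard deviations of those means.
#'
#' @param contrasts Gene x pair-column matrix.
#' @param significant_sets List (or character vector of set ids plus `sets`)
#'   of gene-id vectors for the significant sets.
#' @param sd_mult Deviation threshold in SD units (default 1).
#' @return Data frame with `gene_id`, `mean_change`, `z` (deviation in SD
#'   units), ordered by |z| decreasing.
#' @export
essential_genes <- function(contrasts, significant_sets, sd_mult = 1) {
  if (!length(significant_sets)) {
    stop("at least one significant set is required", call. = FALSE)
  }
  mean_change <- rowMeans(contrasts)
  gm <- mean(mean_change)
  s <- stats::sd(mean_change)
  member <- rownames(contrasts) %in% unique(unlist(significant_sets))
  z <- (mean_change - gm) / s
  keep <- member & abs(mean_change - gm) > sd_mult * s
  out <- data.frame(gene_id = rownames(contrasts)[keep],
                    mean_change = mean_change[keep], z = z[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-abs(out$z)), ]
}

#' Hierarchically cluster genes on Pearson correlation distance
#'
#' Distance 1 - Pearson r across arrays, average linkage. Genes with zero
#' variance (correlation undefined) are reported and excluded.
#'
#' @param mat Numeric gene x array matrix (>= 2 genes with variance).
#' @return List with `order` (gene ids in dendrogram leaf order), `hclust`
#'   (the tree) and `excluded` (zero-variance gene ids).
#' @export
cluster_genes <- function(mat) {
  if (nrow(mat) < 2) {
    stop("insufficient data: need at least 2 genes to cluster", call. = FALSE)
  }
  v <- apply(mat, 1, stats::var)
  excluded <- rownames(mat)[v == 0]
  mat <- mat[v > 0, , drop = FALSE]
  if (nrow(mat) < 2) {
    stop("insufficient data: fewer than 2 genes with nonzero variance",
         call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(t(mat)))
  hc <- stats::hclust(d, method = "average")
  list(order = rownames(mat)[hc$order], hclust = hc, excluded = excluded)
}
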