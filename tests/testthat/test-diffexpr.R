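# Independent Welch oracle, coded directly from the t and
# Welch-Satterthwaite formulas (kept free of stats::t.test).
welch_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

test_that("welch_t matches an independently coded Welch formula", {
  a <- c(1, 2, 3, 4, 5, 6); b <- c(3, 4, 5, 6, 7, 8)
  got <- welch_t(a, b)
  ora <- welch_oracle(a, b)
  expect_equal(got$p, ora$p, tolerance = 1e-10)
  expect_equal(got$t, ora$t, tolerance = 1e-10)

  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1), sd = runif(1, 0.5, 2))
    expect_equal(welch_t(x, y)$p, welch_oracle(x, y)$p, tolerance = 1e-10)
  }

  same <- c(2, 2.5, 3)
  expect_equal(welch_t(same, same)$t, 0)
  expect_equal(welch_t(same, same)$p, 1)
  expect_equal(welch_t(c(1, 1), c(1, 1))$p, 1)   # degenerate, equal means
  expect_equal(welch_t(c(1, 1), c(2, 2))$p, 0)   # degenerate, unequal means
  expect_error(welch_t(1, c(1, 2)), "insufficient replicates")
})

test_that("signed fold change follows the -1/ratio convention", {
  expect_equal(signed_fold_change(1, 0), 2)
  expect_equal(signed_fold_change(0, 1), -2)   # linear ratio 0.5 -> -2
  expect_equal(signed_fold_change(3, 3), 1)
  set.seed(23)
  a <- rnorm(50); b <- rnorm(50)
  fab <- signed_fold_change(a, b); fba <- signed_fold_change(b, a)
  expect_true(all(abs(fab) >= 1))
  off <- abs(a - b) > 1e-12
  expect_equal(fab[off], -fba[off])            # antisymmetric off the fixed point
})

test_that("pairwise DE applies strict and lenient criteria per comparison", {
  # zero noise, planted effects straddling the 1.3-fold gate
  arch <- manual_arch(modes = rep("additive", 3), baseline = 10, effect = 4)
  arch$effect <- c(log2(1.3001), log2(1.25), 0)
  raw <- simulate_intensities(build_design(6), arch, noise_model(0, 0, 0, seed = 1))
  expr <- qc_normalize(raw, normalize = FALSE)
  de <- pairwise_de(expr, "feeding")
  wd <- de$wild_vs_domesticated
  expect_equal(names(de), c("wild_vs_domesticated", "wild_vs_hybrid",
                            "hybrid_vs_domesticated"))
  expect_true(wd$passes_strict[wd$probe_id == "G00001_1"])
  expect_false(wd$passes_strict[wd$probe_id == "G00002_1"])   # FC gate
  expect_true(wd$passes_lenient[wd$probe_id == "G00002_1"])
  expect_false(wd$passes_lenient[wd$probe_id == "G00003_1"])

  # strict list is always a subset of the lenient list
  raw_n <- make_sim(n_genes = 300, de_fraction = 0.3, biological_sd = 0.25,
                    technical_sd = 0.1, seed = 19)
  expr_n <- qc_normalize(raw_n)
  for (cmp in pairwise_de(expr_n, "sac")) {
    expect_true(all(cmp$probe_id[cmp$passes_strict] %in%
                      cmp$probe_id[cmp$passes_lenient]))
  }

  # row-wise statistics agree with stats::t.test probe by probe
  cmp <- pairwise_de(expr_n, "feeding")$wild_vs_hybrid
  iw <- which(expr_n$samples$cross == "wild" & expr_n$samples$stage == "feeding")
  ih <- which(expr_n$samples$cross == "hybrid" & expr_n$samples$stage == "feeding")
  for (p in sample(cmp$probe_id, 25)) {
    ref <- t.test(expr_n$values[p, iw], expr_n$values[p, ih])$p.value
    expect_equal(cmp$p_value[cmp$probe_id == p], ref, tolerance = 1e-12)
  }

  # planted high-SNR effects are recovered by the strict criterion
  raw_hi <- make_sim(n_genes = 1000, de_fraction = 1, effect = 1,
                     biological_sd = 0.15, technical_sd = 0.05, seed = 29)
  expr_hi <- qc_normalize(raw_hi)
  wd_hi <- pairwise_de(expr_hi, "feeding")$wild_vs_domesticated
  expect_gt(mean(wd_hi$passes_strict), 0.95)
})

test_that("venn partition agrees with brute-force set arithmetic", {
  v <- venn_partition(c("a", "b"), c("b", "c"), character())
  expect_equal(unname(v$sizes), c(1L, 1L, 0L, 1L, 0L, 0L, 0L))
  expect_equal(v$regions$ab, "b")

  ids <- letters[1:5]
  v2 <- venn_partition(ids, ids, ids)
  expect_equal(v2$regions$abc, ids)
  expect_equal(sum(v2$sizes), 5L)

  set.seed(37)
  pool <- sprintf("P%04d", 1:900)
  a <- sample(pool, 176); b <- sample(pool, 300); c <- sample(pool, 411)
  v3 <- venn_partition(a, b, c)
  expect_equal(sum(v3$sizes), length(union(union(a, b), c)))
  # regions are disjoint and reassemble the inputs
  all_ids <- unlist(v3$regions)
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_setequal(c(v3$regions$a_only, v3$regions$ab, v3$regions$ac,
                    v3$regions$abc), a)

  u <- union_across_stages(list(x = c("p1", "p2"), y = "p3"),
                           list(x = c("p2", "p4"), y = character()))
  expect_setequal(u$x, c("p1", "p2", "p4"))
  expect_equal(u$y, "p3")
})

test_that("welch ANOVA matches oneway.test and reduces to t^2 for two groups", {
  set.seed(41)
  mat <- matrix(rnorm(50 * 18), 50, 18)
  groups <- factor(rep(c("wild", "hybrid", "domesticated"), each = 6))
  res <- salmocross:::row_welch_anova(mat, groups)
  for (i in sample(50, 15)) {
    ref <- oneway.test(mat[i, ] ~ groups, var.equal = FALSE)
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-10)
    expect_equal(unname(res$stat[i]), unname(ref$statistic), tolerance = 1e-10)
  }

  # identical groups: p = 1
  flat <- matrix(rep(c(1, 2, 3), each = 1, times = 6), 1, 18)
  expect_equal(salmocross:::row_welch_anova(matrix(1, 1, 18), groups)$p, 1)

  # two-group Welch ANOVA equals the squared Welch t
  g2 <- factor(rep(c("a", "b"), each = 5))
  m2 <- matrix(rnorm(30 * 10), 30, 10)
  a2 <- salmocross:::row_welch_anova(m2, g2)
  t2 <- salmocross:::row_welch_t(m2[, 1:5], m2[, 6:10])
  expect_equal(a2$stat, t2$t^2, tolerance = 1e-10)
  expect_equal(a2$p, t2$p, tolerance = 1e-10)

  # the exported interface enforces the design
  raw <- make_sim(n_genes = 60, seed = 3)
  expr <- qc_normalize(raw, normalize = FALSE)
  expr$samples <- expr$samples[-(1:5), ]
  expr$values <- expr$values[, -(1:5)]
  expect_error(welch_anova(expr, "sac"), "insufficient replicates")
})

test_that("BH q-values follow the step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  res <- bh_fdr(p)
  expect_equal(res$q, rep(0.04, 4))   # min over j >= i of m p(j) / j
  expect_true(all(res$pass))

  set.seed(43)
  p2 <- runif(200)
  res2 <- bh_fdr(p2, q_cut = 0.10)
  expect_true(all(res2$q >= p2))
  ord <- order(p2)
  expect_true(all(diff(res2$q[ord]) >= -1e-15))
  expect_equal(res2$pass, res2$q <= 0.10)
})

test_that("unique-gene deduplication keeps the most significant annotated probe", {
  ann <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    gene_id = c("g1", "g1", "g2", "g3"),
                    annotated = c(TRUE, TRUE, FALSE, TRUE))
  res <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    p_value = c(0.005, 0.001, 1e-9, 0.2))
  uni <- dedupe_unique_genes(res, ann)
  expect_equal(uni$probe_id[uni$gene_id == "g1"], "p2")   # smaller p wins
  expect_false("g2" %in% uni$gene_id)                     # unannotated excluded
  expect_equal(nrow(uni), 2)

  # ties broken by probe id, lexicographically
  tie <- data.frame(probe_id = c("pZ", "pA"), p_value = c(0.01, 0.01))
  tie_ann <- data.frame(probe_id = c("pZ", "pA"), gene_id = "g",
                        annotated = TRUE)
  expect_equal(dedupe_unique_genes(tie, tie_ann)$probe_id, "pA")

  # simulated duplicate probes: one record per planted annotated gene
  raw <- make_sim(n_genes = 150, de_fraction = 0.5, biological_sd = 0.2,
                  technical_sd = 0.1, seed = 47,
                  duplicate_probe_fraction = 0.2, annotated_fraction = 0.8)
  expr <- qc_normalize(raw)
  an <- welch_anova(expr, "feeding")
  uni2 <- dedupe_unique_genes(an, raw$probes)
  keep_genes <- raw$architecture$gene_id[raw$architecture$annotated]
  measured <- unique(raw$probes$gene_id[raw$probes$probe_id %in%
                                          rownames(expr$values)])
  expect_setequal(uni2$gene_id, intersect(keep_genes, measured))
  # per gene, the reported p is the minimum over its measured probes
  for (g in sample(uni2$gene_id, 10)) {
    probes_g <- intersect(raw$probes$probe_id[raw$probes$gene_id == g],
                          an$probe_id)
    expect_equal(uni2$p_value[uni2$gene_id == g],
                 min(an$p_value[an$probe_id %in% probes_g]))
  }
})
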