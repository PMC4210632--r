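test_that("contrast matrix enumerates one-on-one array pairs", {
  raw <- make_sim(n_genes = 60, de_fraction = 0.2, seed = 51)
  expr <- qc_normalize(raw, normalize = FALSE)
  ctr <- per_gene_contrast_stats(expr, "feeding")
  expect_equal(ncol(ctr), 36)                      # 6 x 6 pair columns
  expect_equal(nrow(attr(ctr, "pairs")), 36)

  # treat == control: all contrasts zero
  ctr0 <- per_gene_contrast_stats(expr, "feeding", treat = "wild",
                                  control = "wild")
  expect_true(all(ctr0 == 0))

  # planted coordinated up-set at zero noise: identical positive contrasts
  arch <- simulate_architecture(80, de_fraction = 0, seed = 52)
  arch <- plant_pathway_effect(arch, arch$gene_id[1:10], effect = -1)
  raw2 <- simulate_intensities(build_design(6), arch, noise_model(0, 0, 0, seed = 52))
  expr2 <- qc_normalize(raw2, normalize = FALSE)
  ctr2 <- per_gene_contrast_stats(expr2, "feeding", annotation = raw2$probes)
  up <- ctr2[arch$gene_id[1:10], ]
  expect_true(all(up == 1))
  expect_true(all(ctr2[arch$gene_id[11:80], ] == 0))

  expect_error(per_gene_contrast_stats(expr, "feeding", treat = "nonesuch"),
               "design error")
})

test_that("set test calls planted coordinated sets in the right direction", {
  arch <- simulate_architecture(600, de_fraction = 0, seed = 53)
  sets <- simulate_gene_sets(arch$gene_id, 25, c(10, 40), seed = 54)
  planted <- sets[["SET0001"]]
  arch <- plant_pathway_effect(arch, planted, effect = -1)   # up in domesticated
  raw <- simulate_intensities(build_design(6), arch,
                              noise_model(0.25, 0.1, 0, seed = 55))
  expr <- qc_normalize(raw)
  ctr <- per_gene_contrast_stats(expr, "feeding", annotation = raw$probes)
  res <- gage_set_test(ctr, sets)
  up <- res[res$direction == "up", ]
  dn <- res[res$direction == "down", ]
  expect_true(up$significant[up$set_id == "SET0001"])
  expect_false(dn$significant[dn$set_id == "SET0001"])
  expect_true(all(res$bh_q >= res$p_value))

  # sign symmetry: up on negated contrasts equals down on the originals
  neg <- -ctr
  attr(neg, "pairs") <- attr(ctr, "pairs")
  res_neg <- gage_set_test(neg, sets, directions = "up")
  expect_equal(res_neg$p_value, dn$p_value, tolerance = 1e-12)

  # sets below min_size are skipped and recorded
  small <- c(sets, list(TINY = arch$gene_id[1:3]))
  res_s <- gage_set_test(ctr, small, directions = "up", min_size = 10)
  expect_false("TINY" %in% res_s$set_id)
  expect_equal(attr(res_s, "skipped"), "TINY")

  # excluded functional group never reaches testing
  groups <- stats::setNames(rep(c("Metabolism", "Human Diseases"),
                                length.out = length(sets)), names(sets))
  res_x <- gage_set_test(ctr, sets, directions = "up", set_groups = groups,
                         exclude_group = "Human Diseases")
  expect_false(any(res_x$set_id %in% names(groups)[groups == "Human Diseases"]))
})

test_that("set-level p-values are approximately uniform under the null", {
  arch <- simulate_architecture(2000, de_fraction = 0, seed = 57)
  raw <- simulate_intensities(build_design(6), arch,
                              noise_model(0.25, 0.1, 0, seed = 57))
  expr <- qc_normalize(raw)
  ctr <- per_gene_contrast_stats(expr, "feeding", annotation = raw$probes)
  sets <- simulate_gene_sets(arch$gene_id, 200, c(10, 50), seed = 58)
  res <- gage_set_test(ctr, sets, directions = "up")
  expect_gt(stats::ks.test(res$p_value, "punif")$p.value, 0.01)
  expect_false(any(res$significant))
})

test_that("redundancy grouping is a transitive closure with min-p representatives", {
  sets <- list(A = letters[1:10], B = letters[1:10], C = letters[15:20])
  res <- data.frame(set_id = c("A", "B", "C"), direction = "up",
                    p_value = c(0.01, 0.002, 0.03), bh_q = 0.05,
                    set_size = c(10, 10, 6), significant = TRUE)
  nr <- nonredundant_sets(res, sets)
  expect_equal(max(nr$group), 2)                           # A+B merge, C alone
  expect_equal(nr$set_id[nr$representative & nr$group == nr$group[nr$set_id == "A"]], "B")

  # chain A~B, B~C with A and C barely overlapping: one component
  chain <- list(A = sprintf("g%02d", 1:10), B = sprintf("g%02d", 6:15),
                C = sprintf("g%02d", 11:20))
  res_c <- data.frame(set_id = c("A", "B", "C"), direction = "up",
                      p_value = c(0.01, 0.02, 0.03), bh_q = 0.05,
                      set_size = 10, significant = TRUE)
  nr_c <- nonredundant_sets(res_c, chain, overlap_fraction = 0.5)
  expect_equal(max(nr_c$group), 1)
  expect_equal(sum(nr_c$representative), 1)

  # brute-force closure oracle on random families
  set.seed(59)
  pool <- sprintf("g%03d", 1:60)
  fam <- lapply(1:12, function(i) sample(pool, sample(5:20, 1)))
  names(fam) <- LETTERS[1:12]
  res_f <- data.frame(set_id = names(fam), direction = "up",
                      p_value = runif(12), bh_q = 0.05,
                      set_size = lengths(fam), significant = TRUE)
  nr_f <- nonredundant_sets(res_f, fam, overlap_fraction = 0.4)
  link <- outer(names(fam), names(fam), Vectorize(function(i, j) {
    length(intersect(fam[[i]], fam[[j]])) /
      min(length(unique(fam[[i]])), length(unique(fam[[j]]))) >= 0.4
  }))
  reach <- link
  for (k in seq_along(fam)) reach <- reach | (reach %*% (reach * 1) > 0)
  for (i in seq_along(fam)) for (j in seq_along(fam)) {
    same <- nr_f$group[nr_f$set_id == names(fam)[i]] ==
      nr_f$group[nr_f$set_id == names(fam)[j]]
    expect_equal(same, unname(reach[i, j]))
  }

  # no significant results: empty grouping
  res_n <- res; res_n$significant <- FALSE
  expect_equal(nrow(nonredundant_sets(res_n, sets)), 0)
})

test_that("essential genes deviate by more than one SD and belong to a set", {
  vals <- c(seq(-1, 1, length.out = 98), 4, 6)
  names(vals) <- sprintf("g%03d", 1:100)
  ctr <- matrix(vals, 100, 5, dimnames = list(names(vals), paste0("c", 1:5)))
  gm <- mean(vals); s <- sd(vals)
  sig_sets <- list(S1 = names(vals)[c(1:40, 99)])     # includes the +4 gene
  ess <- essential_genes(ctr, sig_sets)
  brute <- names(vals)[abs(vals - gm) > s & names(vals) %in% sig_sets$S1]
  expect_setequal(ess$gene_id, brute)
  expect_true("g099" %in% ess$gene_id)
  expect_false("g100" %in% ess$gene_id)   # extreme but not in a significant set
  g_mid <- names(vals)[which.min(abs(vals - gm))]
  expect_false(g_mid %in% ess$gene_id)    # at the grand mean
  expect_error(essential_genes(ctr, list()), "significant set")
})

test_that("Pearson average-linkage clustering matches a naive oracle", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1))
  cl <- cluster_genes(m)
  expect_equal(cl$hclust$height[1], 0)                      # identical rows first
  d <- 1 - cor(t(m))
  expect_equal(d["a", "c"], 2)                              # anti-correlated

  set.seed(61)
  m10 <- matrix(rnorm(10 * 8), 10, 8, dimnames = list(letters[1:10], NULL))
  cl10 <- cluster_genes(m10)
  # naive O(n^3) average linkage on 1 - Pearson r
  naive_avg <- function(dm) {
    active <- as.list(seq_len(nrow(dm)))
    heights <- numeric(0)
    while (length(active) > 1) {
      best <- c(Inf, NA, NA)
      for (i in seq_along(active)) for (j in seq_len(i - 1)) {
        h <- mean(dm[active[[i]], active[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
      heights <- c(heights, best[1])
      active[[best[2]]] <- c(active[[best[2]]], active[[best[3]]])
      active[[best[3]]] <- NULL
    }
    heights
  }
  dm <- 1 - cor(t(m10))
  expect_equal(cl10$hclust$height, naive_avg(dm), tolerance = 1e-12)

  # zero-variance genes are reported and excluded
  m_z <- rbind(m10, zz = rep(2, 8))
  cl_z <- cluster_genes(m_z)
  expect_equal(cl_z$excluded, "zz")
  expect_setequal(cl_z$order, letters[1:10])
  expect_error(cluster_genes(m10[1, , drop = FALSE]), "insufficient data")
})
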