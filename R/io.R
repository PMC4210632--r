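#' Read a probe x array expression table from TSV
#'
#' Expects a header row (first column = probe id, remaining columns = array
#' ids) and numeric cells. Ragged rows, duplicate probe ids, non-numeric
#' cells and empty files raise parse errors naming the offending line or id.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix with probe ids as row names and array ids as column
#'   names.
#' @export
read_expression_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("parse error: '", path, "' is empty", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != ncols[1])) {
    stop("parse error: ragged row at line ", which(ncols != ncols[1])[1] ,
         " of '", path, "'", call. = FALSE)
  }
  header <- fields[[1]]
  body <- fields[-1]
  if (!length(body)) stop("parse error: '", path, "' has no data rows", call. = FALSE)
  ids <- vapply(body, `[`, "", 1)
  if (anyDuplicated(ids)) {
    stop("parse error: duplicate probe id '", ids[duplicated(ids)][1], "' in '",
         path, "'", call. = FALSE)
  }
  num <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(length(header) - 1))
  )
  if (length(header) == 2) num <- matrix(num, nrow = 1)
  bad <- which(colSums(is.na(num)) > 0)   # columns of vapply result = rows of file
  if (length(bad)) {
    stop("parse error: non-numeric cell at line ", bad[1] + 1, " of '", path,
         "'", call. = FALSE)
  }
  mat <- t(num)
  dimnames(mat) <- list(ids, header[-1])
  mat
}

#' Write a numeric matrix (or data frame) as TSV
#'
#' Matrices are written with an `id` first column holding the row names so
#' that [read_expression_table()] round-trips them.
#'
#' @param obj Matrix or data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(obj, path) {
  if (is.matrix(obj)) {
    obj <- data.frame(id = rownames(obj), obj, check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB gene
#' ids...`. Blank lines are skipped with a warning; duplicate genes within a
#' set are deduplicated with a warning; lines with fewer than 3 fields are a
#' parse error.
#'
#' @param path Path to a GMT file.
#' @return Named list of gene-id character vectors, with the descriptions in
#'   attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    warning("skipping ", sum(blank), " blank line(s) in '", path, "'")
    lines <- lines[!blank]
  }
  if (!length(lines)) stop("parse error: '", path, "' has no gene sets", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    stop("parse error: GMT line ", which(short)[1], " has fewer than 3 fields",
         call. = FALSE)
  }
  sets <- lapply(seq_along(fields), function(i) {
    genes <- fields[[i]][-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene id(s) in set '", fields[[i]][1],
              "'; keeping one copy each")
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- vapply(fields, `[`, "", 1)
  attr(sets, "description") <- stats::setNames(vapply(fields, `[`, "", 2),
                                               names(sets))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of gene-id vectors; descriptions taken from the
#'   `description` attribute (or `"na"`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All stage parameters with their standard values: probe retention 75% of a
#' group in >= 2 groups, strict DE at p <= 0.01 with fold change >= 1.3,
#' lenient DE at p <= 0.05, set test at q <= 0.1 with minimum set size 10,
#' ANOVA selection at 10% BH FDR.
#'
#' @param ... Named overrides of any default.
#' @return A validated list of class `sc_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    replicates = 6L, n_genes = 2000L, n_sets = 50L, seed = 1L,
    de_fraction = 0.15, effect = 1.0,
    biological_sd = 0.25, technical_sd = 0.1, flag_failure_rate = 0.05,
    retain_fraction = 0.75, min_groups = 2L, lowess_span = 0.3,
    p_strict = 0.01, fc_strict = 1.3, p_lenient = 0.05,
    anova_fdr = 0.10, gage_q = 0.1, min_set_size = 10L,
    outlier_sd = 3, plot_limit = 5, exclude_group = "Human Diseases"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("validation error: unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  validate_config(cfg)
  class(cfg) <- "sc_config"
  cfg
}

validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("validation error: ", msg, call. = FALSE)
  chk(cfg$replicates >= 2, "'replicates' must be >= 2")
  chk(cfg$n_genes >= 1, "'n_genes' must be >= 1")
  chk(cfg$fc_strict >= 1, "'fc_strict' must be >= 1 (linear fold change)")
  for (p in c("p_strict", "p_lenient", "anova_fdr", "gage_q")) {
    chk(cfg[[p]] > 0 && cfg[[p]] <= 1, paste0("'", p, "' must be in (0, 1]"))
  }
  chk(cfg$retain_fraction > 0 && cfg$retain_fraction <= 1,
      "'retain_fraction' must be in (0, 1]")
  chk(cfg$min_groups >= 1, "'min_groups' must be >= 1")
  chk(cfg$biological_sd >= 0 && cfg$technical_sd >= 0, "noise SDs must be >= 0")
  chk(cfg$flag_failure_rate >= 0 && cfg$flag_failure_rate <= 1,
      "'flag_failure_rate' must be in [0, 1]")
  chk(cfg$min_set_size >= 1, "'min_set_size' must be >= 1")
  invisible(cfg)
}

#' Run the whole pipeline on simulated or supplied data
#'
#' Executes simulate (unless `raw` is given) -> QC/normalisation ->
#' differential expression (pairwise Welch t, Venn partitions) -> directional
#' set test + essential genes -> Welch ANOVA selection -> inheritance-mode
#' classification, writing every stage table plus a `manifest.txt` listing
#' all parameters. Identical config and seed give identical outputs.
#'
#' @param config An `sc_config` from [default_config()].
#' @param out_dir Output directory (created if needed).
#' @param raw Optional `RawIntensityData` (skips simulation).
#' @param sets Optional named list of gene sets (simulated when `NULL` and
#'   `raw` is also `NULL`).
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir, raw = NULL,
                         sets = NULL) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[salmocross] ", ...)

  if (is.null(raw)) {
    design <- build_design(config$replicates)
    arch <- simulate_architecture(config$n_genes,
                                  de_fraction = config$de_fraction,
                                  effect = config$effect,
                                  seed = config$seed)
    if (is.null(sets)) {
      sets <- simulate_gene_sets(arch$gene_id, n_sets = config$n_sets)
    }
    noise <- noise_model(biological_sd = config$biological_sd,
                         technical_sd = config$technical_sd,
                         flag_failure_rate = config$flag_failure_rate,
                         seed = config$seed)
    raw <- simulate_intensities(design, arch, noise)
    log_stage("simulate: ", nrow(raw$sample), " probes x ", ncol(raw$sample),
              " arrays")
  }
  annotation <- raw$probes

  expr <- qc_normalize(raw, fraction = config$retain_fraction,
                       min_groups = config$min_groups,
                       span = config$lowess_span)
  log_stage("qc: retained ", nrow(expr$values), " of ", expr$n_input_probes,
            " probes")
  outliers <- detect_outlier_arrays(expr, threshold_sd = config$outlier_sd)
  if (length(outliers)) log_stage("qc: PCA-flagged arrays: ",
                                  paste(outliers, collapse = ", "))
  write_table(expr$values, file.path(out_dir, "expression.tsv"))
  qc_report <- data.frame(
    probe_id = rownames(raw$flags),
    retained = rownames(raw$flags) %in% expr$retained_probes,
    stringsAsFactors = FALSE)
  write_table(qc_report, file.path(out_dir, "qc_report.tsv"))

  results <- list(expr = expr, outlier_arrays = outliers)
  strict_by_stage <- list()
  for (stage in sc_stages) {
    de <- pairwise_de(expr, stage, p_strict = config$p_strict,
                      fc_strict = config$fc_strict,
                      p_lenient = config$p_lenient)
    for (nm in names(de)) {
      write_table(de[[nm]], file.path(out_dir, paste0("de_", stage, "_", nm, ".tsv")))
    }
    strict <- lapply(de, function(d) d$probe_id[d$passes_strict])
    log_stage("de ", stage, ": strict counts ",
              paste(names(strict), lengths(strict), sep = "=", collapse = ", "))
    venn <- venn_partition(strict[[1]], strict[[2]], strict[[3]])
    write_table(data.frame(region = names(venn$sizes), size = venn$sizes),
                file.path(out_dir, paste0("venn_", stage, ".tsv")))
    strict_by_stage[[stage]] <- strict

    contrasts <- per_gene_contrast_stats(expr, stage, annotation = annotation)
    enr <- gage_set_test(contrasts, sets, min_size = config$min_set_size,
                         q_cut = config$gage_q)
    write_table(enr, file.path(out_dir, paste0("set_results_", stage, ".tsv")))
    log_stage("enrich ", stage, ": ", sum(enr$significant), " significant ",
              "set-direction calls of ", nrow(enr))
    sig_ids <- unique(enr$set_id[enr$significant])
    if (length(sig_ids)) {
      nr <- nonredundant_sets(enr, sets)
      write_table(nr, file.path(out_dir, paste0("nonredundant_sets_", stage, ".tsv")))
      ess <- essential_genes(contrasts, sets[sig_ids])
      write_table(ess, file.path(out_dir, paste0("essential_genes_", stage, ".tsv")))
      if (nrow(ess) >= 2) {
        cl <- cluster_genes(contrasts[ess$gene_id, , drop = FALSE])
        writeLines(cl$order, file.path(out_dir, paste0("cluster_order_", stage, ".txt")))
      }
    }

    anova <- welch_anova(expr, stage)
    fdr <- bh_fdr(anova$p_value, q_cut = config$anova_fdr)
    anova$bh_q <- fdr$q
    anova$pass <- fdr$pass
    write_table(anova, file.path(out_dir, paste0("anova_", stage, ".tsv")))
    uni <- dedupe_unique_genes(anova[anova$pass, , drop = FALSE], annotation)
    log_stage("anova ", stage, ": ", sum(fdr$pass), " probes at ",
              100 * config$anova_fdr, "% FDR, ", nrow(uni), " unique genes")
    if (nrow(uni)) {
      rec <- classify_mode(compute_alpha_delta(cross_means(expr, stage, uni$probe_id)))
      rec$gene_id <- uni$gene_id[match(rec$probe_id, uni$probe_id)]
      fig4 <- export_fig4_table(expr, stage, uni$probe_id,
                                plot_limit = config$plot_limit)
      rec$sd_alpha <- fig4$sd_alpha
      rec$sd_ratio <- fig4$sd_ratio
      rec$excluded_from_plot <- fig4$excluded_from_plot
      write_table(rec, file.path(out_dir, paste0("inheritance_", stage, ".tsv")))
      props <- summarize_proportions(rec)
      write_table(props, file.path(out_dir, paste0("proportions_", stage, ".tsv")))
      results[[paste0("inheritance_", stage)]] <- rec
      results[[paste0("proportions_", stage)]] <- props
    }
    results[[paste0("de_", stage)]] <- de
    results[[paste0("sets_", stage)]] <- enr
  }
  combined <- union_across_stages(strict_by_stage$sac, strict_by_stage$feeding)
  venn_c <- venn_partition(combined[[1]], combined[[2]], combined[[3]])
  write_table(data.frame(region = names(venn_c$sizes), size = venn_c$sizes),
              file.path(out_dir, "venn_combined.tsv"))
  results$venn_combined <- venn_c

  manifest <- c(
    paste0("salmocross_version=", as.character(utils::packageVersion("salmocross"))),
    paste0(names(config), "=", vapply(unclass(config), paste, "", collapse = ","))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(results)
}
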