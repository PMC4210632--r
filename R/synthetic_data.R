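# Fixed vocabularies for the experimental design: three crosses (the hybrid
# is domesticated dam x wild sire) and two fry life stages.
sc_crosses <- c("wild", "hybrid", "domesticated")
sc_stages  <- c("sac", "feeding")
sc_modes   <- c("additive", "maternal_dominant", "paternal_dominant", "overdominant")

#' Build the cross-by-stage hybridisation design
#'
#' Lays out the common-reference two-colour design: 3 crosses (wild, hybrid,
#' domesticated) x 2 life stages (sac fry, feeding fry) x `replicates`
#' biological replicates, one array per replicate.
#'
#' @param replicates Biological replicates per group (integer >= 2; default 6,
#'   giving the full 36-array layout).
#' @param seed Optional integer; the layout is deterministic, the seed is
#'   accepted for interface symmetry with the simulator.
#' @return A data frame of class `sc_design` with columns `array_id`, `cross`,
#'   `stage` and `replicate`; one row per hybridisation.
#' @examples
#' d <- build_design(6)
#' nrow(d)            # 36 arrays
#' table(d$cross, d$stage)
#' @export
build_design <- function(replicates = 6, seed = NULL) {
  if (!is.numeric(replicates) || length(replicates) != 1 || is.na(replicates) ||
      replicates < 2 || replicates != round(replicates)) {
    stop("invalid design: 'replicates' must be a single integer >= 2", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  grid <- expand.grid(replicate = seq_len(replicates),
                      cross = sc_crosses, stage = sc_stages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- data.frame(
    array_id  = sprintf("A%02d", seq_len(nrow(grid))),
    cross     = grid$cross,
    stage     = grid$stage,
    replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
  class(design) <- c("sc_design", "data.frame")
  design
}

#' Generate a transcript architecture with planted ground truth
#'
#' Draws per-gene baselines and plants differential expression between the
#' wild and domesticated crosses together with an inheritance mode for the
#' hybrid. Genes with `effect = 0` are planted nulls. The default mode mix
#' among differentially expressed genes follows the feeding-fry proportions
#' observed in this system (45 / 42.2 / 6.1 / 6.7 percent additive /
#' maternal-dominant / paternal-dominant / overdominant).
#'
#' @param n_genes Number of genes.
#' @param de_fraction Fraction of genes planted as differentially expressed
#'   between wild and domesticated (the rest are nulls).
#' @param mode_mix Named nonnegative weights over the four inheritance modes
#'   for the differentially expressed genes; normalised internally.
#' @param effect Absolute log2 wild-vs-domesticated offset for DE genes
#'   (W - D = +/- effect; sign drawn at random per gene).
#' @param baseline_mean,baseline_sd Mean and SD of per-gene baseline log2
#'   expression.
#' @param overdominance_shift Log2 distance by which an overdominant hybrid
#'   lies outside the parental range; must exceed `effect / 4` so that
#'   |delta/alpha| > 1.5.
#' @param overdominant_maternal_fraction Probability that an overdominant
#'   hybrid overshoots past the maternal (domesticated) parent rather than the
#'   paternal (wild) one; 0.75 reproduces the ~3:1 maternal skew seen in this
#'   system, 0.5 (default) is symmetric.
#' @param duplicate_probe_fraction Fraction of genes carried by two probes
#'   instead of one (both probes share the gene's true means).
#' @param annotated_fraction Fraction of genes with BLASTx/KEGG-style
#'   annotation (only annotated genes survive unique-gene deduplication).
#' @param stage_specific_fraction Fraction of DE genes whose effect is present
#'   only in the feeding stage (they behave as nulls in sac fry).
#' @param seed Optional integer seed.
#' @return A data frame of class `sc_architecture`, one row per gene, with
#'   columns `gene_id`, `n_probes`, `baseline`, `effect`, `mode`, `od_side`,
#'   `overdominance_shift`, `stage_specific`, `annotated`.
#' @export
simulate_architecture <- function(n_genes = 2000,
                                  de_fraction = 0.15,
                                  mode_mix = c(additive = 0.45,
                                               maternal_dominant = 0.422,
                                               paternal_dominant = 0.061,
                                               overdominant = 0.067),
                                  effect = 1.0,
                                  baseline_mean = 10,
                                  baseline_sd = 1.5,
                                  overdominance_shift = 0.5,
                                  overdominant_maternal_fraction = 0.5,
                                  duplicate_probe_fraction = 0,
                                  annotated_fraction = 1,
                                  stage_specific_fraction = 0,
                                  seed = NULL) {
  stopifnot(n_genes >= 1, de_fraction >= 0, de_fraction <= 1, effect >= 0,
            baseline_sd >= 0, overdominance_shift >= 0)
  if (is.null(names(mode_mix)) || !all(names(mode_mix) %in% sc_modes)) {
    stop("'mode_mix' must be named with the four inheritance modes", call. = FALSE)
  }
  mix <- mode_mix[sc_modes]
  mix[is.na(mix)] <- 0
  names(mix) <- sc_modes
  if (sum(mix) <= 0) stop("'mode_mix' weights must sum to a positive value", call. = FALSE)
  mix <- mix / sum(mix)
  if (!is.null(seed)) set.seed(seed)

  n_de <- round(n_genes * de_fraction)
  de <- rep(FALSE, n_genes)
  if (n_de > 0) de[sample.int(n_genes, n_de)] <- TRUE

  mode <- rep("additive", n_genes)
  if (n_de > 0) {
    mode[de] <- sample(sc_modes, n_de, replace = TRUE, prob = mix)
  }
  eff <- ifelse(de, effect * sample(c(-1, 1), n_genes, replace = TRUE), 0)
  od_side <- rep(NA_character_, n_genes)
  is_od <- mode == "overdominant" & de
  od_side[is_od] <- ifelse(stats::runif(sum(is_od)) < overdominant_maternal_fraction,
                           "maternal", "paternal")

  arch <- data.frame(
    gene_id  = sprintf("G%05d", seq_len(n_genes)),
    n_probes = 1L + (stats::runif(n_genes) < duplicate_probe_fraction),
    baseline = stats::rnorm(n_genes, baseline_mean, baseline_sd),
    effect   = eff,
    mode     = mode,
    od_side  = od_side,
    overdominance_shift = overdominance_shift,
    stage_specific = de & (stats::runif(n_genes) < stage_specific_fraction),
    annotated = stats::runif(n_genes) < annotated_fraction,
    stringsAsFactors = FALSE
  )
  class(arch) <- c("sc_architecture", "data.frame")
  arch
}

#' Probe-to-gene annotation table for an architecture
#'
#' @param arch An `sc_architecture` data frame.
#' @return Data frame with `probe_id`, `gene_id`, `annotated`.
#' @export
probe_annotation <- function(arch) {
  idx <- rep(seq_len(nrow(arch)), arch$n_probes)
  within_gene <- sequence(arch$n_probes)
  data.frame(
    probe_id  = paste0(arch$gene_id[idx], "_", within_gene),
    gene_id   = arch$gene_id[idx],
    annotated = arch$annotated[idx],
    stringsAsFactors = FALSE
  )
}

#' True per-group log2 means implied by an architecture
#'
#' Inverts the inheritance statistics: with wild mean W and domesticated mean
#' D (W - D = planted effect), the hybrid mean H is the parental midpoint for
#' additive genes, equals D (the dam) under maternal dominance, equals W (the
#' sire) under paternal dominance, and lies `overdominance_shift` log2 units
#' outside the parental range for overdominant genes, far enough that
#' |delta/alpha| > 1.5.
#'
#' @param arch An `sc_architecture` data frame.
#' @return Data frame with one row per gene and stage: `gene_id`, `stage`,
#'   `W`, `H`, `D`, `mode` (effective mode at that stage; stage-specific genes
#'   are additive nulls in sac fry).
#' @export
plant_group_means <- function(arch) {
  stopifnot(inherits(arch, "data.frame"), nrow(arch) >= 1)
  bad <- arch$mode == "overdominant" & arch$effect == 0 & arch$overdominance_shift == 0
  if (any(bad)) {
    stop("inconsistent architecture: overdominant gene(s) with effect = 0 and ",
         "overdominance_shift = 0 (first: ", arch$gene_id[which(bad)[1]], ")",
         call. = FALSE)
  }
  weak <- arch$mode == "overdominant" & arch$effect != 0 &
    arch$overdominance_shift <= abs(arch$effect) / 4
  if (any(weak)) {
    stop("inconsistent architecture: overdominance_shift must exceed |effect|/4 ",
         "so that |delta/alpha| > 1.5 (first: ", arch$gene_id[which(weak)[1]], ")",
         call. = FALSE)
  }

  one_stage <- function(stage) {
    eff <- arch$effect
    mode <- arch$mode
    if (stage == "sac") {
      # stage-specific genes have their effect only in the feeding stage
      off <- arch$stage_specific
      eff[off] <- 0
      mode[off] <- "additive"
    }
    W <- arch$baseline + eff / 2
    D <- arch$baseline - eff / 2
    H <- (W + D) / 2
    H[mode == "maternal_dominant"] <- D[mode == "maternal_dominant"]
    H[mode == "paternal_dominant"] <- W[mode == "paternal_dominant"]
    od <- which(mode == "overdominant")
    if (length(od)) {
      s <- arch$overdominance_shift[od]
      side <- arch$od_side[od]
      side[is.na(side)] <- "maternal"
      towards_D <- sign(D[od] - W[od])
      towards_D[towards_D == 0] <- -1       # parents equal: overshoot downwards past the dam
      towards_W <- -towards_D
      H[od] <- ifelse(side == "maternal",
                      D[od] + towards_D * s,
                      W[od] + towards_W * s)
    }
    data.frame(gene_id = arch$gene_id, stage = stage, W = W, H = H, D = D,
               mode = ifelse(eff == 0 & mode != "overdominant", "additive", mode),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_stage("sac"), one_stage("feeding"))
  rownames(out) <- NULL
  out
}

#' Noise model for the two-channel simulator
#'
#' @param biological_sd SD of the per-replicate biological deviate (log2
#'   units, shared by all probes of a gene on one array).
#' @param technical_sd SD of the per-probe, per-channel technical deviate
#'   (log2 units).
#' @param flag_failure_rate Probability that a probe is not "positive and
#'   significant" on an array (i.i.d. Bernoulli).
#' @param dye_bias Optional smooth function of mean log2 intensity A, added to
#'   the sample-channel log2 signal (hence to the log-ratio M); this is what
#'   lowess normalisation is expected to remove. `NULL` means no bias.
#' @param seed Integer seed; identical seed gives bit-identical simulations.
#' @return A list of class `sc_noise`.
#' @export
noise_model <- function(biological_sd = 0.25, technical_sd = 0.1,
                        flag_failure_rate = 0.05, dye_bias = NULL, seed = 1) {
  if (biological_sd < 0 || technical_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  if (flag_failure_rate < 0 || flag_failure_rate > 1) {
    stop("'flag_failure_rate' must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(dye_bias) && !is.function(dye_bias)) {
    stop("'dye_bias' must be NULL or a function of A", call. = FALSE)
  }
  structure(list(biological_sd = biological_sd, technical_sd = technical_sd,
                 flag_failure_rate = flag_failure_rate, dye_bias = dye_bias,
                 seed = seed),
            class = "sc_noise")
}

#' Simulate two-channel probe intensities with known ground truth
#'
#' Each array carries one biological replicate of its group, competitively
#' hybridised against a common reference pool (the equal-weight mean of all
#' six group true means per gene). On the log2 scale the sample channel is
#' `true group mean + biological deviate + technical deviate + dye_bias(A)`
#' and the reference channel is `pool mean + technical deviate`; both are
#' exponentiated (and floored at 0) to give linear intensities. Detection
#' flags fail independently with `flag_failure_rate`.
#'
#' @param design An `sc_design` from [build_design()].
#' @param arch An `sc_architecture` from [simulate_architecture()].
#' @param noise An `sc_noise` from [noise_model()].
#' @return A list of class `RawIntensityData` with matrices `sample`,
#'   `reference`, `flags` (probe x array), plus `design`, `probes`
#'   (probe annotation), `architecture` and `group_means` (the truth).
#' @export
simulate_intensities <- function(design, arch, noise = noise_model()) {
  stopifnot(inherits(design, "sc_design"), inherits(noise, "sc_noise"))
  if (!inherits(arch, "data.frame") || nrow(arch) == 0) {
    stop("empty input: 'arch' must contain at least one transcript architecture",
         call. = FALSE)
  }
  set.seed(noise$seed)
  truth <- plant_group_means(arch)
  key <- paste(truth$stage, truth$gene_id)
  probes <- probe_annotation(arch)
  n_p <- nrow(probes)
  n_a <- nrow(design)

  # gene x group matrix of true means, groups in design order
  groups <- unique(paste(design$cross, design$stage))
  M_true <- matrix(NA_real_, nrow(arch), length(groups),
                   dimnames = list(arch$gene_id, groups))
  for (g in groups) {
    parts <- strsplit(g, " ")[[1]]
    rowv <- truth[match(paste(parts[2], arch$gene_id), key), ]
    M_true[, g] <- switch(parts[1], wild = rowv$W, hybrid = rowv$H,
                          domesticated = rowv$D)
  }
  pool <- rowMeans(M_true)

  gidx <- match(probes$gene_id, arch$gene_id)
  garr <- paste(design$cross, design$stage)

  bio <- matrix(stats::rnorm(nrow(arch) * n_a, 0, noise$biological_sd),
                nrow(arch), n_a)
  true_pa <- M_true[gidx, match(garr, groups), drop = FALSE]
  log2_sample <- true_pa + bio[gidx, , drop = FALSE] +
    matrix(stats::rnorm(n_p * n_a, 0, noise$technical_sd), n_p, n_a)
  log2_ref <- matrix(pool[gidx], n_p, n_a) +
    matrix(stats::rnorm(n_p * n_a, 0, noise$technical_sd), n_p, n_a)
  if (!is.null(noise$dye_bias)) {
    A0 <- (true_pa + matrix(pool[gidx], n_p, n_a)) / 2
    log2_sample <- log2_sample + noise$dye_bias(A0)
  }

  sample_ch <- pmax(2^log2_sample, 0)
  reference_ch <- pmax(2^log2_ref, 0)
  flags <- matrix(stats::runif(n_p * n_a) >= noise$flag_failure_rate, n_p, n_a)
  dimnames(sample_ch) <- dimnames(reference_ch) <- dimnames(flags) <-
    list(probes$probe_id, design$array_id)

  structure(list(sample = sample_ch, reference = reference_ch, flags = flags,
                 design = design, probes = probes, architecture = arch,
                 group_means = truth, noise = noise),
            class = "RawIntensityData")
}

#' Random gene sets plus optional planted coordinated perturbation
#'
#' @param gene_ids Pool of gene identifiers.
#' @param n_sets Number of sets.
#' @param set_size Integer size of each set, or a length-2 range sampled
#'   uniformly.
#' @param seed Optional seed.
#' @return Named list of gene-id character vectors.
#' @export
simulate_gene_sets <- function(gene_ids, n_sets = 200, set_size = c(10, 50),
                               seed = NULL) {
  stopifnot(length(gene_ids) >= max(set_size), n_sets >= 1)
  if (!is.null(seed)) set.seed(seed)
  sizes <- if (length(set_size) == 1) rep(set_size, n_sets) else
    sample(seq(set_size[1], set_size[2]), n_sets, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(gene_ids, s))
  names(sets) <- sprintf("SET%04d", seq_len(n_sets))
  sets
}

#' Plant a coordinated expression shift into a set of genes
#'
#' Overwrites the architecture of the given genes with a common signed effect
#' and additive inheritance, producing the coordinated perturbation a
#' directional gene-set test should detect.
#'
#' @param arch An `sc_architecture`.
#' @param gene_ids Genes to perturb.
#' @param effect Signed log2 wild-vs-domesticated offset (negative values mean
#'   higher expression in the domesticated cross).
#' @return The modified architecture.
#' @export
plant_pathway_effect <- function(arch, gene_ids, effect) {
  i <- match(gene_ids, arch$gene_id)
  if (anyNA(i)) stop("unknown gene id(s) in 'gene_ids'", call. = FALSE)
  arch$effect[i] <- effect
  arch$mode[i] <- "additive"
  arch$od_side[i] <- NA_character_
  arch$stage_specific[i] <- FALSE
  arch
}

#' Write a simulation to TSV/GMT files
#'
#' Emits `intensities.tsv` (long table: probe_id, array_id, sample, reference,
#' flag), `samples.tsv` (array_id, cross, stage), `truth.tsv` (per gene and
#' stage: mode and true W/H/D means) and, if `sets` is given, `pathways.gmt`.
#'
#' @param raw A `RawIntensityData`.
#' @param dir Output directory (created if missing).
#' @param sets Optional named list of gene sets.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(raw, dir, sets = NULL) {
  stopifnot(inherits(raw, "RawIntensityData"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- data.frame(
    probe_id = rep(rownames(raw$sample), ncol(raw$sample)),
    array_id = rep(colnames(raw$sample), each = nrow(raw$sample)),
    sample = as.vector(raw$sample),
    reference = as.vector(raw$reference),
    flag = as.vector(raw$flags),
    stringsAsFactors = FALSE
  )
  paths <- c(intensities = file.path(dir, "intensities.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"))
  utils::write.table(long, paths["intensities"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(raw$design, paths["samples"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- merge(raw$group_means,
                 raw$architecture[, c("gene_id", "annotated")], by = "gene_id")
  utils::write.table(truth[order(truth$stage, truth$gene_id), ],
                     paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sets)) {
    paths <- c(paths, pathways = file.path(dir, "pathways.gmt"))
    write_gmt(sets, paths["pathways"])
  }
  invisible(paths)
}
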