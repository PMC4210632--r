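# Shared fixtures: small seeded simulations built in code.

# A complete small simulation; zero-noise by default so planted values are
# exact. Returns raw data plus the feeding-stage truth lookup.
make_sim <- function(n_genes = 200, de_fraction = 0.3, effect = 1,
                     biological_sd = 0, technical_sd = 0,
                     flag_failure_rate = 0, dye_bias = NULL,
                     replicates = 6, seed = 42, ...) {
  design <- build_design(replicates)
  arch <- simulate_architecture(n_genes, de_fraction = de_fraction,
                                effect = effect, seed = seed, ...)
  noise <- noise_model(biological_sd, technical_sd, flag_failure_rate,
                       dye_bias = dye_bias, seed = seed)
  raw <- simulate_intensities(design, arch, noise)
  raw
}

# Truth for one stage, keyed by probe id.
truth_by_probe <- function(raw, stage) {
  tr <- raw$group_means[raw$group_means$stage == stage, ]
  tr[match(raw$probes$gene_id, tr$gene_id), c("gene_id", "W", "H", "D", "mode")]
}

# Hand-built minimal architecture rows (one gene per mode), W = 10, D = 6.
manual_arch <- function(modes = c("additive", "maternal_dominant",
                                  "paternal_dominant", "overdominant"),
                        baseline = 8, effect = 4, shift = 2,
                        od_side = "paternal") {
  arch <- data.frame(
    gene_id = sprintf("G%05d", seq_along(modes)),
    n_probes = 1L,
    baseline = baseline,
    effect = effect,
    mode = modes,
    od_side = ifelse(modes == "overdominant", od_side, NA_character_),
    overdominance_shift = shift,
    stage_specific = FALSE,
    annotated = TRUE,
    stringsAsFactors = FALSE
  )
  class(arch) <- c("sc_architecture", "data.frame")
  arch
}
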