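# Shared settings for the analysis scripts.  Each numbered script sources
# this file, so the whole workflow is driven by one seed and one parameter
# set.  Generator objects (genome, truth profiles) are re-derived from the
# seed where needed; sequencing-scale intermediates (FASTQ, methylome
# tables) are read from results/study/.

library(rrbsdmr)

SEED <- 20200416L
OUT <- "results/study"
ARMS <- c("medium", "pVC", "TGFb", "TGFb_pVC")

CFG <- default_run_config(SEED)
CFG$genome$chrom_length <- 60000
CFG$genome$n_genes <- 20
CFG$genome$n_truth_dmrs <- 4
CFG$reads$mean_depth <- 15

study_genome <- function() {
  g <- CFG$genome
  generate_genome(g$n_chrom, g$chrom_length, g$gc_fraction, g$ccgg_boost,
                  g$n_genes, g$n_truth_dmrs, seed = SEED)
}

study_dmr_spec <- function(genome) {
  pr <- CFG$profile
  c(list(tsdr = unlist(pr$tsdr_levels)),
    stats::setNames(
      rep(list(unlist(pr$truth_dmr_levels)),
          sum(genome$features$kind == "truth_dmr")),
      genome$features$id[genome$features$kind == "truth_dmr"]))
}

study_profile <- function(genome, arm) {
  pr <- CFG$profile
  assign_profile(genome, arm, pr$base_cg_level, pr$base_noncg_level,
                 study_dmr_spec(genome), pr$jitter_sd,
                 seed = SEED + 10L + match(arm, ARMS))
}

dir.create(OUT, recursive = TRUE, showWarnings = FALSE)
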