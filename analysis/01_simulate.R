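#!/usr/bin/env Rscript
# Stage 1 -- simulate the study inputs.
#
# Builds the synthetic reference genome (CCGG-dense, with genes, promoters,
# CpG islands, four ground-truth DMR cassettes and one TSDR-like locus),
# assigns a ground-truth methylation profile to each of the four culture
# arms (medium, pVC, TGF-beta, TGF-beta + pVC; the TSDR is demethylated
# only in the TGF-beta + pVC arm, the truth cassettes in both pVC arms),
# digests with MspI, size-selects 40-220 bp fragments and writes
# directional bisulfite FASTQ for every arm.

source("analysis/00_config.R")

genome <- study_genome()
cat("genome:", sum(nchar(genome$chromosomes)), "bp;",
    nrow(genome$features), "features\n")
write_genome_fasta(genome, file.path(OUT, "genome.fa"))
export_features_bed(genome, file.path(OUT, "features.bed"))
export_genes_gtf(genome, file.path(OUT, "genes.gtf"))

fragments <- size_select(digest_mspi(genome),
                         CFG$size_select$min_bp, CFG$size_select$max_bp)
cat(sprintf("MspI fragments retained after size selection: %d (%.0f%% of bp)\n",
            nrow(fragments),
            100 * sum(fragments$length) / sum(nchar(genome$chromosomes))))

for (arm in ARMS) {
  prof <- study_profile(genome, arm)
  rd <- CFG$reads
  reads <- simulate_reads(genome, fragments, prof, rd$read_length,
                          rd$mean_depth, rd$conversion_rate, rd$error_rate,
                          seed = SEED + 20L + match(arm, ARMS))
  write_fastq(reads, file.path(OUT, sprintf("reads_%s.fastq", arm)))
  cat(sprintf("  %-9s %6d reads\n", arm, nrow(reads)))
}

truth <- list(seed = SEED,
              truth_regions = genome$features[
                genome$features$kind %in% c("truth_dmr", "tsdr"), ],
              arm_levels = study_dmr_spec(genome))
jsonlite::write_json(truth, file.path(OUT, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("ground truth written to", file.path(OUT, "truth.json"), "\n")
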