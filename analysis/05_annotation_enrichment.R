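#!/usr/bin/env Rscript
# Stage 5 -- associate DMRs with genes and test gene-set enrichment.
#
# Assigns each DMR to gene bodies (>= 1 bp overlap) and promoters
# (TSS -2000/+500, strand-aware), then runs a local hypergeometric
# over-representation test of the DMR-associated genes against synthetic
# gene sets (one set enriched in DMR genes among random ones), with the
# full gene annotation as background and raw p <= 0.05 as the
# significance call.

source("analysis/00_config.R")

genome <- study_genome()
genes <- genome_features(genome, "gene")$id
an <- CFG$annotation

assignments <- dplyr::bind_rows(lapply(
  c("medium_vs_pVC", "TGFb_vs_TGFb_pVC"), function(nm) {
    dm <- readr::read_tsv(file.path(OUT, sprintf("dmrs_%s.tsv", nm)),
                          show_col_types = FALSE)
    a <- assign_regions(dm, genome, an$promoter_up, an$promoter_down)
    if (nrow(a)) a$comparison <- nm
    a
  }))
readr::write_tsv(assignments, file.path(OUT, "gene_assignments.tsv"))
cat("DMR-gene assignments:", nrow(assignments), "\n")
print(as.data.frame(assignments))

sets <- withr::with_seed(SEED + 40L, {
  s <- lapply(seq_len(an$n_random_sets), function(i) {
    sample(genes, min(an$random_set_size, length(genes)))
  })
  names(s) <- sprintf("random_set_%d", seq_along(s))
  s$dmr_associated <- unique(assignments$gene_id)
  s
})
write_gmt(sets, file.path(OUT, "gene_sets.gmt"))

er <- enrich(unique(assignments$gene_id), read_gmt(file.path(OUT,
                                                             "gene_sets.gmt")),
             genes)
readr::write_tsv(er, file.path(OUT, "enrichment.tsv"))
cat("enrichment (p <= 0.05 flagged significant):\n")
print(as.data.frame(er))
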