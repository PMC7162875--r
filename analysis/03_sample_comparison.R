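#!/usr/bin/env Rscript
# Stage 3 -- compare the four methylomes at the sample level.
#
# Builds the matrix of CpG sites covered >= 5-fold in all four arms,
# computes the Pearson correlation between arms and a PCA of the samples
# (site-wise centering, no scaling), and summarises mean methylation by
# sequence context (mCG/mCHG/mCHH) within promoters, CpG islands, gene
# bodies and genome-wide.

source("analysis/00_config.R")

genome <- study_genome()
tables <- lapply(ARMS, function(arm) {
  import_cx(file.path(OUT, sprintf("methylome_%s.tsv", arm)), sample = arm)
})
names(tables) <- ARMS

m <- build_matrix(tables, context = "CpG", min_cov = CFG$dmr$min_cov)
cat("shared mCG sites across all four arms:", nrow(m), "\n")
readr::write_tsv(tibble::as_tibble(cbind(site = rownames(m),
                                         as.data.frame(m))),
                 file.path(OUT, "site_matrix.tsv"))

pm <- pearson_matrix(m)
cat("Pearson correlation between arms:\n")
print(round(pm, 3))
utils::write.csv(pm, file.path(OUT, "pearson.csv"))

pca <- pca_samples(m)
cat("variance explained:",
    paste(sprintf("%.1f%%", 100 * pca$var_explained[1:3]), collapse = ", "),
    "\n")
cat("sample coordinates (PC1/PC2):\n")
print(round(pca$coordinates[, 1:2], 2))
utils::write.csv(as.data.frame(pca$coordinates), file.path(OUT, "pca.csv"))
utils::write.csv(data.frame(component = paste0("PC",
                                               seq_along(pca$var_explained)),
                            var_explained = pca$var_explained),
                 file.path(OUT, "pca_varexp.csv"), row.names = FALSE)

ctx <- dplyr::bind_rows(lapply(ARMS, function(arm) {
  s <- context_feature_summary(tables[[arm]], genome)
  s$sample <- arm
  s
}))
readr::write_tsv(ctx, file.path(OUT, "context_summary.tsv"))
cat("context-by-feature summary written; genome-wide mCG per arm:\n")
print(as.data.frame(ctx[ctx$feature_class == "genome_wide" &
                          ctx$context == "CpG", c("sample", "level")]))
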