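#!/usr/bin/env Rscript
# Stage 6 -- targeted TSDR amplicon analysis.
#
# Simulates pyrosequencing-style per-CpG methylation tables (7 CpGs) for
# FOXP3+ and FOXP3- sorted fractions from cultures with and without pVC,
# summarises per-CpG percentages and per-sample averages, encodes the
# heatmap colors (yellow 0% -> green 50% -> blue 100%), and compares the
# sorted fractions: only FOXP3+ cells from pVC cultures carry a
# demethylated TSDR.

source("analysis/00_config.R")

am <- CFG$amplicon
donors <- 1:4
groups <- list()
rows <- list(); crows <- list()
for (grp in names(am$levels)) {
  lv <- rep(am$levels[[grp]], am$n_cpgs)
  summaries <- lapply(donors, function(d) {
    a <- simulate_amplicon(lv, am$n_reads, sample = sprintf("%s_d%d", grp, d),
                           seed = SEED + 50L + 10L * match(grp,
                                                           names(am$levels)) + d)
    rows[[length(rows) + 1L]] <<- cbind(group = grp, donor = d, a)
    summarize_amplicon(a)
  })
  groups[[grp]] <- summaries
  for (s in summaries) {
    crows[[length(crows) + 1L]] <- tibble::as_tibble(cbind(
      data.frame(sample = s$sample, cpg = seq_along(s$percent)),
      as.data.frame(heatmap_color(s$percent))))
  }
}
readr::write_csv(dplyr::bind_rows(rows), file.path(OUT, "amplicon.csv"))
readr::write_csv(dplyr::bind_rows(crows),
                 file.path(OUT, "amplicon_colors.csv"))

cmp <- compare_sorted_fractions(groups)
readr::write_tsv(cmp, file.path(OUT, "tsdr_group_summary.tsv"))
cat("average TSDR methylation by sorted fraction and culture:\n")
print(as.data.frame(cmp))

# optional heatmap figure (per-CpG percent, Fig-4-style color code)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  tab <- dplyr::bind_rows(rows)
  tab$sample <- sprintf("%s_d%d", tab$group, tab$donor)
  gg <- ggplot2::ggplot(tab, ggplot2::aes(sample, factor(cpg),
                                          fill = percent)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "yellow", mid = "darkgreen",
                                  high = "blue", midpoint = 50,
                                  limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "CpG", fill = "% methylation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
  ggplot2::ggsave(file.path(OUT, "tsdr_heatmap.pdf"), gg,
                  width = 7, height = 3)
  cat("heatmap written to", file.path(OUT, "tsdr_heatmap.pdf"), "\n")
}
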