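# DMR-to-gene assignment and local hypergeometric gene-set enrichment
# (an offline replacement for web-based over-representation tools).

#' Assign DMRs to gene bodies and promoters
#'
#' A DMR is assigned to a gene body on at least 1 bp overlap with the gene
#' interval, and to a promoter on at least 1 bp overlap with the
#' strand-aware window `[TSS - promoter_up, TSS + promoter_down)`.  A DMR
#' overlapping both receives both relations.
#'
#' @param dmrs DMR tibble from [call_dmrs()] (needs dmr_id, chrom, start,
#'   end).
#' @param genome A `ref_genome` with stranded gene features.
#' @param promoter_up,promoter_down Promoter extent upstream/downstream of
#'   the TSS in bp (defaults 2000/500).
#' @return Tibble (dmr_id, gene_id, relation, overlap_bp).
#' @export
assign_regions <- function(dmrs, genome, promoter_up = 2000,
                           promoter_down = 500) {
  empty <- tibble(dmr_id = character(), gene_id = character(),
                  relation = character(), overlap_bp = integer())
  genes <- genome_features(genome, "gene")
  if (nrow(dmrs) == 0 || nrow(genes) == 0) return(empty)
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene features must be stranded")
  }
  gr_dmr <- GenomicRanges::GRanges(
    dmrs$chrom, IRanges::IRanges(dmrs$start + 1L, dmrs$end))

  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  prom_start <- ifelse(genes$strand == "+", tss - promoter_up,
                       tss - promoter_down + 1L)
  prom_end <- ifelse(genes$strand == "+", tss + promoter_down,
                     tss + promoter_up + 1L)
  prom_start <- pmax(prom_start, 0L)

  out <- list()
  for (rel in c("gene_body", "promoter")) {
    if (rel == "gene_body") {
      gr_g <- GenomicRanges::GRanges(
        genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
    } else {
      gr_g <- GenomicRanges::GRanges(
        genes$chrom, IRanges::IRanges(prom_start + 1L, prom_end))
    }
    hits <- GenomicRanges::findOverlaps(gr_dmr, gr_g, minoverlap = 1L)
    if (length(hits) == 0) next
    ov <- IRanges::width(IRanges::pintersect(
      gr_dmr[S4Vectors::queryHits(hits)], gr_g[S4Vectors::subjectHits(hits)]))
    out[[rel]] <- tibble(
      dmr_id = dmrs$dmr_id[S4Vectors::queryHits(hits)],
      gene_id = genes$id[S4Vectors::subjectHits(hits)],
      relation = rel, overlap_bp = as.integer(ov))
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) empty else arrange(res, .data$dmr_id, .data$gene_id)
}

#' Read a GMT gene-set file
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of term descriptions
#'   (defaults to the term names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation test
#'
#' For each term, the p value is the upper hypergeometric tail
#' `P(X >= overlap)` with the full gene universe as population, the term's
#' genes (intersected with the universe) as successes and the query as the
#' draw.  No multiple-testing correction is applied to the significance
#' call (raw p <= 0.05); a Benjamini-Hochberg column is included for
#' information.
#'
#' @param query_genes Character vector of query genes (non-empty, a subset
#'   of `background`).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param background Character vector: the gene universe.
#' @return Tibble (term, term_size, overlap, p, padj, significant) sorted by
#'   p; terms without background overlap are skipped and listed in the
#'   `skipped` attribute.
#' @export
enrich <- function(query_genes, gene_sets, background) {
  query_genes <- unique(query_genes)
  background <- unique(background)
  if (length(query_genes) == 0) abort("empty query gene set")
  if (!all(query_genes %in% background)) {
    abort("query genes must be a subset of the background")
  }
  rows <- list()
  skipped <- character()
  for (term in names(gene_sets)) {
    tset <- intersect(gene_sets[[term]], background)
    if (length(tset) == 0) { skipped <- c(skipped, term); next }
    ov <- length(intersect(query_genes, tset))
    p <- phyper(ov - 1, length(tset), length(background) - length(tset),
                length(query_genes), lower.tail = FALSE)
    rows[[term]] <- tibble(term = term, term_size = length(tset),
                           overlap = ov, p = p)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(term = character(), term_size = integer(),
                  overlap = integer(), p = numeric())
  }
  out <- arrange(out, .data$p)
  out$padj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p <= 0.05
  attr(out, "skipped") <- skipped
  out
}
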