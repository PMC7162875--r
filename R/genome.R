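# Synthetic reference genomes with RRBS-friendly annotation.
#
# Coordinates are 0-based half-open everywhere inside the package; BED export
# keeps them unchanged, GTF export converts to 1-based inclusive.

# CpG-bearing cassettes implanted into the background sequence.  Each cassette
# is flanked by MspI sites (CCGG) so that its interior falls on a fragment that
# survives 40-220 bp size selection and is at least one read long.  Unit
# positions marked by A/T draws make every implanted copy unique, so cassette
# reads place unambiguously; the draws cannot create CpG or CCGG, keeping the
# CpG count per cassette fixed (one per unit plus the flanks).
.dmr_cassette <- function(n_units = 12) {
  w <- matrix(sample(c("A", "T"), 3 * n_units, replace = TRUE), ncol = 3)
  units <- paste0("T", w[, 1], "ACG", w[, 2], w[, 3], "A")
  paste0("CCGG", paste(units, collapse = ""), "CCGG")
}

.cgi_cassette <- function(n_units = 15) {
  w <- matrix(sample(c("A", "T"), 2 * n_units, replace = TRUE), ncol = 2)
  units <- paste0("TACG", w[, 1], w[, 2], "GCGA")
  paste0("CCGG", paste(units, collapse = ""), "CCGG")
}

#' Generate a synthetic reference genome with annotation
#'
#' Draws i.i.d. background sequence at a requested GC fraction, implants extra
#' MspI (CCGG) sites so that reduced-representation fragments densely tile the
#' genome, and lays down feature annotation: genes with strand, promoters
#' (TSS -2000/+500), CpG islands, optional ground-truth DMR cassettes, and one
#' TSDR-like cassette carrying at least 7 CpGs on its plus strand.  All
#' cassette features sit on MspI fragments of 40-220 bp so that downstream
#' read simulation covers them.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp (>= 10000).
#' @param gc_fraction Background GC fraction, in (0, 1).
#' @param ccgg_boost Multiplier controlling implanted CCGG density; a value of
#'   `b` implants roughly `(b - 1)` extra motifs per kb, so `b >= 2` gives at
#'   least one CCGG per kb on average.
#' @param n_genes Total number of gene features (distributed over chromosomes).
#' @param n_truth_dmrs Number of ground-truth DMR cassettes to implant
#'   (all on the first chromosome).
#' @param seed Integer seed; fixed seed gives a byte-identical genome.
#' @return An object of class `ref_genome`: a list with `chromosomes` (named
#'   character vector of uppercase DNA) and `features` (tibble with columns
#'   chrom, start, end, kind, id, strand; kinds are gene, promoter, CGI,
#'   truth_dmr, tsdr).
#' @export
generate_genome <- function(n_chrom = 1, chrom_length = 50000, gc_fraction = 0.5,
                            ccgg_boost = 3, n_genes = 20, n_truth_dmrs = 0,
                            seed = 1) {
  n_chrom <- check_positive_int(n_chrom, "n_chrom")
  chrom_length <- check_positive_int(chrom_length, "chrom_length")
  if (chrom_length < 10000) abort("`chrom_length` must be >= 10000")
  check_unit_interval(gc_fraction, "gc_fraction", open = TRUE)
  if (ccgg_boost < 1) abort("`ccgg_boost` must be >= 1")
  n_genes <- check_positive_int(n_genes, "n_genes")
  if (n_truth_dmrs < 0) abort("`n_truth_dmrs` must be >= 0")

  withr::with_seed(seed, {
    chrom_names <- paste0("chr", seq_len(n_chrom))
    genes_per_chrom <- diff(floor(seq(0, n_genes, length.out = n_chrom + 1)))
    chromosomes <- character(n_chrom)
    names(chromosomes) <- chrom_names
    feats <- list()
    gene_counter <- 0L

    for (ci in seq_len(n_chrom)) {
      L <- chrom_length
      ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
                            gc_fraction / 2, (1 - gc_fraction) / 2))

      # implanted CCGG motifs give RRBS fragment density
      n_implant <- round(L / 1000 * max(0, ccgg_boost - 1))
      if (n_implant > 0) {
        at <- sample.int(L - 3L, n_implant)          # 1-based start
        for (p in at) ch[p:(p + 3L)] <- c("C", "C", "G", "G")
      }

      # cassette anchors: well-separated grid slots away from chromosome ends
      is_first <- ci == 1L
      n_cgi <- max(2L, n_genes %/% 10L)
      n_cassettes <- n_cgi + if (is_first) n_truth_dmrs + 1L else 0L
      grid <- seq(2500L, L - 2500L, by = 1500L)
      if (length(grid) < n_cassettes) {
        abort("chromosome too short for the requested number of features")
      }
      anchors <- sort(sample(grid, n_cassettes))
      kinds <- c(rep("CGI", n_cgi),
                 if (is_first) c(rep("truth_dmr", n_truth_dmrs), "tsdr"))
      kinds <- sample(kinds)   # interleave cassette kinds along the chromosome
      cgi_i <- 0L; dmr_i <- 0L
      for (j in seq_along(anchors)) {
        cass <- switch(kinds[j], CGI = .cgi_cassette(), .dmr_cassette())
        cw <- nchar(cass)
        p0 <- anchors[j]                              # 0-based start
        ch[(p0 + 1L):(p0 + cw)] <- strsplit(cass, "", fixed = TRUE)[[1]]
        id <- switch(kinds[j],
                     CGI = { cgi_i <- cgi_i + 1L
                             sprintf("cgi_%s_%d", ci, cgi_i) },
                     truth_dmr = { dmr_i <- dmr_i + 1L
                                   sprintf("dmr_%d", dmr_i) },
                     tsdr = "tsdr")
        feats[[length(feats) + 1L]] <- tibble(
          chrom = chrom_names[ci], start = p0, end = p0 + cw,
          kind = kinds[j], id = id, strand = "+")
      }

      # genes on per-chromosome slots; promoters strand-aware around the TSS
      ng <- genes_per_chrom[ci]
      if (ng > 0) {
        W <- L %/% ng
        for (g in seq_len(ng)) {
          gene_counter <- gene_counter + 1L
          slot0 <- (g - 1L) * W
          glen_hi <- min(3000L, W - 200L)
          glen_lo <- min(1000L, glen_hi)
          if (glen_hi < 200L) abort("`n_genes` too large for `chrom_length`")
          glen <- sample(glen_lo:glen_hi, 1)
          gstart <- slot0 + sample.int(max(1L, W - glen - 100L), 1)
          gend <- gstart + glen
          strand <- sample(c("+", "-"), 1)
          gid <- sprintf("gene_%d", gene_counter)
          tss <- if (strand == "+") gstart else gend - 1L
          prom <- if (strand == "+") c(tss - 2000L, tss + 500L)
                  else c(gend - 500L, gend + 2000L)
          prom <- pmin(pmax(prom, 0L), L)
          feats[[length(feats) + 1L]] <- tibble(
            chrom = chrom_names[ci],
            start = c(gstart, prom[1]), end = c(gend, prom[2]),
            kind = c("gene", "promoter"),
            id = c(gid, paste0(gid, "_prom")),
            strand = strand)
        }
      }
      chromosomes[ci] <- paste(ch, collapse = "")
    }

    features <- bind_rows(feats) |> arrange(.data$chrom, .data$start)
    structure(list(chromosomes = chromosomes, features = features),
              class = "ref_genome")
  })
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("<ref_genome> %d chromosome(s), %s bp total, %d features\n",
              length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ","),
              nrow(x$features)))
  print(table(x$features$kind))
  invisible(x)
}

#' Look up features of a reference genome
#'
#' @param genome A `ref_genome`.
#' @param kind Optional feature kind(s) to keep.
#' @return Tibble of features.
#' @export
genome_features <- function(genome, kind = NULL) {
  f <- genome$features
  if (!is.null(kind)) f <- f[f$kind %in% kind, ]
  f
}

#' Write a reference genome to FASTA
#'
#' @param genome A `ref_genome`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$chromosomes)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Export genome features as BED6
#'
#' @param genome A `ref_genome`.
#' @param path Output BED path.
#' @param kind Optional feature kind(s) to keep.
#' @return `path`, invisibly.
#' @export
export_features_bed <- function(genome, path, kind = NULL) {
  f <- genome_features(genome, kind)
  gr <- GenomicRanges::GRanges(
    f$chrom, IRanges::IRanges(f$start + 1L, f$end), strand = f$strand)
  gr$name <- paste(f$kind, f$id, sep = ":")
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export gene features as GTF
#'
#' @param genome A `ref_genome`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
export_genes_gtf <- function(genome, path) {
  f <- genome_features(genome, "gene")
  gr <- GenomicRanges::GRanges(
    f$chrom, IRanges::IRanges(f$start + 1L, f$end), strand = f$strand)
  gr$source <- "rrbsdmr"
  gr$type <- "gene"
  gr$gene_id <- f$id
  rtracklayer::export(gr, path, format = "GTF")
  invisible(path)
}
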