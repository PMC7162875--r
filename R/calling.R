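# Collapsed-alphabet read placement and per-cytosine methylation calling.
#
# Bisulfite conversion makes the read alphabet asymmetric: an original-top
# (OT) read matches the forward reference once both are collapsed C->T, and
# the reverse complement of an original-bottom (OB) read matches the forward
# reference once both are collapsed G->A.  Placement searches both
# orientations, keeps a unique best hit with at most `max_mismatch`
# mismatches, and discards ambiguous or unplaced reads (counted on the
# result).  Exact hits are found in bulk with a PDict; only reads without an
# exact hit fall back to the mismatch-tolerant scan.

#' Place bisulfite reads on a reference genome
#'
#' @param reads Tibble with columns `id` and `seq` (constant read length),
#'   e.g. from [simulate_reads()] or [read_fastq()].
#' @param genome A `ref_genome`.
#' @param max_mismatch Maximum mismatches for the fallback scan (default 2).
#' @return Tibble (id, seq, chrom, start, lib, mismatches) of placed reads
#'   (`start` 0-based, `lib` in OT/OB), with attributes `n_input`,
#'   `n_placed`, `n_ambiguous`, `n_unplaced`.
#' @export
place_reads <- function(reads, genome, max_mismatch = 2) {
  n_input <- nrow(reads)
  if (n_input == 0) {
    out <- tibble(id = character(), seq = character(), chrom = character(),
                  start = integer(), lib = character(), mismatches = integer())
    attr(out, "n_input") <- 0L
    return(out)
  }
  if (length(unique(nchar(reads$seq))) != 1) {
    abort("reads must have constant length within a run")
  }

  q_ot <- chartr("C", "T", reads$seq)
  q_ob <- chartr("G", "A", revcomp(reads$seq))
  subj_ct <- lapply(genome$chromosomes,
                    function(s) Biostrings::DNAString(chartr("C", "T", s)))
  subj_ga <- lapply(genome$chromosomes,
                    function(s) Biostrings::DNAString(chartr("G", "A", s)))

  hit_table <- function(queries, subjects, lib) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(queries))
    hits <- lapply(names(subjects), function(cn) {
      mi <- Biostrings::matchPDict(pd, subjects[[cn]])
      st <- Biostrings::startIndex(mi)
      nh <- lengths(st)
      if (sum(nh) == 0) return(NULL)
      tibble(read_idx = rep(seq_along(st), nh),
             chrom = cn, start1 = unlist(st), lib = lib)
    })
    bind_rows(hits)
  }

  exact <- bind_rows(hit_table(q_ot, subj_ct, "OT"),
                     hit_table(q_ob, subj_ga, "OB"))
  if (nrow(exact) == 0) {
    exact <- tibble(read_idx = integer(), chrom = character(),
                    start1 = integer(), lib = character())
  }
  n_hits <- tabulate(exact$read_idx, nbins = n_input)
  ambiguous <- n_hits > 1L
  placed <- exact[exact$read_idx %in% which(n_hits == 1L), ]
  placed$mismatches <- 0L

  # mismatch-tolerant fallback for reads without an exact hit
  extra <- list()
  if (max_mismatch > 0) {
    for (ri in which(n_hits == 0L)) {
      cand <- list()
      for (cn in names(subj_ct)) {
        for (lib in c("OT", "OB")) {
          q <- if (lib == "OT") q_ot[ri] else q_ob[ri]
          subj <- if (lib == "OT") subj_ct[[cn]] else subj_ga[[cn]]
          m <- Biostrings::matchPattern(q, subj, max.mismatch = max_mismatch)
          if (length(m) == 0) next
          mm <- Biostrings::neditStartingAt(Biostrings::DNAString(q), subj,
                                            starting.at = BiocGenerics::start(m),
                                            with.indels = FALSE)
          cand[[length(cand) + 1L]] <- tibble(
            read_idx = ri, chrom = cn, start1 = BiocGenerics::start(m),
            lib = lib, mismatches = as.integer(mm))
        }
      }
      if (!length(cand)) next
      cand <- bind_rows(cand)
      best <- cand[cand$mismatches == min(cand$mismatches), ]
      if (nrow(best) == 1L) {
        extra[[length(extra) + 1L]] <- best
      } else {
        ambiguous[ri] <- TRUE
      }
    }
  }

  placed <- bind_rows(placed, bind_rows(extra))
  out <- tibble(id = reads$id[placed$read_idx],
                seq = reads$seq[placed$read_idx],
                chrom = placed$chrom,
                start = placed$start1 - 1L,
                lib = placed$lib,
                mismatches = placed$mismatches)
  attr(out, "n_input") <- n_input
  attr(out, "n_placed") <- nrow(out)
  attr(out, "n_ambiguous") <- sum(ambiguous)
  attr(out, "n_unplaced") <- n_input - nrow(out) - sum(ambiguous)
  out
}

#' Call per-cytosine methylation from placed reads
#'
#' At each reference cytosine on a read's informative strand (top-strand C
#' for OT reads, top-strand G -- a bottom-strand C -- for OB reads), a read
#' base C increments the methylated count `mC`, a T increments the
#' unmethylated count `uC`, and any other base is ignored as sequencing
#' error.  The level is `mC / (mC + uC)`; sites with total coverage below
#' `min_coverage` are omitted.
#'
#' @param placements Tibble from [place_reads()].
#' @param genome A `ref_genome`.
#' @param min_coverage Minimum `mC + uC` for a site to be reported.
#' @param sample Sample label stored on the table.
#' @return Methylome tibble (chrom, pos, strand, context, mC, uC, level)
#'   sorted by chrom then position, unique per (chrom, pos, strand).
#' @export
call_cytosines <- function(placements, genome, min_coverage = 1,
                           sample = "sample1") {
  tabs <- list()
  for (cn in names(genome$chromosomes)) {
    seq <- genome$chromosomes[[cn]]
    L <- nchar(seq)
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    pl <- placements[placements$chrom == cn, ]
    mC_p <- uC_p <- mC_m <- uC_m <- integer(L)
    if (nrow(pl)) {
      rl <- nchar(pl$seq[1])
      for (lib in c("OT", "OB")) {
        sel <- pl$lib == lib
        if (!any(sel)) next
        seqs <- if (lib == "OT") pl$seq[sel] else revcomp(pl$seq[sel])
        idx <- rep(pl$start[sel], each = rl) + seq_len(rl)   # 1-based
        base <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
        ref <- ch[idx]
        if (lib == "OT") {
          at_c <- ref == "C"
          mC_p <- mC_p + tabulate(idx[at_c & base == "C"], nbins = L)
          uC_p <- uC_p + tabulate(idx[at_c & base == "T"], nbins = L)
        } else {
          at_g <- ref == "G"
          mC_m <- mC_m + tabulate(idx[at_g & base == "G"], nbins = L)
          uC_m <- uC_m + tabulate(idx[at_g & base == "A"], nbins = L)
        }
      }
    }
    ctx <- cytosine_contexts(seq)
    i1 <- ctx$pos + 1L
    mC <- ifelse(ctx$strand == "+", mC_p[i1], mC_m[i1])
    uC <- ifelse(ctx$strand == "+", uC_p[i1], uC_m[i1])
    keep <- (mC + uC) >= max(1L, min_coverage)
    if (any(keep)) {
      tabs[[cn]] <- tibble(chrom = cn, pos = ctx$pos[keep],
                           strand = ctx$strand[keep],
                           context = ctx$context[keep],
                           mC = as.integer(mC[keep]),
                           uC = as.integer(uC[keep]))
    }
  }
  out <- bind_rows(tabs)
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), pos = integer(), strand = character(),
                  context = character(), mC = integer(), uC = integer())
  }
  out$level <- out$mC / (out$mC + out$uC)
  out <- arrange(out, .data$chrom, .data$pos, .data$strand)
  attr(out, "sample") <- sample
  attr(out, "min_coverage") <- min_coverage
  out
}

#' Export a methylome table as a CX-style TSV report
#'
#' @param table Methylome tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_cx <- function(table, path) {
  readr::write_tsv(table[, c("chrom", "pos", "strand", "context",
                             "mC", "uC", "level")], path)
  invisible(path)
}

#' Import a CX-style TSV report
#'
#' The level column is recomputed from the counts so that a round trip
#' through [export_cx()] reproduces the table exactly.
#'
#' @param path TSV path written by [export_cx()].
#' @param sample Sample label to attach.
#' @return Methylome tibble.
#' @export
import_cx <- function(path, sample = "sample1") {
  out <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    strand = readr::col_character(), context = readr::col_character(),
    mC = readr::col_integer(), uC = readr::col_integer(),
    level = readr::col_double()))
  out$level <- out$mC / (out$mC + out$uC)
  out <- arrange(out, .data$chrom, .data$pos, .data$strand)
  attr(out, "sample") <- sample
  out
}

#' Export per-site methylation levels as bedGraph
#'
#' @param table Methylome tibble.
#' @param path Output bedGraph path.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(table, path) {
  gr <- GenomicRanges::GRanges(table$chrom,
                               IRanges::IRanges(table$pos + 1L, width = 1L),
                               score = table$level)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
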