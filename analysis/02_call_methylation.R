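#!/usr/bin/env Rscript
# Stage 2 -- place the bisulfite reads and call per-cytosine methylation.
#
# Reads each arm's FASTQ back from disk, places reads with the
# collapsed-alphabet search (C->T on the forward strand, G->A on the
# reverse; unique best placement with <= 2 mismatches), and tabulates
# methylated (C) vs unmethylated (T) observations at every covered
# cytosine: level = mC / (mC + uC).  Writes one CX-style TSV and one
# bedGraph per arm.

source("analysis/00_config.R")

genome <- study_genome()
for (arm in ARMS) {
  reads <- read_fastq(file.path(OUT, sprintf("reads_%s.fastq", arm)))
  pl <- place_reads(reads, genome, CFG$calling$max_mismatch)
  tab <- call_cytosines(pl, genome, CFG$calling$min_coverage, sample = arm)
  export_cx(tab, file.path(OUT, sprintf("methylome_%s.tsv", arm)))
  export_bedgraph(tab, file.path(OUT, sprintf("levels_%s.bedGraph", arm)))
  cat(sprintf(
    "  %-9s %6d placed / %d reads (%d ambiguous), %6d sites called\n",
    arm, attr(pl, "n_placed"), attr(pl, "n_input"),
    attr(pl, "n_ambiguous"), nrow(tab)))
}
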