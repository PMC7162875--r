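# Read placement and per-cytosine methylation calling.

test_that("context classification follows the strand-aware definition", {
  g <- toy_genome(c(chrA = "TACGTCAGTCTTG"))
  #                 0123456789...
  expect_equal(classify_context(g, "chrA", 2, "+"), "CpG")  # C G
  expect_equal(classify_context(g, "chrA", 5, "+"), "CHG")  # C A G
  expect_equal(classify_context(g, "chrA", 9, "+"), "CHH")  # C T T
  expect_equal(classify_context(g, "chrA", 3, "-"), "CpG")  # G preceded by C
  expect_error(classify_context(g, "chrA", 0, "+"), "not a cytosine")
  # truncated context near the chromosome end defaults to CHH
  g2 <- toy_genome(c(chrA = "AAC"))
  expect_equal(classify_context(g2, "chrA", 2, "+"), "CHH")
})

test_that("reads place uniquely under the collapsed alphabet", {
  # unique 20-mer inside a toy chromosome; read carries C->T conversions
  g <- toy_genome(c(chrA = paste0("GATTACAGATTACA",
                                  "ACGTTGCAATCGGATCATGC",
                                  "TTGACCTTGGAATT")))
  read_ot <- chartr("C", "T", "ACGTTGCAATCGGATCATGC")
  pl <- place_reads(tibble::tibble(id = "r1", seq = read_ot), g)
  expect_equal(nrow(pl), 1L)
  expect_equal(pl$start, 14L)
  expect_equal(pl$lib, "OT")

  # a read matching two loci equally is discarded as ambiguous
  g2 <- toy_genome(c(chrA = paste0("ACGTTGCAATCGGATCATGC", "TTTTT",
                                   "ACGTTGCAATCGGATCATGC")))
  pl2 <- place_reads(tibble::tibble(id = "r1", seq = read_ot), g2)
  expect_equal(nrow(pl2), 0L)
  expect_equal(attr(pl2, "n_ambiguous"), 1L)
})

test_that("simulated error-free reads place back at their true origin", {
  g <- generate_genome(1, 20000, 0.5, 3, 5, n_truth_dmrs = 1, seed = 21)
  fr <- size_select(digest_mspi(g))
  pr <- assign_profile(g, "TGFb", seed = 22)
  rd <- simulate_reads(g, fr, pr, 50, 8, 0.995, 0, seed = 23)
  pl <- place_reads(rd, g)
  expect_gte(attr(pl, "n_placed") / nrow(rd), 0.99)
  m <- dplyr::inner_join(pl, rd, by = "id", suffix = c(".obs", ".true"))
  expect_true(all(m$start.obs == m$start.true & m$lib.obs == m$lib.true))
})

test_that("cytosine calling implements mC / (mC + uC)", {
  # 12 bp toy genome, one CpG at pos 4 (+); four OT reads: C,C,C,T there
  g <- toy_genome(c(chrA = "ATTACGATTTAG"))
  base <- "ATTACGATTTAG"
  reads <- tibble::tibble(
    id = paste0("r", 1:4),
    seq = c(base, base, base, sub("CG", "TG", base)),
    chrom = "chrA", start = 0L, lib = "OT", mismatches = 0L)
  tab <- call_cytosines(reads, g, min_coverage = 1)
  site <- tab[tab$pos == 4 & tab$strand == "+", ]
  expect_equal(site$mC, 3L)
  expect_equal(site$uC, 1L)
  expect_equal(site$level, 0.75)
  expect_equal(site$context, "CpG")
  # the bottom-strand partner of the CpG has no OB coverage -> absent
  expect_false(any(tab$strand == "-"))
  # uncovered chromosome -> empty table, and calling is deterministic
  expect_identical(call_cytosines(reads, g, 1), tab)
})

test_that("calling is exact when conversion is perfect and error-free", {
  g <- generate_genome(1, 15000, 0.5, 3, 4, n_truth_dmrs = 1, seed = 31)
  fr <- size_select(digest_mspi(g))
  pr <- assign_profile(g, "medium", 1, 0, jitter_sd = 0, seed = 32)
  rd <- simulate_reads(g, fr, pr, 50, 15, 1, 0, seed = 33)
  tab <- call_cytosines(place_reads(rd, g), g, 1)
  cmp <- dplyr::inner_join(tab, pr, by = c("chrom", "pos", "strand",
                                           "context"))
  expect_equal(nrow(cmp), nrow(tab))     # every called site is a cytosine
  expect_equal(max(abs(cmp$level - cmp$true_level)), 0)
  # coverage never exceeds the number of overlapping placed reads
  expect_lte(max(tab$mC + tab$uC), nrow(rd))
})

test_that("CX report round-trips exactly", {
  g <- generate_genome(1, 12000, 0.5, 3, 3, seed = 41)
  fr <- size_select(digest_mspi(g))
  pr <- assign_profile(g, "pVC", seed = 42)
  rd <- simulate_reads(g, fr, pr, 50, 6, 0.995, 0.001, seed = 43)
  tab <- call_cytosines(place_reads(rd, g), g, 1, sample = "pVC")
  f <- tempfile(fileext = ".tsv")
  export_cx(tab, f)
  back <- import_cx(f, sample = "pVC")
  expect_equal(as.data.frame(back), as.data.frame(tab), ignore_attr = TRUE)
  # bedGraph export emits one line per site plus the track header
  bg <- tempfile(fileext = ".bedGraph")
  export_bedgraph(tab, bg)
  expect_gte(length(readLines(bg)), nrow(tab))
})

test_that("min_coverage filters sites from the table", {
  g <- generate_genome(1, 12000, 0.5, 3, 3, seed = 51)
  fr <- size_select(digest_mspi(g))
  pr <- assign_profile(g, "medium", seed = 52)
  rd <- simulate_reads(g, fr, pr, 50, 6, 0.995, 0, seed = 53)
  pl <- place_reads(rd, g)
  t1 <- call_cytosines(pl, g, 1)
  t5 <- call_cytosines(pl, g, 5)
  expect_lt(nrow(t5), nrow(t1))
  expect_true(all(t5$mC + t5$uC >= 5))
  keys <- function(t) paste(t$chrom, t$pos, t$strand)
  expect_true(all(keys(t5) %in% keys(t1)))
})
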