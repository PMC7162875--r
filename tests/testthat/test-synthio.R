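# Synthetic genome, profile, digestion and read/assay generators.

test_that("genome generation is seed-deterministic and seed-sensitive", {
  g1 <- generate_genome(1, 50000, 0.5, 3, 20, seed = 1)
  g2 <- generate_genome(1, 50000, 0.5, 3, 20, seed = 1)
  g3 <- generate_genome(1, 50000, 0.5, 3, 20, seed = 2)
  expect_identical(g1$chromosomes, g2$chromosomes)
  expect_identical(g1$features, g2$features)
  expect_false(identical(g1$chromosomes, g3$chromosomes))
})

test_that("ccgg_boost increases CCGG density as promised", {
  lo <- generate_genome(1, 50000, 0.5, 1, 20, seed = 1)
  hi <- generate_genome(1, 50000, 0.5, 3, 20, seed = 1)
  expect_gt(count_ccgg(hi$chromosomes[[1]]), count_ccgg(lo$chromosomes[[1]]))
  boosted <- generate_genome(1, 50000, 0.5, 2, 20, seed = 3)
  expect_gte(count_ccgg(boosted$chromosomes[[1]]), 50000 / 1000)
})

test_that("genome annotation is well-formed", {
  g <- generate_genome(2, 20000, 0.45, 3, 10, n_truth_dmrs = 3, seed = 5)
  f <- g$features
  lens <- nchar(g$chromosomes)
  expect_true(all(f$start >= 0))
  expect_true(all(f$end <= lens[f$chrom]))
  expect_true(all(f$start < f$end))
  expect_true(all(grepl("^[ACGT]+$", g$chromosomes)))
  # every gene has a promoter; exactly one TSDR with >= 7 CpGs
  expect_equal(sum(f$kind == "promoter"), sum(f$kind == "gene"))
  tsdr <- f[f$kind == "tsdr", ]
  expect_equal(nrow(tsdr), 1L)
  tseq <- substr(g$chromosomes[[tsdr$chrom]], tsdr$start + 1, tsdr$end)
  expect_gte(count_ccgg(tseq) + lengths(regmatches(
    tseq, gregexpr("CG", tseq)))[1], 7)
  expect_equal(sum(f$kind == "truth_dmr"), 3L)
  expect_error(generate_genome(1, 5000, 0.5, 3, 5, seed = 1), "chrom_length")
  expect_error(generate_genome(0, 20000, 0.5, 3, 5, seed = 1), "n_chrom")
  expect_error(generate_genome(1, 20000, 1.5, 3, 5, seed = 1), "gc_fraction")
})

test_that("MspI digestion cuts after the first C of every CCGG", {
  g <- toy_genome(c(chrA = "AACCGGTTCCGGAA"))
  fr <- digest_mspi(g)
  expect_equal(fr$start, c(0L, 3L, 9L))
  expect_equal(fr$end, c(3L, 9L, 14L))
  expect_equal(fr$length, c(3L, 6L, 5L))

  g2 <- toy_genome(c(chrA = "CCGGCCGG"))
  fr2 <- digest_mspi(g2)
  expect_equal(fr2$start, c(0L, 1L, 5L))
  expect_equal(fr2$end, c(1L, 5L, 8L))

  g3 <- toy_genome(c(chrA = "ATATATATAT"))
  fr3 <- digest_mspi(g3)
  expect_equal(nrow(fr3), 1L)
  expect_equal(fr3$length, 10L)
})

test_that("fragments partition every chromosome", {
  g <- generate_genome(2, 15000, 0.55, 3, 6, seed = 9)
  fr <- digest_mspi(g)
  for (cn in names(g$chromosomes)) {
    fc <- fr[fr$chrom == cn, ]
    expect_equal(sum(fc$length), nchar(g$chromosomes[[cn]]))
    expect_equal(fc$start[-1], fc$end[-nrow(fc)])  # contiguous tiling
    expect_equal(fc$start[1], 0L)
  }
})

test_that("size selection keeps the inclusive 40-220 bp range", {
  fr <- tibble::tibble(chrom = "c", start = 0L,
                       end = c(39L, 40L, 220L, 221L),
                       length = c(39L, 40L, 220L, 221L))
  kept <- size_select(fr)
  expect_equal(kept$length, c(40L, 220L))
  expect_equal(nrow(size_select(fr[0, ])), 0L)
  mid <- tibble::tibble(chrom = "c", start = 0L, end = c(99L, 100L, 101L),
                        length = c(99L, 100L, 101L))
  expect_equal(size_select(mid, 100, 100)$length, 100L)
  expect_identical(size_select(size_select(fr)), size_select(fr))
  expect_error(size_select(fr, 100, 50), "min_bp")
})

test_that("profiles assign condition-specific levels inside spec features", {
  g <- generate_genome(1, 20000, 0.5, 3, 5, n_truth_dmrs = 1, seed = 2)
  spec <- list(tsdr = c(TGFb_pVC = 0.1), dmr_1 = c(TGFb_pVC = 0.2,
                                                   medium = 0.9))
  pr <- assign_profile(g, "TGFb_pVC", 0.8, 0.01, spec, seed = 4)
  tsdr <- genome_features(g, "tsdr")
  sel <- pr$chrom == tsdr$chrom & pr$pos >= tsdr$start &
    pr$pos < tsdr$end & pr$context == "CpG"
  expect_true(all(pr$true_level[sel] == 0.1))
  expect_gte(sum(sel), 7)

  # background levels: in [0,1], mean near the requested base levels
  out <- !(pr$pos >= tsdr$start & pr$pos < tsdr$end)
  d1 <- genome_features(g, "truth_dmr")
  out <- out & !(pr$pos >= d1$start & pr$pos < d1$end)
  expect_true(all(pr$true_level >= 0 & pr$true_level <= 1))
  expect_lt(abs(mean(pr$true_level[out & pr$context == "CHH"]) - 0.01), 0.005)
  expect_lt(abs(mean(pr$true_level[out & pr$context == "CpG"]) - 0.8), 0.01)

  # two arms sharing the spec agree exactly inside spec features
  pr2 <- assign_profile(g, "TGFb_pVC", 0.3, 0.05, spec, seed = 99)
  expect_equal(pr$true_level[sel], pr2$true_level[sel])

  expect_error(assign_profile(g, "mock", 0.8, 0.01, seed = 1), "condition")
  expect_error(assign_profile(g, "medium", 0.8, 0.01,
                              dmr_spec = list(nope = c(medium = 1)),
                              seed = 1), "nope")
})

test_that("every reference cytosine appears exactly once in a profile", {
  g <- generate_genome(1, 12000, 0.5, 2, 3, seed = 8)
  pr <- assign_profile(g, "medium", seed = 1)
  ch <- strsplit(g$chromosomes[[1]], "")[[1]]
  expect_equal(sum(pr$strand == "+"), sum(ch == "C"))
  expect_equal(sum(pr$strand == "-"), sum(ch == "G"))
  expect_false(any(duplicated(pr[, c("chrom", "pos", "strand")])))
})

test_that("bisulfite reads reflect methylation state and conversion", {
  g <- generate_genome(1, 15000, 0.5, 3, 4, seed = 3)
  fr <- size_select(digest_mspi(g))

  # fully methylated, perfect conversion, no errors: reads == reference
  pr1 <- assign_profile(g, "medium", 1, 1, jitter_sd = 0, seed = 1)
  rd1 <- simulate_reads(g, fr, pr1, 50, 5, 1, 0, seed = 7)
  ot <- rd1[rd1$lib == "OT", ]
  refs <- substr(g$chromosomes[ot$chrom], ot$start + 1, ot$start + 50)
  expect_equal(ot$seq, unname(refs))
  ob <- rd1[rd1$lib == "OB", ]
  refs_ob <- substr(g$chromosomes[ob$chrom], ob$start + 1, ob$start + 50)
  expect_equal(ob$seq, unname(as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(refs_ob)))))

  # fully unmethylated: every cytosine on the read strand is emitted as T,
  # so no read of either library orientation contains a C
  pr0 <- assign_profile(g, "medium", 0, 0, jitter_sd = 0, seed = 1)
  rd0 <- simulate_reads(g, fr, pr0, 50, 5, 1, 0, seed = 7)
  expect_false(any(grepl("C", rd0$seq)))

  # incomplete conversion at level 0 leaves ~1% residual C
  rd99 <- simulate_reads(g, fr, pr0, 50, 20, 0.99, 0, seed = 11)
  ot99 <- rd99[rd99$lib == "OT", ]
  ref99 <- substr(g$chromosomes[ot99$chrom], ot99$start + 1, ot99$start + 50)
  refc <- strsplit(unname(ref99), "")
  readc <- strsplit(ot99$seq, "")
  at_c <- unlist(refc) == "C"
  obs <- unlist(readc)[at_c]
  n <- length(obs)
  expect_gt(n, 10000)
  se <- sqrt(0.01 * 0.99 / n)
  expect_lt(abs(mean(obs == "C") - 0.01), 3 * se)
})

test_that("FASTQ output is byte-identical for a fixed seed and round-trips", {
  g <- generate_genome(1, 12000, 0.5, 3, 3, seed = 4)
  fr <- size_select(digest_mspi(g))
  pr <- assign_profile(g, "pVC", seed = 2)
  rd <- simulate_reads(g, fr, pr, 50, 4, 0.995, 0.001, seed = 5)
  rd_again <- simulate_reads(g, fr, pr, 50, 4, 0.995, 0.001, seed = 5)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(rd, f1); write_fastq(rd_again, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_fastq(f1)
  expect_equal(back$seq, rd$seq)
  expect_equal(back$start, rd$start)
  expect_equal(back$lib, rd$lib)
  expect_error(simulate_reads(g, fr, pr, 50, 4, 1.5, 0, seed = 1),
               "conversion_rate")
})

test_that("amplicon simulation follows the binomial sampling model", {
  a0 <- simulate_amplicon(rep(0, 7), 500, seed = 1)
  expect_true(all(a0$percent == 0))
  a1 <- simulate_amplicon(rep(1, 7), 500, seed = 1)
  expect_true(all(a1$percent == 100))
  ah <- simulate_amplicon(rep(0.5, 7), 10000, seed = 3)
  expect_true(all(abs(ah$percent - 50) < 1.5))   # 3 binomial SE
})

test_that("cytometry event tables honour the requested composition", {
  ev <- simulate_suppression_assay(c(gd = 100, cd4 = 0), 500, c(1), seed = 1)
  expect_equal(sum(ev$role == "cd4"), 0L)
  expect_equal(sum(ev$role == "standard"), 500L)
  ev2 <- simulate_suppression_assay(c(cd4 = 2000), 100, c(1), seed = 2)
  cfse <- ev2$cfse[ev2$role == "cd4"]
  # all-in-generation-0: one tight lognormal mode
  expect_true(all(ev2$generation[ev2$role == "cd4"] == 0))
  expect_lt(diff(range(log2(cfse))), 2)
  expect_error(simulate_suppression_assay(c(cd4 = -5), 100, c(1), seed = 1),
               "true_counts")
})
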