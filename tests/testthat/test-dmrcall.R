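# Fisher exact test and the windowing / testing / merging DMR algorithm.

test_that("two-sided Fisher p matches hand enumeration on known tables", {
  # margins 10/10: only the two extreme tables are as improbable
  expect_equal(fisher_exact_two_sided(10, 0, 0, 10), 2 / 184756,
               tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_two_sided(0, 0, 0, 0), 1)   # convention
  expect_equal(fisher_exact_two_sided(0, 0, 3, 5), 1)   # degenerate margin
  expect_error(fisher_exact_two_sided(-1, 0, 0, 1), "counts")
})

test_that("Fisher p agrees with enumeration and stats::fisher.test", {
  set.seed(71)
  for (i in 1:300) {
    n <- sample(1:40, 1)
    a <- sample(0:n, 1); b <- n - a
    m <- sample(0:40, 1)
    c <- sample(0:m, 1); d <- m - c
    mine <- fisher_exact_two_sided(a, b, c, d)
    expect_equal(mine, enum_fisher(a, b, c, d), tolerance = 1e-10)
    if (a + b > 0 && c + d > 0 && a + c + b + d > 0) {
      expect_equal(mine,
                   stats::fisher.test(matrix(c(a, b, c, d), 2,
                                             byrow = TRUE))$p.value,
                   tolerance = 1e-9)
    }
  }
})

test_that("window scan slides one site at a time over qualifying sites", {
  mk <- function(n, mC, uC, pos = NULL) {
    toy_methylome("chr1", pos %||% seq(0, by = 10, length.out = n),
                  "+", "CpG", rep(mC, n), rep(uC, n))
  }
  m1 <- mk(7, 8, 2); m2 <- mk(7, 2, 8)
  w <- scan_windows(m1, m2, min_sites = 5, min_cov = 5)
  expect_equal(nrow(w), 3L)          # n - w + 1
  expect_equal(w$start, c(0L, 10L, 20L))
  expect_equal(w$end, c(41L, 51L, 61L))
  expect_true(all(w$mC1 == 40 & w$uC2 == 40))

  expect_equal(nrow(scan_windows(mk(4, 8, 2), mk(4, 2, 8))), 0L)

  # a site covered in one sample only is excluded everywhere
  m1b <- mk(6, 8, 2)
  m2b <- mk(6, 2, 8)
  m2b <- m2b[m2b$pos != 20, ]        # drop one site from sample 2
  wb <- scan_windows(m1b, m2b, min_sites = 5, min_cov = 5)
  expect_equal(nrow(wb), 1L)
  expect_false(20 %in% (attr(wb, "sites")$pos))

  # low-coverage sites do not qualify
  m1c <- mk(6, 8, 2); m2c <- mk(6, 2, 8)
  m2c$uC[3] <- 1L; m2c$level <- m2c$mC / (m2c$mC + m2c$uC)  # cov 3 < 5
  expect_equal(nrow(qualifying_sites <- attr(
    scan_windows(m1c, m2c), "sites")), 5L)
})

test_that("window criteria combine fold change, Fisher p and hypomethylation", {
  w <- tibble::tibble(chrom = "chr1", start = 0L, end = 50L, site_from = 1L,
                      site_to = 5L, n_sites = 5L,
                      mC1 = c(30L, 15L, 30L), uC1 = c(20L, 85L, 10L),
                      mC2 = c(12L, 5L, 10L), uC2 = c(36L, 95L, 30L),
                      L1 = NA_real_, L2 = NA_real_,
                      window_id = paste0("w", 1:3))
  w$L1 <- w$mC1 / (w$mC1 + w$uC1)
  w$L2 <- w$mC2 / (w$mC2 + w$uC2)
  out <- test_windows(w)
  # 0.60 vs 0.25 -> fold 2.4
  expect_equal(out$fold_change[1], 2.4)
  expect_true(out$pass[1])
  # 0.15 vs 0.05 -> both below the 0.2 threshold, fails the hypo rule
  expect_equal(out$fold_change[2], 3)
  expect_false(out$pass[2])
  # (30,10) vs (10,30): fold 0.75/0.25 = 3, enumeration p < 0.05
  expect_equal(out$fold_change[3], 3)
  expect_lt(out$fisher_p[3], 0.05)
  expect_equal(out$fisher_p[3], enum_fisher(30, 10, 10, 30),
               tolerance = 1e-12)
  expect_true(out$pass[3])
  # "neither" rule rejects windows where only one sample clears 0.2
  strict <- test_windows(w, hypo_rule = "neither")
  expect_false(strict$pass[3] && out$L2[3] < 0.2)

  # a zero level gives infinite fold change and can still pass
  wz <- w[1, ]
  wz$mC2 <- 0L; wz$uC2 <- 48L
  wz$L2 <- 0; wz$L1 <- 0.6
  outz <- test_windows(wz)
  expect_equal(outz$fold_change, Inf)
  expect_true(outz$pass)
})

test_that("interdependent regions merge; independent ones stay apart", {
  # a continuous run of 10 strongly differential CpGs collapses into a
  # single region pooling 80/20 vs 20/80
  pos <- seq(0, 90, by = 10)
  m1 <- toy_methylome("chr1", pos, "+", "CpG", rep(8, 10), rep(2, 10))
  m2 <- toy_methylome("chr1", pos, "+", "CpG", rep(2, 10), rep(8, 10))
  dm <- call_dmrs(m1, m2, max_gap = 500)
  expect_equal(nrow(dm), 1L)
  expect_equal(dm$n_sites, 10L)
  expect_equal(dm$mC1, 80L)
  expect_equal(dm$uC2, 80L)
  expect_gt(length(strsplit(dm$merged_from, ",")[[1]]), 1L)

  # two differential clusters separated by non-differential sites: when the
  # putative regions end up within max_gap, the spanning region (including
  # the null sites) still shows a 2-fold difference and the pair merges
  two_cluster <- function(null_pos) {
    pos2 <- c(seq(0, 40, by = 10), null_pos,
              seq(max(null_pos) + 130, by = 10, length.out = 5))
    n <- length(pos2)
    strong <- c(rep(TRUE, 5), rep(FALSE, length(null_pos)), rep(TRUE, 5))
    list(m1 = toy_methylome("chr1", pos2, "+", "CpG",
                            ifelse(strong, 8, 5), ifelse(strong, 2, 5)),
         m2 = toy_methylome("chr1", pos2, "+", "CpG",
                            ifelse(strong, 2, 5), ifelse(strong, 8, 5)))
  }
  near <- two_cluster(seq(60, 110, by = 10))
  dmn <- call_dmrs(near$m1, near$m2, max_gap = 500)
  expect_equal(nrow(dmn), 1L)
  expect_equal(dmn$n_sites, 16L)

  # with the null sites spread over 2 kb the putative regions sit farther
  # apart than max_gap and are reported as independent DMRs
  far <- two_cluster(seq(240, 2040, by = 200))
  dmf <- call_dmrs(far$m1, far$m2, max_gap = 500)
  expect_equal(nrow(dmf), 2L)

  # a single putative window is returned unchanged
  m1s <- toy_methylome("chr1", pos[1:5], "+", "CpG", rep(8, 5), rep(2, 5))
  m2s <- toy_methylome("chr1", pos[1:5], "+", "CpG", rep(2, 5), rep(8, 5))
  dms <- call_dmrs(m1s, m2s)
  expect_equal(nrow(dms), 1L)
  expect_equal(dms$n_sites, 5L)
})

test_that("merge_dmrs joins a pair only when the spanning region passes", {
  # region 1: 0.8 vs 0.2 (strongly differential); region 2: 0.3 vs 0.45
  mk_sites <- function() tibble::tibble(
    chrom = "chr1", pos = as.integer(c(seq(0, 40, 10), seq(100, 140, 10))),
    strand = "+",
    mC1 = as.integer(c(rep(8, 5), rep(3, 5))),
    uC1 = as.integer(c(rep(2, 5), rep(7, 5))),
    mC2 = as.integer(c(rep(2, 5), rep(5, 5))),
    uC2 = as.integer(c(rep(8, 5), rep(6, 5))))
  sites <- mk_sites()
  regs <- tibble::tibble(chrom = "chr1", site_from = c(1L, 6L),
                         site_to = c(5L, 10L),
                         merged_from = list("w1", "w2"))
  # spanning pool: L1 = 55/100, L2 = 35/110 -> fold 1.73 < 2: no merge
  out <- merge_dmrs(regs, sites, max_gap = 500)
  expect_equal(nrow(out), 2L)
  expect_equal(out$site_to, c(5L, 10L))

  # a single putative region passes through unchanged
  one <- merge_dmrs(regs[1, ], sites, max_gap = 500)
  expect_equal(nrow(one), 1L)
  expect_equal(one$site_from, 1L)

  # make region 2 equally differential: the span passes and the pair merges
  sites2 <- mk_sites()
  sites2$mC1[6:10] <- 8L; sites2$uC1[6:10] <- 2L
  sites2$mC2[6:10] <- 2L; sites2$uC2[6:10] <- 8L
  merged <- merge_dmrs(regs, sites2, max_gap = 500)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$site_from, 1L)
  expect_equal(merged$site_to, 10L)
  expect_equal(merged$merged_from[[1]], c("w1", "w2"))
  # beyond max_gap the same pair is left alone
  expect_equal(nrow(merge_dmrs(regs, sites2, max_gap = 50)), 2L)
})

test_that("identical samples yield no DMRs", {
  cmpx <- sim_comparison(seed = 81, n_truth = 0)
  expect_equal(nrow(call_dmrs(cmpx$m1, cmpx$m1)), 0L)
})

test_that("implanted truth DMRs are recovered at their loci", {
  cmpx <- sim_comparison(seed = 91, n_truth = 2, depth = 30)
  dm <- call_dmrs(cmpx$m1, cmpx$m2)
  expect_equal(nrow(dm), 2L)
  for (i in seq_len(nrow(cmpx$truth))) {
    hit <- dm$start < cmpx$truth$end[i] & dm$end > cmpx$truth$start[i]
    expect_true(any(hit))
  }
})

test_that("every reported DMR satisfies the criteria and pairs are independent", {
  cmpx <- sim_comparison(seed = 101, n_truth = 3, depth = 25)
  dm <- call_dmrs(cmpx$m1, cmpx$m2)
  expect_gt(nrow(dm), 0L)
  # post-merge re-check on each region's own pooled counts
  expect_true(all(dm$fold_change >= 2))
  expect_true(all(dm$fisher_p < 0.05))
  expect_true(all(pmax(dm$L1, dm$L2) >= 0.2))
  expect_true(all(dm$n_sites >= 5))
  expect_equal(dm$fisher_p,
               fisher_exact_two_sided(dm$mC1, dm$uC1, dm$mC2, dm$uC2))
  # adjacent reported pairs within max_gap must fail the spanning test
  sites <- attr(dm, "sites")
  if (nrow(dm) > 1) {
    for (i in seq_len(nrow(dm) - 1)) {
      if (dm$chrom[i] != dm$chrom[i + 1]) next
      if (dm$start[i + 1] - dm$end[i] > 500) next
      span <- sites$pos >= dm$start[i] & sites$pos < dm$end[i + 1] &
        sites$chrom == dm$chrom[i]
      a <- sum(sites$mC1[span]); b <- sum(sites$uC1[span])
      c <- sum(sites$mC2[span]); d <- sum(sites$uC2[span])
      L1 <- a / (a + b); L2 <- c / (c + d)
      fold <- if (L1 == L2) 1 else if (min(L1, L2) == 0) Inf
              else max(L1, L2) / min(L1, L2)
      ok <- fold >= 2 && enum_fisher(a, b, c, d) < 0.05 && max(L1, L2) >= 0.2
      expect_false(ok)
    }
  }
})

test_that("merging reaches the same fixpoint from either sweep direction", {
  for (s in c(111, 112, 113)) {
    cmpx <- sim_comparison(seed = s, n_truth = 3, depth = 20)
    w <- scan_windows(cmpx$m1, cmpx$m2)
    sites <- attr(w, "sites")
    w <- test_windows(w)
    passing <- w[w$pass, ]
    if (nrow(passing) == 0) next
    regs <- rrbsdmr:::.collapse_windows(passing, sites, 2, 0.05, 0.2,
                                        "not_both")
    ltr <- merge_dmrs(regs, sites, sweep = "ltr")
    rtl <- merge_dmrs(regs, sites, sweep = "rtl")
    expect_equal(ltr[, c("chrom", "site_from", "site_to")],
                 rtl[, c("chrom", "site_from", "site_to")])
  }
})

test_that("caller and brute-force enumerator agree on full comparisons", {
  for (s in c(121, 122)) {
    cmpx <- sim_comparison(seed = s, n_truth = 2, depth = 20)
    dm <- call_dmrs(cmpx$m1, cmpx$m2)
    ref <- call_dmrs_reference(cmpx$m1, cmpx$m2)
    expect_equal(nrow(dm), nrow(ref))
    expect_equal(dm$start, ref$start)
    expect_equal(dm$end, ref$end)
    expect_equal(dm$n_sites, ref$n_sites)
    expect_equal(dm$fisher_p, ref$fisher_p, tolerance = 1e-9)
  }
})

test_that("DMR BED export carries capped -log10 p scores", {
  pos <- seq(0, 40, by = 10)
  m1 <- toy_methylome("chr1", pos, "+", "CpG", rep(40, 5), rep(2, 5))
  m2 <- toy_methylome("chr1", pos, "+", "CpG", rep(2, 5), rep(40, 5))
  dm <- call_dmrs(m1, m2)
  f <- tempfile(fileext = ".bed")
  export_dmrs_bed(dm, f)
  bed <- read.table(f, sep = "\t")
  expect_equal(nrow(bed), 1L)
  expect_equal(bed$V2, dm$start)   # BED keeps 0-based starts
  expect_equal(bed$V3, dm$end)
  expect_lte(bed$V5, 100)
})
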