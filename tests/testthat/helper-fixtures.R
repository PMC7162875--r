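# Shared fixtures and independent oracles used across test files.

# build a ref_genome by hand from named chromosome strings
toy_genome <- function(chromosomes, features = NULL) {
  if (is.null(features)) {
    features <- tibble::tibble(chrom = character(), start = integer(),
                               end = integer(), kind = character(),
                               id = character(), strand = character())
  }
  structure(list(chromosomes = chromosomes, features = features),
            class = "ref_genome")
}

# build a methylome tibble by hand; level derived from the counts
toy_methylome <- function(chrom, pos, strand, context, mC, uC,
                          sample = "toy") {
  out <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                        strand = strand, context = context,
                        mC = as.integer(mC), uC = as.integer(uC))
  out$level <- out$mC / (out$mC + out$uC)
  out <- dplyr::arrange(out, chrom, pos, strand)
  attr(out, "sample") <- sample
  out
}

# enumeration oracle for the two-sided Fisher exact test, written directly
# from the hypergeometric definition with lchoose (independent of dhyper)
enum_fisher <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  if (n1 + n2 == 0 || k == 0 || k == n1 + n2 || n1 == 0 || n2 == 0) return(1)
  xs <- max(0, k - n2):min(k, n1)
  lp <- lchoose(n1, xs) + lchoose(n2, k - xs) - lchoose(n1 + n2, k)
  pobs <- lchoose(n1, a) + lchoose(n2, c) - lchoose(n1 + n2, k)
  min(1, sum(exp(lp[lp <= pobs + log1p(1e-7)])))
}

# enumeration oracle for the upper hypergeometric tail used in enrichment
enum_hyper_tail <- function(overlap, term_size, bg_size, query_size) {
  xs <- overlap:min(term_size, query_size)
  sum(exp(lchoose(term_size, xs) +
            lchoose(bg_size - term_size, query_size - xs) -
            lchoose(bg_size, query_size)))
}

# count CCGG occurrences in a chromosome string
count_ccgg <- function(seq) {
  m <- gregexpr("(?=CCGG)", seq, perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

# a small two-arm comparison on count-simulated methylomes
sim_comparison <- function(chrom_length = 30000, n_truth = 2, depth = 25,
                           seed = 1, level_hi = 0.9, level_lo = 0.1) {
  g <- generate_genome(1, chrom_length, 0.5, 2, 6, n_truth_dmrs = n_truth,
                       seed = seed)
  ids <- genome_features(g, "truth_dmr")$id
  spec <- stats::setNames(
    rep(list(c(medium = level_hi, pVC = level_lo)), length(ids)), ids)
  p1 <- assign_profile(g, "medium", 0.75, 0.01, spec, seed = seed + 1000L)
  p2 <- assign_profile(g, "pVC", 0.75, 0.01, spec, seed = seed + 2000L)
  m1 <- simulate_methylome(p1, depth, sample = "medium", seed = seed + 3000L)
  m2 <- simulate_methylome(p2, depth, sample = "pVC", seed = seed + 4000L)
  list(genome = g, m1 = m1, m2 = m2,
       truth = genome_features(g, "truth_dmr"))
}
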