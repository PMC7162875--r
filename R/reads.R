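# Directional bisulfite read simulation from size-selected MspI fragments.

.other_bases <- matrix(c("C", "G", "T",
                         "A", "G", "T",
                         "A", "C", "T",
                         "A", "C", "G"), nrow = 3)
colnames(.other_bases) <- c("A", "C", "G", "T")

#' Simulate directional bisulfite reads
#'
#' Draws single-end reads from the 5' ends of the original-top (OT) and
#' original-bottom (OB) strands of retained fragments.  Each cytosine on the
#' read's strand is emitted as C with probability
#' `true_level + (1 - true_level) * (1 - conversion_rate)` and as T
#' otherwise; independent substitution errors (to one of the three other
#' bases) are applied at `error_rate`.  Retained fragments shorter than the
#' read length are not sequenced, keeping the read length constant within a
#' run; their count is recorded in the `n_fragments_skipped` attribute.
#'
#' @param genome A `ref_genome`.
#' @param fragments Size-selected fragments, as from [size_select()].
#' @param profile Truth profile from [assign_profile()] for the arm being
#'   sequenced.
#' @param read_length Read length in bp (default 50).
#' @param mean_depth Target mean coverage over sequenced fragment bases.
#' @param conversion_rate Bisulfite conversion rate in `[0, 1]`.
#' @param error_rate Per-base substitution error rate in `[0, 1]`.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return Tibble (id, seq, chrom, start, lib) where `start` is the 0-based
#'   leftmost reference coordinate of the read and `lib` is `"OT"` or
#'   `"OB"`.  The id encodes the true origin as `name|chrom|start|lib`.
#' @export
simulate_reads <- function(genome, fragments, profile, read_length = 50,
                           mean_depth = 10, conversion_rate = 0.995,
                           error_rate = 0.001, seed = 1) {
  check_unit_interval(conversion_rate, "conversion_rate")
  check_unit_interval(error_rate, "error_rate")
  read_length <- check_positive_int(read_length, "read_length")
  if (nrow(fragments) == 0 || read_length > max(fragments$length)) {
    abort("`read_length` exceeds the longest retained fragment")
  }

  keep <- fragments$length >= read_length
  n_skipped <- sum(!keep)
  frg <- fragments[keep, ]

  # per-chromosome lookup of true levels by strand
  lev <- list()
  for (cn in names(genome$chromosomes)) {
    L <- nchar(genome$chromosomes[[cn]])
    lp <- rep(NA_real_, L); lm <- rep(NA_real_, L)
    pc <- profile[profile$chrom == cn, ]
    lp[pc$pos[pc$strand == "+"] + 1L] <- pc$true_level[pc$strand == "+"]
    lm[pc$pos[pc$strand == "-"] + 1L] <- pc$true_level[pc$strand == "-"]
    lev[[cn]] <- list(p = lp, m = lm)
  }

  chars <- lapply(genome$chromosomes,
                  function(s) strsplit(s, "", fixed = TRUE)[[1]])

  withr::with_seed(seed, {
    out <- vector("list", 2L * nrow(frg))
    counter <- 0L
    for (fi in seq_len(nrow(frg))) {
      cn <- frg$chrom[fi]
      ch <- chars[[cn]]
      flen <- frg$length[fi]
      lambda <- mean_depth * flen / read_length / 2
      for (ori in c("OT", "OB")) {
        n <- rpois(1, lambda)
        if (n == 0) next
        if (ori == "OT") {
          idx <- (frg$start[fi] + 1L):(frg$start[fi] + read_length)
          template <- ch[idx]
          cpos <- which(template == "C")
          p_meth <- lev[[cn]]$p[idx[cpos]]
        } else {
          idx <- (frg$end[fi] - read_length + 1L):frg$end[fi]
          template <- unname(.COMP[ch[idx]])   # bottom strand, 3'->5' layout
          cpos <- which(template == "C")       # top-strand G positions
          p_meth <- lev[[cn]]$m[idx[cpos]]
        }
        p_obs <- p_meth + (1 - p_meth) * (1 - conversion_rate)
        mat <- matrix(template, nrow = read_length, ncol = n)
        if (length(cpos)) {
          draw <- matrix(runif(length(cpos) * n) < p_obs,
                         nrow = length(cpos), ncol = n)
          mat[cpos, ] <- ifelse(draw, "C", "T")
        }
        if (ori == "OB") mat <- mat[rev(seq_len(read_length)), , drop = FALSE]
        if (error_rate > 0) {
          err <- which(runif(read_length * n) < error_rate)
          if (length(err)) {
            mat[err] <- .other_bases[cbind(sample.int(3L, length(err),
                                                      replace = TRUE),
                                           match(mat[err],
                                                 colnames(.other_bases)))]
          }
        }
        counter <- counter + 1L
        out[[counter]] <- tibble(
          seq = apply(mat, 2, paste, collapse = ""),
          chrom = cn, start = idx[1L] - 1L, lib = ori)
      }
    }
    reads <- bind_rows(out[seq_len(counter)])
    if (nrow(reads)) {
      reads$id <- sprintf("read%06d|%s|%d|%s", seq_len(nrow(reads)),
                          reads$chrom, reads$start, reads$lib)
      reads <- reads[, c("id", "seq", "chrom", "start", "lib")]
    } else {
      reads <- tibble(id = character(), seq = character(), chrom = character(),
                      start = integer(), lib = character())
    }
    attr(reads, "read_length") <- read_length
    attr(reads, "n_fragments_skipped") <- n_skipped
    reads
  })
}

#' Write simulated reads to FASTQ
#'
#' @param reads Tibble from [simulate_reads()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  q <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file of simulated reads
#'
#' Recovers the origin fields (`chrom`, `start`, `lib`) from read names of
#' the form `name|chrom|start|lib` when present.
#'
#' @param path FASTQ path.
#' @return Tibble (id, seq, chrom, start, lib); origin columns are `NA` for
#'   reads whose names do not carry them.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  parts <- strsplit(names(x), "|", fixed = TRUE)
  has4 <- lengths(parts) == 4L
  tibble(
    id = names(x),
    seq = unname(as.character(x)),
    chrom = ifelse(has4, vapply(parts, `[`, "", 2L), NA_character_),
    start = ifelse(has4, suppressWarnings(
      as.integer(vapply(parts, `[`, "", 3L))), NA_integer_),
    lib = ifelse(has4, vapply(parts, `[`, "", 4L), NA_character_))
}

#' Simulate a targeted-amplicon (pyrosequencing-style) methylation table
#'
#' Each CpG of the amplicon receives `n_reads` binomial observations at its
#' true methylation level; the observed percent is
#' `100 * n_meth / n_total`.
#'
#' @param true_levels Numeric vector of per-CpG true levels (default length 7,
#'   the TSDR assay size).
#' @param n_reads Reads per CpG.
#' @param sample Sample label.
#' @param seed Integer seed.
#' @return Tibble (cpg, true_level, n_meth, n_total, percent) with attribute
#'   `sample`.
#' @export
simulate_amplicon <- function(true_levels, n_reads = 1000, sample = "sample",
                              seed = 1) {
  if (any(true_levels < 0 | true_levels > 1)) {
    abort("`true_levels` must lie in [0, 1]")
  }
  n_reads <- check_positive_int(n_reads, "n_reads")
  withr::with_seed(seed, {
    k <- length(true_levels)
    m <- rbinom(k, n_reads, true_levels)
    out <- tibble(cpg = seq_len(k), true_level = true_levels,
                  n_meth = m, n_total = n_reads,
                  percent = 100 * m / n_reads)
    attr(out, "sample") <- sample
    out
  })
}

#' Simulate a suppression-assay cytometry event table
#'
#' Emits one row per acquired event with a role label (`gd` for
#' FITC-gated gamma/delta T cells, `cd4` for PE-gated CD4 responder cells,
#' `standard` for the spiked-in APC-labelled standard cells) and a CFSE
#' intensity for CD4 events that halves per division with lognormal spread.
#' Standard events are emitted exactly `n_standard_added` times; an optional
#' uniform subsampling of all event classes models partial acquisition.
#'
#' @param true_counts Named vector of true viable cell counts, e.g.
#'   `c(gd = 20000, cd4 = 20000)`.
#' @param n_standard_added Number of standard cells spiked in (> 0).
#' @param cfse_generations Probability vector over divisions 0, 1, 2, ... for
#'   CD4 events (normalised internally).
#' @param cfse_peak Undivided (generation 0) CFSE intensity.
#' @param cfse_cv Lognormal spread of intensities around each generation mode.
#' @param subsample_fraction Probability that any event is acquired.
#' @param seed Integer seed.
#' @return Tibble (role, viable, generation, cfse) with attribute
#'   `n_standard_added`.
#' @export
simulate_suppression_assay <- function(true_counts, n_standard_added = 10000,
                                       cfse_generations = c(1),
                                       cfse_peak = 10000, cfse_cv = 0.15,
                                       subsample_fraction = 1, seed = 1) {
  if (any(true_counts < 0)) abort("`true_counts` must be >= 0")
  n_standard_added <- check_positive_int(n_standard_added, "n_standard_added")
  check_unit_interval(subsample_fraction, "subsample_fraction")
  pr <- cfse_generations / sum(cfse_generations)
  withr::with_seed(seed, {
    rows <- list()
    for (role in names(true_counts)) {
      n <- as.integer(true_counts[[role]])
      if (n == 0) next
      if (role == "cd4") {
        gen <- sample(seq_along(pr) - 1L, n, replace = TRUE, prob = pr)
        cfse <- cfse_peak / 2^gen * exp(rnorm(n, 0, cfse_cv))
      } else {
        gen <- rep(NA_integer_, n); cfse <- rep(NA_real_, n)
      }
      rows[[role]] <- tibble(role = role, viable = TRUE,
                             generation = gen, cfse = cfse)
    }
    rows$standard <- tibble(role = "standard", viable = TRUE,
                            generation = NA_integer_, cfse = NA_real_)[
                              rep(1, n_standard_added), ]
    ev <- bind_rows(rows)
    if (subsample_fraction < 1) {
      ev <- ev[runif(nrow(ev)) < subsample_fraction, ]
    }
    attr(ev, "n_standard_added") <- n_standard_added
    ev
  })
}
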