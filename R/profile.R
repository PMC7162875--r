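# Ground-truth methylation profiles for the four culture arms.

# Vectorised cytosine enumeration with context classification for one
# chromosome sequence.  Context is strand-aware: CpG when the next base
# (5'->3' on the cytosine's strand) is G, CHG when the base after next is G,
# CHH otherwise; cytosines whose context is truncated by the chromosome end
# fall back to CHH.
cytosine_contexts <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  pos_p <- which(ch == "C")
  nxt1 <- ch[pos_p + 1L]                       # NA past the end
  nxt2 <- ch[pos_p + 2L]
  ctx_p <- ifelse(!is.na(nxt1) & nxt1 == "G", "CpG",
           ifelse(!is.na(nxt2) & nxt2 == "G", "CHG", "CHH"))
  pos_m <- which(ch == "G")
  prv1 <- ifelse(pos_m - 1L >= 1L, ch[pmax(pos_m - 1L, 1L)], NA)
  prv2 <- ifelse(pos_m - 2L >= 1L, ch[pmax(pos_m - 2L, 1L)], NA)
  ctx_m <- ifelse(!is.na(prv1) & prv1 == "C", "CpG",
           ifelse(!is.na(prv2) & prv2 == "C", "CHG", "CHH"))
  out <- tibble(
    pos = c(pos_p, pos_m) - 1L,
    strand = rep(c("+", "-"), c(length(pos_p), length(pos_m))),
    context = c(ctx_p, ctx_m))
  arrange(out, .data$pos, .data$strand)
}

#' Classify the sequence context of a cytosine
#'
#' @param genome A `ref_genome`.
#' @param chrom Chromosome name.
#' @param pos 0-based position of the cytosine.
#' @param strand `"+"` or `"-"`; the reference base must be C on that strand
#'   (i.e. C on the top strand for `"+"`, G for `"-"`).
#' @return One of `"CpG"`, `"CHG"`, `"CHH"`.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  seq <- genome$chromosomes[[chrom]]
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  base <- ch[pos + 1L]
  if (strand == "+" && !identical(base, "C")) {
    abort(sprintf("position %d (+) is %s, not a cytosine", pos, base))
  }
  if (strand == "-" && !identical(base, "G")) {
    abort(sprintf("position %d (-) is %s, not a cytosine", pos, base))
  }
  L <- length(ch)
  if (strand == "+") {
    n1 <- if (pos + 2L <= L) ch[pos + 2L] else NA
    n2 <- if (pos + 3L <= L) ch[pos + 3L] else NA
  } else {
    n1 <- if (pos >= 1L) ch[pos] else NA
    n2 <- if (pos >= 2L) ch[pos - 1L] else NA
    n1 <- if (is.na(n1)) NA else unname(.COMP[n1])
    n2 <- if (is.na(n2)) NA else unname(.COMP[n2])
  }
  if (!is.na(n1) && n1 == "G") return("CpG")
  if (!is.na(n2) && n2 == "G") return("CHG")
  "CHH"
}

#' Assign a ground-truth methylation profile for one culture condition
#'
#' Every cytosine on both strands receives a true methylation level: a
#' context-dependent background (CpG vs non-CpG) with bounded jitter outside
#' any listed feature, and an exact condition-specific level at CpG cytosines
#' inside the features named in `dmr_spec`.  The jitter SD shrinks near the
#' 0/1 bounds so that the mean background level equals the requested base
#' level; `jitter_sd = 0` gives a fully deterministic profile.
#'
#' @param genome A `ref_genome`.
#' @param condition One of `"medium"`, `"pVC"`, `"TGFb"`, `"TGFb_pVC"`.
#' @param base_cg_level Background true level for CpG cytosines.
#' @param base_noncg_level Background true level for CHG/CHH cytosines.
#' @param dmr_spec Named list: feature id -> named numeric vector of
#'   per-condition levels, e.g. `list(tsdr = c(TGFb = 0.9, TGFb_pVC = 0.1))`.
#'   Conditions absent from a vector fall back to background behaviour.
#' @param jitter_sd Background jitter SD (truncated at 2 SD).
#' @param seed Integer seed.
#' @return Tibble (chrom, pos, strand, context, true_level) with attributes
#'   `condition` and `seed`.
#' @export
assign_profile <- function(genome, condition, base_cg_level = 0.75,
                           base_noncg_level = 0.01, dmr_spec = list(),
                           jitter_sd = 0.05, seed = 1) {
  if (!condition %in% ARM_LABELS) {
    abort(sprintf("unknown condition '%s'; expected one of %s",
                  condition, paste(ARM_LABELS, collapse = ", ")))
  }
  check_unit_interval(base_cg_level, "base_cg_level")
  check_unit_interval(base_noncg_level, "base_noncg_level")
  if (length(dmr_spec)) {
    missing <- setdiff(names(dmr_spec), genome$features$id)
    if (length(missing)) {
      abort(paste("unknown feature id(s) in dmr_spec:",
                  paste(missing, collapse = ", ")))
    }
  }

  withr::with_seed(seed, {
    prof <- lapply(names(genome$chromosomes), function(cn) {
      ctx <- cytosine_contexts(genome$chromosomes[[cn]])
      base <- ifelse(ctx$context == "CpG", base_cg_level, base_noncg_level)
      if (jitter_sd > 0) {
        # shrink the SD near the bounds so clipping does not bias the mean
        sd_eff <- pmin(jitter_sd, base / 2, (1 - base) / 2)
        j <- rnorm(nrow(ctx), 0, 1) * sd_eff
        j <- pmax(pmin(j, 2 * sd_eff), -2 * sd_eff)
        lev <- clip01(base + j)
      } else {
        lev <- base
      }
      tibble(chrom = cn, pos = ctx$pos, strand = ctx$strand,
             context = ctx$context, true_level = lev)
    })
    prof <- bind_rows(prof)

    for (fid in names(dmr_spec)) {
      levels <- dmr_spec[[fid]]
      if (!condition %in% names(levels)) next
      frow <- genome$features[genome$features$id == fid, ][1, ]
      sel <- prof$chrom == frow$chrom & prof$pos >= frow$start &
        prof$pos < frow$end & prof$context == "CpG"
      prof$true_level[sel] <- check_unit_interval(
        unname(levels[[condition]]), paste0("dmr_spec$", fid))
    }

    attr(prof, "condition") <- condition
    attr(prof, "seed") <- seed
    prof
  })
}

#' Simulate a methylome count table directly from a truth profile
#'
#' Draws per-site sequencing coverage from a Poisson distribution and
#' methylated counts from a binomial at the (conversion-adjusted) true level,
#' skipping the read level entirely.  This is the fast generator used for
#' DMR-scale experiments; `simulate_reads()` + `place_reads()` +
#' `call_cytosines()` exercise the full read path.
#'
#' @param profile Output of [assign_profile()].
#' @param mean_depth Mean per-site coverage (Poisson).
#' @param min_coverage Minimum coverage for a site to be reported.
#' @param conversion_rate Bisulfite conversion rate; an unmethylated cytosine
#'   is still read as C with probability `1 - conversion_rate`.
#' @param sample Sample label stored on the table.
#' @param seed Integer seed.
#' @return A methylome tibble (chrom, pos, strand, context, mC, uC, level)
#'   sorted by position, with attributes `sample` and `min_coverage`.
#' @export
simulate_methylome <- function(profile, mean_depth = 20, min_coverage = 1,
                               conversion_rate = 1, sample = "sample1",
                               seed = 1) {
  check_unit_interval(conversion_rate, "conversion_rate")
  withr::with_seed(seed, {
    n <- nrow(profile)
    cov <- rpois(n, mean_depth)
    p_obs <- profile$true_level + (1 - profile$true_level) * (1 - conversion_rate)
    mC <- rbinom(n, cov, p_obs)
    out <- tibble(chrom = profile$chrom, pos = profile$pos,
                  strand = profile$strand, context = profile$context,
                  mC = mC, uC = cov - mC)
    out <- out[cov >= max(1L, min_coverage), ]
    out$level <- out$mC / (out$mC + out$uC)
    out <- arrange(out, .data$chrom, .data$pos, .data$strand)
    attr(out, "sample") <- sample
    attr(out, "min_coverage") <- min_coverage
    out
  })
}
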