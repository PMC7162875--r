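# Sliding-window DMR discovery with pooled Fisher testing, fold-change and
# hypomethylation filters, and iterative merging of interdependent regions.
#
# The caller compares two single methylomes (no replicates, no dispersion
# model, no multiple-testing correction).  Windows are site-count windows of
# exactly `min_sites` consecutive qualifying sites sliding by one site;
# overlapping passing windows are collapsed into maximal putative regions,
# which are then iteratively merged whenever the spanning region of two
# nearby regions itself satisfies all criteria on its pooled counts.

# sites of one context covered >= min_cov in BOTH samples, sorted
qualifying_sites <- function(m1, m2, context = "CpG", min_cov = 5) {
  s1 <- m1[m1$context == context & (m1$mC + m1$uC) >= min_cov,
           c("chrom", "pos", "strand", "mC", "uC")]
  s2 <- m2[m2$context == context & (m2$mC + m2$uC) >= min_cov,
           c("chrom", "pos", "strand", "mC", "uC")]
  out <- inner_join(s1, s2, by = c("chrom", "pos", "strand"),
                    suffix = c("1", "2"))
  arrange(out, .data$chrom, .data$pos, .data$strand)
}

.fold_change <- function(L1, L2) {
  ifelse(L1 == L2, 1,
         ifelse(pmin(L1, L2) == 0, Inf, pmax(L1, L2) / pmin(L1, L2)))
}

# pooled statistics over a run of qualifying sites (global row indices)
.span_stats <- function(sites, from, to) {
  idx <- from:to
  mC1 <- sum(sites$mC1[idx]); uC1 <- sum(sites$uC1[idx])
  mC2 <- sum(sites$mC2[idx]); uC2 <- sum(sites$uC2[idx])
  L1 <- mC1 / (mC1 + uC1); L2 <- mC2 / (mC2 + uC2)
  list(mC1 = mC1, uC1 = uC1, mC2 = mC2, uC2 = uC2, L1 = L1, L2 = L2,
       fold_change = .fold_change(L1, L2),
       fisher_p = .fisher1(mC1, uC1, mC2, uC2))
}

.passes <- function(fold_change, fisher_p, L1, L2, fold_min, p_max,
                    hypo_threshold, hypo_rule) {
  hypo_ok <- if (hypo_rule == "neither") pmin(L1, L2) >= hypo_threshold
             else pmax(L1, L2) >= hypo_threshold
  fold_change >= fold_min & fisher_p < p_max & hypo_ok
}

#' Enumerate candidate DMR windows
#'
#' Sites of the requested context covered at least `min_cov`-fold in both
#' samples are sorted by position; every run of exactly `min_sites`
#' consecutive such sites on one chromosome yields one candidate window with
#' counts pooled over its member sites.
#'
#' @param m1,m2 Methylome tibbles for the two samples.
#' @param context Sequence context class (`"CpG"`, `"CHG"` or `"CHH"`).
#' @param min_sites Window size in sites (default 5).
#' @param min_cov Minimum coverage per site in each sample (default 5).
#' @return Tibble of windows (chrom, start, end, site_from, site_to,
#'   n_sites, pooled counts, L1, L2) with the qualifying site table in the
#'   `sites` attribute.
#' @export
scan_windows <- function(m1, m2, context = "CpG", min_sites = 5, min_cov = 5) {
  min_sites <- check_positive_int(min_sites, "min_sites")
  sites <- qualifying_sites(m1, m2, context, min_cov)
  wins <- list()
  offset <- 0L
  for (cn in unique(sites$chrom)) {
    sc <- sites[sites$chrom == cn, ]
    n <- nrow(sc)
    if (n >= min_sites) {
      from <- seq_len(n - min_sites + 1L)
      to <- from + min_sites - 1L
      csum <- function(x) { cs <- c(0, cumsum(x)); cs[to + 1L] - cs[from] }
      mC1 <- csum(sc$mC1); uC1 <- csum(sc$uC1)
      mC2 <- csum(sc$mC2); uC2 <- csum(sc$uC2)
      wins[[cn]] <- tibble(
        chrom = cn, start = sc$pos[from], end = sc$pos[to] + 1L,
        site_from = from + offset, site_to = to + offset,
        n_sites = min_sites,
        mC1 = mC1, uC1 = uC1, mC2 = mC2, uC2 = uC2,
        L1 = mC1 / (mC1 + uC1), L2 = mC2 / (mC2 + uC2))
    }
    offset <- offset + n
  }
  out <- bind_rows(wins)
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  site_from = integer(), site_to = integer(),
                  n_sites = integer(), mC1 = integer(), uC1 = integer(),
                  mC2 = integer(), uC2 = integer(),
                  L1 = numeric(), L2 = numeric())
  }
  out$window_id <- if (nrow(out)) sprintf("win_%d", seq_len(nrow(out)))
                   else character()
  attr(out, "sites") <- sites
  attr(out, "context") <- context
  out
}

#' Apply the DMR criteria to candidate windows
#'
#' A window passes when its pooled fold change is at least `fold_min`, its
#' two-sided Fisher p value is below `p_max`, and the samples are not both
#' hypomethylated.  The default hypomethylation rule (`"not_both"`) requires
#' `max(L1, L2) >= hypo_threshold`; `"neither"` requires both samples to
#' clear the threshold.  A window in which one pooled level is exactly zero
#' has infinite fold change and passes the fold criterion.
#'
#' @param windows Tibble from [scan_windows()].
#' @param fold_min Minimum pooled fold change (default 2).
#' @param p_max Fisher p-value threshold (default 0.05).
#' @param hypo_threshold Pooled level below which a sample counts as
#'   hypomethylated (default 0.2).
#' @param hypo_rule `"not_both"` (default) or `"neither"`.
#' @return `windows` with added columns fold_change, fisher_p, pass.
#' @export
test_windows <- function(windows, fold_min = 2, p_max = 0.05,
                         hypo_threshold = 0.2,
                         hypo_rule = c("not_both", "neither")) {
  hypo_rule <- match.arg(hypo_rule)
  windows$fold_change <- .fold_change(windows$L1, windows$L2)
  windows$fisher_p <- fisher_exact_two_sided(windows$mC1, windows$uC1,
                                             windows$mC2, windows$uC2)
  windows$pass <- .passes(windows$fold_change, windows$fisher_p,
                          windows$L1, windows$L2, fold_min, p_max,
                          hypo_threshold, hypo_rule)
  windows
}

# collapse overlapping passing windows into maximal putative regions,
# re-testing each region on its own pooled counts
.collapse_windows <- function(passing, sites, fold_min, p_max,
                              hypo_threshold, hypo_rule) {
  regs <- list()
  for (cn in unique(passing$chrom)) {
    wc <- passing[passing$chrom == cn, ]
    wc <- wc[order(wc$start), ]
    grp <- cumsum(c(1L, as.integer(wc$start[-1] >= cummax(wc$end)[-nrow(wc)])))
    for (g in unique(grp)) {
      sel <- grp == g
      regs[[length(regs) + 1L]] <- tibble(
        chrom = cn,
        site_from = min(wc$site_from[sel]),
        site_to = max(wc$site_to[sel]),
        merged_from = list(wc$window_id[sel]))
    }
  }
  regs <- bind_rows(regs)
  keep <- logical(nrow(regs))
  stats <- vector("list", nrow(regs))
  for (i in seq_len(nrow(regs))) {
    st <- .span_stats(sites, regs$site_from[i], regs$site_to[i])
    keep[i] <- .passes(st$fold_change, st$fisher_p, st$L1, st$L2,
                       fold_min, p_max, hypo_threshold, hypo_rule)
    stats[[i]] <- st
  }
  regs <- regs[keep, ]
  regs$stats <- stats[keep]
  regs
}

.finalize_dmrs <- function(regs, sites, context) {
  if (nrow(regs) == 0) {
    return(tibble(dmr_id = character(), chrom = character(),
                  start = integer(), end = integer(), context = character(),
                  n_sites = integer(), mC1 = integer(), uC1 = integer(),
                  mC2 = integer(), uC2 = integer(), L1 = numeric(),
                  L2 = numeric(), fold_change = numeric(),
                  fisher_p = numeric(), merged_from = character()))
  }
  st <- bind_rows(lapply(regs$stats, as_tibble))
  tibble(
    dmr_id = sprintf("DMR_%03d", seq_len(nrow(regs))),
    chrom = regs$chrom,
    start = sites$pos[regs$site_from],
    end = sites$pos[regs$site_to] + 1L,
    context = context,
    n_sites = regs$site_to - regs$site_from + 1L,
    mC1 = st$mC1, uC1 = st$uC1, mC2 = st$mC2, uC2 = st$uC2,
    L1 = st$L1, L2 = st$L2,
    fold_change = st$fold_change, fisher_p = st$fisher_p,
    merged_from = vapply(regs$merged_from, paste, "", collapse = ","))
}

#' Iteratively merge interdependent DMRs
#'
#' Two nearby putative DMRs on the same chromosome (gap at most `max_gap`
#' bp) are interdependent when the spanning region from the start of the
#' upstream DMR to the end of the downstream DMR -- pooled over *all*
#' qualifying sites inside it -- itself satisfies the fold-change, Fisher and
#' hypomethylation criteria; such pairs are replaced by the spanning region.
#' Sweeps repeat until a full pass makes no merge, so the final regions are
#' pairwise independent.
#'
#' @param putative Region tibble with columns chrom, site_from, site_to,
#'   merged_from (as produced internally by [call_dmrs()]), sorted by
#'   position.
#' @param sites Qualifying-site table (the `sites` attribute of
#'   [scan_windows()]).
#' @param max_gap Maximum gap in bp between mergeable regions (default 500).
#' @param fold_min,p_max,hypo_threshold,hypo_rule Criteria, as in
#'   [test_windows()].
#' @param sweep Sweep direction, `"ltr"` (default) or `"rtl"`; the fixpoint
#'   does not depend on it.
#' @return Region tibble after merging, with a `stats` list column.
#' @export
merge_dmrs <- function(putative, sites, max_gap = 500, fold_min = 2,
                       p_max = 0.05, hypo_threshold = 0.2,
                       hypo_rule = c("not_both", "neither"),
                       sweep = c("ltr", "rtl")) {
  hypo_rule <- match.arg(hypo_rule)
  sweep <- match.arg(sweep)
  regs <- putative
  if (!"stats" %in% names(regs)) {
    regs$stats <- lapply(seq_len(nrow(regs)), function(i) {
      .span_stats(sites, regs$site_from[i], regs$site_to[i])
    })
  }
  if (nrow(regs) <= 1) return(regs)
  repeat {
    merged <- FALSE
    ord <- if (sweep == "ltr") seq_len(nrow(regs) - 1L)
           else rev(seq_len(nrow(regs) - 1L))
    i <- 1L
    while (i <= length(ord)) {
      a <- ord[i]
      if (a + 1L > nrow(regs)) { i <- i + 1L; next }
      b <- a + 1L
      same_chrom <- regs$chrom[a] == regs$chrom[b]
      gap <- sites$pos[regs$site_from[b]] - (sites$pos[regs$site_to[a]] + 1L)
      if (same_chrom && gap <= max_gap) {
        st <- .span_stats(sites, regs$site_from[a], regs$site_to[b])
        if (.passes(st$fold_change, st$fisher_p, st$L1, st$L2,
                    fold_min, p_max, hypo_threshold, hypo_rule)) {
          regs$site_to[a] <- regs$site_to[b]
          regs$merged_from[[a]] <- c(regs$merged_from[[a]],
                                     regs$merged_from[[b]])
          regs$stats[[a]] <- st
          regs <- regs[-b, ]
          merged <- TRUE
          ord <- if (sweep == "ltr") seq_len(nrow(regs) - 1L)
                 else rev(seq_len(nrow(regs) - 1L))
          next
        }
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  regs
}

#' Call differentially methylated regions between two methylomes
#'
#' Composition of [scan_windows()], [test_windows()], maximal collapse of
#' overlapping passing windows (each collapsed region re-tested on its own
#' pooled counts), and [merge_dmrs()].  Every reported DMR satisfies all
#' three criteria on its pooled counts, and re-testing the span of any two
#' adjacent reported DMRs fails at least one criterion.
#'
#' @param m1,m2 Methylome tibbles for the two samples being compared.
#' @param context Sequence context class (default `"CpG"`).
#' @param min_sites Window size in qualifying sites (default 5).
#' @param min_cov Minimum per-sample site coverage (default 5).
#' @param fold_min Minimum pooled fold change (default 2).
#' @param p_max Fisher p threshold (default 0.05).
#' @param hypo_threshold Hypomethylation level threshold (default 0.2).
#' @param max_gap Maximum merge gap in bp (default 500).
#' @param hypo_rule `"not_both"` (default) or `"neither"`.
#' @return DMR tibble (dmr_id, chrom, start, end, context, n_sites, pooled
#'   counts, L1, L2, fold_change, fisher_p, merged_from) with a `report`
#'   attribute summarising the run and a `params` attribute.
#' @export
call_dmrs <- function(m1, m2, context = "CpG", min_sites = 5, min_cov = 5,
                      fold_min = 2, p_max = 0.05, hypo_threshold = 0.2,
                      max_gap = 500, hypo_rule = c("not_both", "neither")) {
  hypo_rule <- match.arg(hypo_rule)
  w <- scan_windows(m1, m2, context, min_sites, min_cov)
  sites <- attr(w, "sites")
  if (nrow(sites) == 0) {
    warn("no qualifying sites shared by the two samples")
  }
  w <- test_windows(w, fold_min, p_max, hypo_threshold, hypo_rule)
  passing <- w[w$pass, ]
  if (nrow(passing) == 0) {
    out <- .finalize_dmrs(tibble(), sites, context)
  } else {
    regs <- .collapse_windows(passing, sites, fold_min, p_max,
                              hypo_threshold, hypo_rule)
    regs <- merge_dmrs(regs, sites, max_gap, fold_min, p_max,
                       hypo_threshold, hypo_rule)
    out <- .finalize_dmrs(regs, sites, context)
  }
  attr(out, "params") <- list(context = context, min_sites = min_sites,
                              min_cov = min_cov, fold_min = fold_min,
                              p_max = p_max, hypo_threshold = hypo_threshold,
                              max_gap = max_gap, hypo_rule = hypo_rule)
  attr(out, "report") <- list(n_sites = nrow(sites), n_windows = nrow(w),
                              n_passing = nrow(passing), n_dmrs = nrow(out))
  attr(out, "sites") <- sites
  out
}

#' Export DMRs as BED6
#'
#' Scores are `-log10(p)` capped at 100.
#'
#' @param dmrs DMR tibble from [call_dmrs()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
export_dmrs_bed <- function(dmrs, path) {
  if (nrow(dmrs) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(dmrs$chrom,
                               IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  gr$name <- dmrs$dmr_id
  gr$score <- pmin(-log10(dmrs$fisher_p), 100)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
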