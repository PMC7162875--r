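# Brute-force reference implementation of the DMR definition, used as an
# independent cross-check of call_dmrs().  Deliberately written with plain
# loops, data frames and stats::fisher.test; it shares no helper with the
# production caller.

.ref_fisher <- function(a, b, c, d) {
  if (a + b + c + d == 0) return(1)
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (all(rowSums(m) > 0) || all(colSums(m) > 0)) {
    stats::fisher.test(m)$p.value
  } else {
    1
  }
}

.ref_eval <- function(df, idx, fold_min, p_max, hypo_threshold, hypo_rule) {
  a <- sum(df$mC1[idx]); b <- sum(df$uC1[idx])
  c <- sum(df$mC2[idx]); d <- sum(df$uC2[idx])
  L1 <- a / (a + b); L2 <- c / (c + d)
  if (L1 == L2) fc <- 1
  else if (min(L1, L2) == 0) fc <- Inf
  else fc <- max(L1, L2) / min(L1, L2)
  p <- .ref_fisher(a, b, c, d)
  hypo_ok <- if (hypo_rule == "neither") min(L1, L2) >= hypo_threshold
             else max(L1, L2) >= hypo_threshold
  list(pass = (fc >= fold_min) && (p < p_max) && hypo_ok,
       L1 = L1, L2 = L2, fold_change = fc, fisher_p = p,
       mC1 = a, uC1 = b, mC2 = c, uC2 = d)
}

#' Brute-force reference DMR enumerator
#'
#' Independent re-implementation of the DMR definition used by
#' [call_dmrs()]: it enumerates every window of `min_sites` consecutive
#' qualifying sites with explicit loops, evaluates each with
#' `stats::fisher.test`, collapses overlapping passing windows, and merges
#' interdependent regions by repeated full scans.  Intended as a validation
#' oracle on small genomes, not for production use.
#'
#' @inheritParams call_dmrs
#' @return Data frame (chrom, start, end, n_sites, L1, L2, fold_change,
#'   fisher_p), one row per final DMR, sorted by position.
#' @export
call_dmrs_reference <- function(m1, m2, context = "CpG", min_sites = 5,
                                min_cov = 5, fold_min = 2, p_max = 0.05,
                                hypo_threshold = 0.2, max_gap = 500,
                                hypo_rule = "not_both") {
  d1 <- as.data.frame(m1)
  d2 <- as.data.frame(m2)
  d1 <- d1[d1$context == context & (d1$mC + d1$uC) >= min_cov, ]
  d2 <- d2[d2$context == context & (d2$mC + d2$uC) >= min_cov, ]
  df <- merge(d1[, c("chrom", "pos", "strand", "mC", "uC")],
              d2[, c("chrom", "pos", "strand", "mC", "uC")],
              by = c("chrom", "pos", "strand"), suffixes = c("1", "2"))
  df <- df[order(df$chrom, df$pos, df$strand), ]
  rownames(df) <- NULL

  # pass 1: all exact min_sites windows that satisfy the criteria
  passing <- list()
  for (cn in unique(df$chrom)) {
    rows <- which(df$chrom == cn)
    n <- length(rows)
    if (n < min_sites) next
    for (i in 1:(n - min_sites + 1)) {
      idx <- rows[i:(i + min_sites - 1)]
      ev <- .ref_eval(df, idx, fold_min, p_max, hypo_threshold, hypo_rule)
      if (ev$pass) {
        passing[[length(passing) + 1]] <-
          data.frame(chrom = cn, from = idx[1], to = idx[min_sites])
      }
    }
  }
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(), L1 = numeric(),
                      L2 = numeric(), fold_change = numeric(),
                      fisher_p = numeric())
  if (!length(passing)) return(empty)
  pw <- do.call(rbind, passing)

  # pass 2: collapse genomically overlapping passing windows, re-test each
  # collapsed region on its pooled counts and drop failures
  regions <- list()
  cur <- pw[1, ]
  flush <- function(cur) {
    ev <- .ref_eval(df, cur$from:cur$to, fold_min, p_max,
                    hypo_threshold, hypo_rule)
    if (ev$pass) cur else NULL
  }
  if (nrow(pw) > 1) {
    for (i in 2:nrow(pw)) {
      same <- pw$chrom[i] == cur$chrom
      overlaps <- same && df$pos[pw$from[i]] < df$pos[cur$to] + 1
      if (overlaps) {
        cur$to <- max(cur$to, pw$to[i])
      } else {
        r <- flush(cur)
        if (!is.null(r)) regions[[length(regions) + 1]] <- r
        cur <- pw[i, ]
      }
    }
  }
  r <- flush(cur)
  if (!is.null(r)) regions[[length(regions) + 1]] <- r
  if (!length(regions)) return(empty)
  reg <- do.call(rbind, regions)

  # pass 3: iterative merging by repeated full scans (right-to-left),
  # pooling over all qualifying sites inside the span
  repeat {
    did_merge <- FALSE
    if (nrow(reg) >= 2) {
      for (i in (nrow(reg) - 1):1) {
        if (i + 1 > nrow(reg)) next
        same <- reg$chrom[i] == reg$chrom[i + 1]
        gap <- df$pos[reg$from[i + 1]] - (df$pos[reg$to[i]] + 1)
        if (same && gap <= max_gap) {
          ev <- .ref_eval(df, reg$from[i]:reg$to[i + 1], fold_min, p_max,
                          hypo_threshold, hypo_rule)
          if (ev$pass) {
            reg$to[i] <- reg$to[i + 1]
            reg <- reg[-(i + 1), ]
            did_merge <- TRUE
          }
        }
      }
    }
    if (!did_merge) break
  }

  out <- empty
  for (i in seq_len(nrow(reg))) {
    ev <- .ref_eval(df, reg$from[i]:reg$to[i], fold_min, p_max,
                    hypo_threshold, hypo_rule)
    out <- rbind(out, data.frame(
      chrom = reg$chrom[i], start = df$pos[reg$from[i]],
      end = df$pos[reg$to[i]] + 1, n_sites = reg$to[i] - reg$from[i] + 1,
      L1 = ev$L1, L2 = ev$L2, fold_change = ev$fold_change,
      fisher_p = ev$fisher_p))
  }
  out[order(out$chrom, out$start), ]
}
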