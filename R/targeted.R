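# Targeted-amplicon (TSDR-style) methylation summaries and the
# yellow -> green -> blue percent color code.

#' Summarise a targeted amplicon methylation assay
#'
#' Accepts either a per-CpG count table (columns `n_meth`, `n_total`,
#' optionally `cpg`) such as [simulate_amplicon()] returns, or a logical
#' per-read call matrix (rows = reads, columns = CpGs).  Per-CpG percent is
#' `100 * methylated / total`; the average is the unweighted mean over
#' CpGs.  A CpG with zero observations is reported as `NA` and excluded
#' from the average with a warning.
#'
#' @param x Count table or per-read logical matrix.
#' @param sample Sample label.
#' @return List (class `amplicon_methylation`) with `sample`, `percent`
#'   (per-CpG vector) and `average`.
#' @export
summarize_amplicon <- function(x, sample = NULL) {
  if (is.matrix(x)) {
    n_meth <- colSums(x)
    n_total <- rep(nrow(x), ncol(x))
  } else {
    n_meth <- x$n_meth
    n_total <- x$n_total
  }
  sample <- sample %||% attr(x, "sample") %||% "sample"
  percent <- ifelse(n_total > 0, 100 * n_meth / n_total, NA_real_)
  if (any(n_total == 0)) {
    warn(sprintf("%d CpG(s) with zero observations excluded from the average",
                 sum(n_total == 0)))
  }
  structure(list(sample = sample, percent = percent,
                 average = mean(percent, na.rm = TRUE)),
            class = "amplicon_methylation")
}

#' @export
print.amplicon_methylation <- function(x, ...) {
  cat(sprintf("<amplicon_methylation> %s: %s (average %.1f%%)\n", x$sample,
              paste(sprintf("%.1f", x$percent), collapse = ", "), x$average))
  invisible(x)
}

#' Map methylation percentages to the yellow-green-blue color code
#'
#' Piecewise-linear interpolation from yellow (255, 255, 0) at 0% through
#' green (0, 128, 0) at 50% to blue (0, 0, 255) at 100%, the conventional
#' encoding for amplicon methylation heatmaps.
#'
#' @param percent Numeric vector in `[0, 100]`.
#' @return Integer matrix with one row per input and columns R, G, B.
#' @export
heatmap_color <- function(percent) {
  if (any(is.na(percent)) || any(percent < 0 | percent > 100)) {
    abort("`percent` must lie in [0, 100]")
  }
  yellow <- c(255, 255, 0); green <- c(0, 128, 0); blue <- c(0, 0, 255)
  out <- t(vapply(percent, function(p) {
    if (p <= 50) {
      t <- p / 50
      yellow + (green - yellow) * t
    } else {
      t <- (p - 50) / 50
      green + (blue - green) * t
    }
  }, numeric(3)))
  out <- round(out)
  storage.mode(out) <- "integer"
  colnames(out) <- c("R", "G", "B")
  out
}

#' Group means and SDs of average amplicon methylation
#'
#' @param groups Named list; each element is a list of
#'   `amplicon_methylation` objects (or a numeric vector of average
#'   percents) for one sorted population / culture condition.
#' @return Tibble (group, n, mean_percent, sd_percent); the SD of a
#'   single-sample group is `NA` (undefined, not zero).  No inferential
#'   statistics are computed.
#' @export
compare_sorted_fractions <- function(groups) {
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    avgs <- if (is.numeric(x)) x
            else vapply(x, function(a) a$average, numeric(1))
    tibble(group = g, n = length(avgs), mean_percent = mean(avgs),
           sd_percent = if (length(avgs) > 1) stats::sd(avgs) else NA_real_)
  })
  bind_rows(rows)
}
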