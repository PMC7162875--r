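# Two-sided Fisher exact test on 2x2 count tables, computed in log space.
#
# The two-sided p value is the sum of hypergeometric probabilities of all
# tables sharing the observed margins whose probability does not exceed that
# of the observed table (with a relative tolerance of 1e-7 on the
# comparison, guarding against ties lost to floating point).

.fisher1 <- function(a, b, c, d) {
  n1 <- a + b
  n2 <- c + d
  k <- a + c
  if (n1 + n2 == 0L) return(1)            # all-zero table, by convention
  if (k == 0L || k == n1 + n2 || n1 == 0L || n2 == 0L) return(1)
  lo <- max(0L, k - n2)
  hi <- min(k, n1)
  lp <- dhyper(lo:hi, n1, n2, k, log = TRUE)
  lobs <- dhyper(a, n1, n2, k, log = TRUE)
  min(1, sum(exp(lp[lp <= lobs + log1p(1e-7)])))
}

#' Two-sided Fisher exact test for pooled methylation counts
#'
#' Vectorised over tables `(mC1, uC1; mC2, uC2)`.  An all-zero table returns
#' p = 1 by convention; negative counts are an error.
#'
#' @param mC1,uC1 Methylated/unmethylated counts in sample 1.
#' @param mC2,uC2 Methylated/unmethylated counts in sample 2.
#' @return Vector of two-sided p values in (0, 1].
#' @export
fisher_exact_two_sided <- function(mC1, uC1, mC2, uC2) {
  if (any(c(mC1, uC1, mC2, uC2) < 0)) abort("counts must be >= 0")
  n <- length(mC1)
  if (!all(lengths(list(uC1, mC2, uC2)) == n)) {
    abort("count vectors must have equal length")
  }
  vapply(seq_len(n), function(i) {
    .fisher1(as.integer(mC1[i]), as.integer(uC1[i]),
             as.integer(mC2[i]), as.integer(uC2[i]))
  }, numeric(1))
}
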