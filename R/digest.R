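# In silico MspI digestion and RRBS size selection.

#' Digest a genome with MspI (C^CGG)
#'
#' Cuts after the first C of every CCGG occurrence.  The fragments of each
#' chromosome partition it exactly (0-based half-open coordinates); a
#' chromosome without any CCGG yields a single fragment.
#'
#' @param genome A `ref_genome`.
#' @return Tibble (chrom, start, end, length).
#' @export
digest_mspi <- function(genome) {
  frags <- lapply(names(genome$chromosomes), function(cn) {
    seq <- genome$chromosomes[[cn]]
    L <- nchar(seq)
    m <- gregexpr("(?=CCGG)", seq, perl = TRUE)[[1]]
    cuts <- if (m[1] == -1L) integer() else as.integer(m)  # cut after first C
    bounds <- unique(c(0L, cuts, L))
    tibble(chrom = cn, start = head(bounds, -1), end = tail(bounds, -1))
  })
  out <- bind_rows(frags)
  out$length <- out$end - out$start
  out
}

#' Size-select restriction fragments
#'
#' Keeps fragments whose length lies in `[min_bp, max_bp]` (bounds
#' inclusive), mirroring gel-based 40-220 bp selection.  Order is preserved
#' and the operation is idempotent.
#'
#' @param fragments Tibble as returned by [digest_mspi()].
#' @param min_bp,max_bp Inclusive length bounds in bp.
#' @return Filtered fragment tibble.
#' @export
size_select <- function(fragments, min_bp = 40, max_bp = 220) {
  if (min_bp > max_bp) abort("`min_bp` must be <= `max_bp`")
  fragments[fragments$length >= min_bp & fragments$length <= max_bp, ]
}
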