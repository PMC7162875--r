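# Suppression-assay quantification: standard-cell dilution absolute counts,
# relative expansion quotients, and CFSE-dilution proliferating fractions.

#' Absolute cell count by standard cell dilution assay (SCDA)
#'
#' A known number of labelled, fixed standard cells is spiked into the
#' sample shortly before acquisition; the absolute number of viable target
#' cells is the target-to-standard event ratio scaled by the number of
#' standard cells added.
#'
#' @param events_target Acquired target-cell events (e.g. FITC+ gamma/delta
#'   or PE-CD4+).
#' @param events_standard Acquired standard-cell events (APC+); must be > 0.
#' @param n_standard_added Number of standard cells spiked in.
#' @return Estimated absolute viable-cell count.
#' @export
scda_count <- function(events_target, events_standard, n_standard_added) {
  if (any(events_standard <= 0)) {
    abort("`events_standard` must be > 0; the count is undefined otherwise")
  }
  if (any(events_target < 0) || any(n_standard_added <= 0)) {
    abort("`events_target` must be >= 0 and `n_standard_added` > 0")
  }
  events_target / events_standard * n_standard_added
}

#' Relative expansion quotient
#'
#' Viable-cell count of a co-culture condition divided by the count of the
#' solo-cultured responder cells, whose quotient is 1 by construction;
#' quotients below 1 indicate suppression.
#'
#' @param count_condition Viable-cell count under the condition of interest.
#' @param count_solo Viable-cell count of the solo culture (> 0).
#' @return Quotient `count_condition / count_solo`.
#' @export
relative_expansion <- function(count_condition, count_solo) {
  if (any(count_solo <= 0)) abort("`count_solo` must be > 0")
  count_condition / count_solo
}

#' Locate a CFSE low/high threshold from the intensity distribution
#'
#' Works on the log2 intensity scale (CFSE halves per division, so
#' generations are equally spaced and each forms its own mode).  Bins with
#' Freedman-Diaconis widths, smooths the histogram with a 3-bin moving
#' average, and returns the intensity at the valley between the rightmost
#' mode (the undivided, generation-0 population) and its nearest diluted
#' neighbour -- the boundary below which cells have divided at least once.
#'
#' @param intensities Positive CFSE intensities.
#' @return Threshold on the original intensity scale.
#' @export
cfse_threshold <- function(intensities) {
  if (length(intensities) == 0 || any(intensities <= 0)) {
    abort("intensities must be positive and non-empty")
  }
  h <- graphics::hist(log2(intensities), breaks = "FD", plot = FALSE)
  cnt <- h$counts
  sm <- stats::filter(cnt, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- cnt[is.na(sm)]
  sm <- as.numeric(sm)
  n <- length(sm)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) sm[i - 1] else -Inf
    right <- if (i < n) sm[i + 1] else -Inf
    sm[i] > 0 && sm[i] >= left && sm[i] >= right
  }, logical(1))
  peaks <- which(is_max)
  # collapse plateaus of equal smoothed height and drop noise bumps well
  # below the main mode
  if (length(peaks) > 1) peaks <- peaks[c(TRUE, diff(peaks) > 1)]
  peaks <- peaks[sm[peaks] >= 0.05 * max(sm)]
  if (length(peaks) < 2) {
    abort("could not locate two CFSE modes; supply an explicit threshold")
  }
  gen0 <- peaks[length(peaks)]
  prev <- peaks[length(peaks) - 1L]
  valley <- prev + which.min(sm[prev:gen0]) - 1L
  2^h$mids[valley]
}

#' Fraction of proliferating (CFSE-low) cells
#'
#' @param intensities Positive CFSE intensities of gated viable responder
#'   cells.
#' @param threshold Intensity below which a cell counts as divided; found
#'   automatically with [cfse_threshold()] when `NULL`.
#' @return Fraction in `[0, 1]` of events with intensity below the
#'   threshold.
#' @export
cfse_low_fraction <- function(intensities, threshold = NULL) {
  if (length(intensities) == 0) abort("empty intensity vector")
  if (is.null(threshold)) threshold <- cfse_threshold(intensities)
  mean(intensities < threshold)
}
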