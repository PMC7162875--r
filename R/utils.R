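#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_rows filter group_by inner_join left_join
#'   mutate n select summarise ungroup
#' @importFrom stats dhyper phyper rbinom rnorm rpois runif p.adjust cor var
#' @importFrom utils head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Convert a mass concentration to micromolar
#'
#' Converts a concentration given in micrograms per millilitre into
#' micromolar units given the molar mass of the compound. Used for dosing
#' arithmetic, e.g. the phospho-vitamin C working concentration of
#' 50 ug/mL (molar mass 289.54 g/mol) corresponds to ~173 uM.
#'
#' @param ug_per_ml Mass concentration in micrograms per millilitre.
#' @param molar_mass Molar mass in grams per mole.
#' @return Concentration in micromoles per litre.
#' @examples
#' mass_conc_to_uM(50, 289.54)
#' @export
mass_conc_to_uM <- function(ug_per_ml, molar_mass) {
  if (any(ug_per_ml < 0) || any(molar_mass <= 0)) {
    abort("ug_per_ml must be >= 0 and molar_mass > 0")
  }
  # ug/mL == mg/L; (mg/L) / (g/mol) == mmol/L == 1000 uM
  ug_per_ml / molar_mass * 1000
}

# reverse complement of plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

check_positive_int <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x <= 0 || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single positive integer", name))
  }
  as.integer(x)
}

check_unit_interval <- function(x, name, open = FALSE) {
  if (length(x) != 1 || is.na(x) ||
      (open && (x <= 0 || x >= 1)) || (!open && (x < 0 || x > 1))) {
    abort(sprintf("`%s` must lie in %s", name,
                  if (open) "(0, 1)" else "[0, 1]"))
  }
  as.numeric(x)
}

ARM_LABELS <- c("medium", "pVC", "TGFb", "TGFb_pVC")
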