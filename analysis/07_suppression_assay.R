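#!/usr/bin/env Rscript
# Stage 7 -- quantify the suppression assay.
#
# Simulates cytometry event tables for CD4 responder cells co-cultured
# with differently expanded gamma/delta T cells, derives absolute viable
# counts by the standard cell dilution assay (SCDA), expresses each
# condition as a relative expansion quotient (solo culture = 1.0), and
# measures the proliferating (CFSE-low) fraction of responders under
# increasing suppression.

source("analysis/00_config.R")

cy <- CFG$cytometry
n_std <- cy$n_standard_added

# true CD4 counts after 5 days of co-culture: strong expansion alone,
# progressively suppressed by TGF-beta-expanded gd T cells +/- pVC
truth_counts <- c(solo = 30000, gd_TGFb = 18000, gd_TGFb_pVC = 7500)
scda <- sapply(names(truth_counts), function(cond) {
  ev <- simulate_suppression_assay(
    c(gd = if (cond == "solo") 0 else 20000,
      cd4 = unname(truth_counts[cond])),
    n_std, c(1), seed = SEED + 70L + match(cond, names(truth_counts)))
  scda_count(sum(ev$role == "cd4"), sum(ev$role == "standard"), n_std)
})
quotients <- relative_expansion(scda, scda["solo"])
scda_tab <- data.frame(condition = names(truth_counts),
                       true_cd4 = unname(truth_counts),
                       scda_count = unname(scda),
                       expansion_quotient = unname(quotients))
readr::write_csv(scda_tab, file.path(OUT, "scda_quotients.csv"))
cat("SCDA counts and relative expansion quotients (solo = 1.0):\n")
print(scda_tab, row.names = FALSE)

# CFSE dilution: divided fractions mirroring increasing suppression
divided <- c(solo = 0.74, gd_TGFb = 0.59, gd_TGFb_pVC = 0.33)
cfse <- sapply(names(divided), function(cond) {
  ev <- simulate_suppression_assay(
    c(cd4 = 30000), n_std,
    cfse_generations = c(1 - divided[[cond]], rep(divided[[cond]] / 4, 4)),
    seed = SEED + 80L + match(cond, names(divided)))
  100 * cfse_low_fraction(ev$cfse[ev$role == "cd4"])
})
cfse_tab <- data.frame(condition = names(divided),
                       true_divided_percent = 100 * unname(divided),
                       cfse_low_percent = round(unname(cfse), 1))
readr::write_csv(cfse_tab, file.path(OUT, "cfse_fractions.csv"))
cat("\nCFSE-low (proliferating) percentages:\n")
print(cfse_tab, row.names = FALSE)

cat(sprintf("\npVC working concentration: 50 ug/mL = %d uM (MW 289.54)\n",
            round(mass_conc_to_uM(50, 289.54))))
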