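---
title: "Methods: simulated RRBS methylomes and sliding-window DMR discovery"
author: "rrbsdmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated RRBS methylomes and sliding-window DMR discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrbsdmr)
```

## Scope and model

`rrbsdmr` re-creates, on fully synthetic data with known ground truth, the
computational chain of a reduced representation bisulfite sequencing (RRBS)
study of T-cell methylomes: a vitamin-C-derivative (pVC) can convert
TGF-β-stimulated human γδ T cells into FOXP3-expressing regulatory-like
cells, and the conversion is accompanied by demethylation of the
Treg-specific demethylated region (TSDR) of *FOXP3* plus a set of
differentially methylated regions (DMRs) elsewhere in the genome. The
package covers: RRBS library construction *in silico* (MspI digestion, size
selection, directional bisulfite reads), read placement and per-cytosine
methylation calling, DMR discovery, sample-level methylome comparison,
DMR-to-gene annotation with gene-set enrichment, targeted-amplicon (TSDR)
summaries, and quantification of the accompanying suppression assay.

Four culture arms are modelled throughout: `medium`, `pVC`, `TGFb` and
`TGFb_pVC`. The synthetic TSDR-like locus is demethylated only in the
`TGFb_pVC` arm; implanted ground-truth DMR cassettes are demethylated in
both pVC arms. One library per arm is simulated — the DMR caller compares
two single methylomes and deliberately carries no replicate/dispersion
model.

## The synthetic data generator

`generate_genome()` draws i.i.d. background sequence at a chosen GC
fraction and implants extra CCGG motifs (about `ccgg_boost − 1` per kb) so
that MspI fragments densely tile the genome, as in a real
reduced-representation library. Annotation features (genes, strand-aware
promoters at TSS −2000/+500, CpG islands, ground-truth DMR cassettes, one
TSDR-like cassette) are laid down with the cassettes flanked by CCGG so
that their interiors sit on 40–220 bp fragments that survive size
selection and are at least one read long. Cassette interiors contain fixed
CpG positions (≥ 7 in the TSDR cassette, matching the 7-CpG targeted
assay) interleaved with random A/T positions; the randomization makes each
implanted copy unique so its reads place unambiguously, without changing
the CpG count.

`assign_profile()` gives every cytosine on both strands a true methylation
level: a CpG background (default 0.75) and a non-CpG background (default
0.01, the low CHG/CHH methylation typical of somatic cells), plus bounded
jitter, with exact condition-specific levels at CpGs inside the features
named in `dmr_spec`. Two generator details are deliberate:

* **Jitter.** Background jitter (truncated normal, SD 0.05, cut at 2 SD)
  is drawn independently per arm so that null windows are not artificially
  identical across arms. Near the 0/1 bounds the SD shrinks
  proportionally; a constant SD clipped to [0, 1] would bias the mean of
  low-level contexts upward, and the generator promises that the mean CHH
  level equals the requested background.
* **Spec levels apply to CpGs.** Inside a `dmr_spec` feature the
  condition-specific level is applied to CpG-context cytosines only;
  non-CpG cytosines keep the background, since non-CpG methylation stays
  low regardless of condition and the DMR analysis runs per context.

Reads are single-end (default 50 bp), drawn from the 5′ ends of the
original-top and original-bottom strands of retained fragments —
a directional library. Each cytosine on the read strand is emitted as C
with probability `level + (1 − level)(1 − conversion)` (bisulfite
conversion default 0.995) and substitution errors are applied at a default
rate of 0.001; both are typical instrument values and configurable. No
adapter, PCR-duplicate, indel or quality-score realism is attempted.
Retained fragments shorter than the read length are skipped (their count
is recorded) so that read length stays constant within a run.

Because read-level simulation is expensive at DMR scale,
`simulate_methylome()` also generates count tables directly: Poisson
coverage per site, binomial methylated counts at the (conversion-adjusted)
true level. The read path and the count path are both exercised by the
test suite; DMR-scale experiments (oracle equivalence, recovery, null
control) use the count path, read-level fidelity is verified end-to-end
separately.

## Read placement and methylation calling

Bisulfite conversion collapses the read alphabet: an original-top read
matches the forward reference after C→T collapse on both, and the reverse
complement of an original-bottom read matches after G→A collapse.
`place_reads()` searches both orientations, accepts a unique best
placement with at most 2 mismatches (exact hits found in bulk via a
`Biostrings::PDict`, the mismatch-tolerant scan only as a fallback), and
discards ambiguous or unplaced reads with counts reported. This in-package
placer keeps the pipeline free of external aligners and lets placement be
validated against the simulator's origin fields; no equivalence with any
specific production aligner is claimed.

`call_cytosines()` implements the level definition used throughout:
at each reference cytosine on the read's informative strand a read C
increments `mC`, a T increments `uC`, any other base is ignored as
sequencing error, and `level = mC / (mC + uC)`. Bases other than C/T are
*excluded from the denominator* — the "total C" of the definition is the
number of C/T observations. Calling is deterministic; tables round-trip
exactly through the CX-style TSV export (`export_cx()` / `import_cx()`
recompute the level from the counts on import).

Context is strand-aware: CpG when the next base 5′→3′ on the cytosine's
strand is G; CHG when the base after next is G; CHH otherwise; cytosines
whose context is truncated by a chromosome end default to CHH.

## DMR discovery

The caller compares two methylomes per context class with four rules:

1. **Windows.** Sites covered ≥ `min_cov` (default 5) in *both* samples
   are sorted by position; every run of exactly `min_sites` (default 5)
   consecutive such sites forms a candidate window, sliding by one site.
   Pure site-count windows avoid an arbitrary bp width; "at least 5
   sites" regions arise from the collapse step below.
2. **Criteria.** Counts are pooled over window sites
   (`L = Σ mC / Σ (mC + uC)`); a window passes when the pooled fold change
   `max(L1, L2) / min(L1, L2)` is ≥ 2, the two-sided Fisher exact p on the
   pooled 2×2 table is < 0.05, and the samples are not both
   hypomethylated. Pooling the counts for the fold change keeps it
   consistent with pooling for the Fisher table; an unweighted-mean mode
   was considered and rejected for that reason. A pooled level of exactly
   0 gives an infinite fold change (the criterion is then decided by the
   other two rules).
3. **Collapse.** Overlapping passing windows are collapsed into maximal
   putative regions; each collapsed region is re-tested on its own pooled
   counts and dropped if it fails, so every reported region satisfies the
   criteria itself.
4. **Merging.** Two putative regions on one chromosome within `max_gap`
   (default 500 bp) are *interdependent* when the spanning region — pooled
   over **all** qualifying sites from the upstream start to the downstream
   end, not just the member sites — itself satisfies all criteria; such
   pairs are replaced by their span. Sweeps repeat to a fixpoint, so the
   final regions are pairwise independent; the fixpoint is checked to be
   sweep-order invariant on the test corpus.

Open definitional points were resolved as follows, all configurable:
"nearby" = 500 bp; "hypomethylated" = pooled level < 0.2; "both samples
should not be hypomethylated" is read as *not both* (`max(L1, L2) ≥ 0.2`),
since demethylation of one sample is exactly the biological signal sought
— the stricter *neither* reading is available via `hypo_rule = "neither"`.
The Fisher test is applied to counts pooled across window sites (not per
site), consistent with the pooled fold change. No smoothing, no
beta-binomial dispersion and no multiple-testing correction are applied.

The two-sided Fisher p is computed in log space from `dhyper`: the sum of
probabilities of all tables with the observed margins whose probability is
at most that of the observed table, with a 1e−7 relative tolerance on the
comparison to protect ties against floating-point noise; an all-zero table
returns 1 by convention. The package also ships
`call_dmrs_reference()` — a deliberately plain brute-force enumerator
(explicit loops, `stats::fisher.test`) of the same definition — used as an
independent oracle: on random 100 kb two-arm comparisons the production
caller and the enumerator produce identical final sets.

## Sample-level comparison

`build_matrix()` intersects qualifying CpG sites across all samples
(min coverage 5, per-strand sites; symmetric CpG pairs are not pooled,
matching the per-cytosine level definition). `pearson_matrix()` reports
undefined entries for zero-variance samples as `NA` rather than 0.
`pca_samples()` centres site-wise (no scaling — levels already share the
[0, 1] scale) and eigendecomposes the sample Gram matrix (the dual of
site-space PCA, exact and cheap for a handful of samples); coordinates are
`eigenvector × √eigenvalue`, the sign convention makes each component's
first nonzero loading positive, and variance-explained fractions sum to 1.
`context_feature_summary()` reports coverage-pooled mean levels per
context (mCG/mCHG/mCHH) for promoters, CpG islands, gene bodies and
genome-wide, with empty combinations reported as `NA`, never 0.

## Annotation and enrichment

DMRs are assigned to gene bodies and promoters on ≥ 1 bp overlap; the
promoter extent (TSS −2000/+500, strand-aware) is a declared convention,
not a quantity the analysis is sensitive to, and is configurable.
Enrichment replaces a web-based over-representation service with the exact
hypergeometric upper tail (`P(X ≥ overlap)` via `phyper`), with the full
gene annotation as background. Mirroring the original analysis choice,
significance is called on raw p ≤ 0.05 with no multiple-testing
correction; a Benjamini–Hochberg column is emitted for information only.
Enrichment is validated on synthetic gene sets — which biological term
libraries would reproduce any particular published hit is unknowable from
the term lists alone.

## Targeted amplicon and suppression assay

`summarize_amplicon()` computes per-CpG percentages and their unweighted
mean over the (default 7) assay CpGs; a zero-coverage CpG is excluded from
the average with a warning rather than imputed. `heatmap_color()`
interpolates yellow (255, 255, 0) → green (0, 128, 0) → blue (0, 0, 255)
piecewise-linearly with exact anchors at 0/50/100 % — the standard named
colors, since exact RGB values are a presentation convention.

`scda_count()` implements absolute counting with spiked-in standard
cells: `target events / standard events × standards added`. The estimator
is linear in both factors and, as a ratio estimator, unbiased to O(1/n)
under uniform event subsampling. `relative_expansion()` normalises viable
counts to the solo culture (quotient 1 by construction; < 1 means
suppression). `cfse_low_fraction()` thresholds CFSE intensities; the
automatic threshold works on the log2 scale (the dye halves per division,
so generations are equally spaced), bins with Freedman–Diaconis widths,
smooths with a 3-bin moving average, and takes the valley between the
rightmost mode (generation 0) and its nearest diluted neighbour. Peaks
below 5 % of the main mode are ignored as noise; a distribution without
two such modes is refused rather than silently thresholded. Event tables
are plain CSV with a viability flag supplied by the generator — FCS
parsing, compensation and gating reconstruction are out of scope.

## Numerical and testing choices

* Coordinates are 0-based half-open internally and in BED; GTF export is
  1-based; human-readable reports state positions as-is from the tables.
* Deterministic ordering everywhere: sites by (chrom, pos, strand),
  windows left to right; fixed seeds give byte-identical FASTQ/CSV/JSON.
* The test suite and the acceptance script size their simulations to the
  package's validation needs: 100 kb genomes for DMR oracle equivalence
  (20 comparisons) and recovery (10 implanted cassettes × 5 seeds, 25×
  coverage), 60 kb for the null-comparison control (> 7000 windows), and
  a 40 kb read-level run for calling fidelity.
* The calling-fidelity check uses a deliberately bimodal profile (true
  levels exactly 0 and 1, jitter 0) with conversion 1 and error 0: every
  base call is then deterministic, so observed levels must equal the truth
  *exactly* — stricter than any standard-error band, and the strongest
  end-to-end statement about digestion, read simulation, placement and
  calling composing correctly. For interior levels a per-site "within
  3 SE at every site" bound is not statistically attainable (each site
  fails with probability ≈ 0.3 %, so some site among thousands will), so
  intermediate levels are instead checked in aggregate: observed C
  fractions within 3 binomial SE over ≥ 10 000 site-observations, and
  amplicon percentages within 3 SE per CpG.
* The null control (identical truth profiles in both arms, independent
  count noise) bounds the fraction of candidate windows passing all
  criteria by the nominal 0.05; in practice the conjunction of the
  conservative Fisher test with the 2-fold rule leaves it near zero.

## What passing tests do and do not show

The generator emulates fragment-restricted coverage, strand-resolved
calls, context mixtures, condition-specific demethylation and sampling
noise. It does not emulate alignment ambiguity from genomic repeats, CpG
density gradients and methylation domain structure of real chromosomes,
PCR/conversion bias, batch effects, or biological replicate variance.
Recovery and error-control results on synthetic data therefore validate
the *implementation* of the DMR definition and the pipeline's plumbing —
they are not estimates of sensitivity or specificity on real RRBS data.

## Configuration and orchestration

`run_pipeline()` executes the whole chain from one nested configuration
(`default_run_config()`), writes every stage output plus a ground-truth
manifest, and records parameters and per-file MD5 checksums in a run
manifest; identical config and seed give identical checksums, and each
stage can be re-run from the intermediate files. Configurations
round-trip through YAML (`write_run_config()` / `read_run_config()`) —
a declarative format with no code execution. The numbered scripts under
`analysis/` present the same chain as a narrative workflow.
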