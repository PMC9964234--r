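---
title: "Gene-pair correlation rewiring: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair correlation rewiring: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccrewire)
```

## The question the package answers

Expression studies with repeated conditions — here a three-phase design
with columns labelled `Pre`, `In` and `Post` relative to an exposure such
as spaceflight — are usually analysed gene by gene. ccrewire analyses
them *pair by pair*: for each condition it computes the Pearson
correlation of every gene pair across that condition's samples, and it
treats the change of that correlation between conditions,
ΔCC = CC_later − CC_earlier, as the biological signal. A pair whose
correlation collapses from 0.93 to −0.09 reveals a lost regulatory
coupling even if neither gene's mean level moves. Panels of such pairs
are candidates for compact monitoring assays (e.g. an RT²-PCR panel for
astronaut health).

## The selection model

Selection is deliberately rule-based, not inferential — with 20 samples
per condition, formal tests on correlation differences would have little
power, and the aim is a reproducible shortlist, not p-values:

1. **Magnitude screen.** Keep unordered pairs with |ΔCC| ≥ `delta_cut`
   (default 0.70, a dimensionless correlation difference in [0, 2]). The
   threshold is applied as ≥: published two-decimal tables contain pairs
   sitting exactly at 0.70 that belong to the selection, so a strict `>`
   on rounded values would mis-drop them.
2. **Strength-class transition rule.** Each |CC| is classed weak
   (< 0.36), moderate (0.36 ≤ |CC| < 0.68) or strong (≥ 0.68). The
   intervals are half-open so every real value gets exactly one class
   while agreeing with the conventional two-decimal bounds (0.35 weak,
   0.36 moderate, 0.67 moderate, 0.68 strong). A pair is panel-eligible
   only if its class moves strong→weak, weak→strong, or strong→strong
   with a strict sign flip. Moderate endpoints are excluded by design:
   they dilute an assay with pairs whose rewiring is partial.
3. **Sign categories.** Independently of selection, each pair is
   categorised 1–4 by the signs of (CC_before, CC_after); exact zero
   counts as nonnegative, which only affects pairs printed as 0.00. The
   dominance of categories 2 and 3 (sign flips) over 1 and 4 is the
   package's summary of coordination loss.

The panel is the lexicographically sorted distinct-gene union over
selected pairs. Pairs are stored unordered (`gene_a < gene_b`), matrices
are read upper-triangle only, and reports are sorted by |ΔCC| descending
then pair id, so outputs are byte-deterministic.

## Parameters that matter

| parameter | default | units / range | why |
|---|---|---|---|
| `delta_cut` | 0.70 | correlation difference, [0, 2] | separates rewired pairs from sampling noise at the study's scale |
| strength bounds | 0.36, 0.68 | \|CC\| | conventional weak/moderate/strong trichotomy |
| `lfc_cut` | 3.00 | log2 fold change | DEG screen feeding the pathway gene lists |
| `p_cut` | 0.05 | probability | raw p threshold; no multiplicity correction by default (a BH option exists) |
| `noise_sd` | 0.5 | log2 intensity SD | synthetic generator; typical processed-microarray residual spread |
| `background_cc` | 0 | correlation | synthetic non-planted pair correlation |

Input intensities are assumed log2-scale, the norm for processed
two-colour arrays; `scale = "linear"` declares otherwise and triggers a
log2(x + 1) transform at read time.

## The differential-expression stage

The DEG stage re-implements a Poisson likelihood-ratio test of equal
per-sample rate on per-condition totals: with totals C_a, C_b from n_a,
n_b samples and π = n_a/(n_a + n_b),

D = 2[C_a·ln(C_a/(πT)) + C_b·ln(C_b/((1−π)T))],  T = C_a + C_b,

with a zero count contributing 0 and D referred to χ²₁. Log2 intensities
are rescaled to linear pseudo-counts (2^x) before summing, mirroring what
count-model DE callers compute when handed array intensities. This is a
deliberate design choice: the test is fully self-contained and its null
calibration is verified by simulation in the suite (the rejection rate at
p < 0.05 under an equal-rate Poisson null sits at 0.05 ± 0.02). Users who
object to count models on intensities can switch to a Welch t-test
(`test = "welch"`). The degenerate all-zero case returns D = 0, p = 1 and
is flagged.

Probe rows are *not* collapsed to genes after symbol annotation: the gene
symbol is carried as an annotation, preserving transcript-level
resolution (several probes of one gene stay separate rows). A
mean-collapse option exists but is off by default. Replicate profiles of
a subject are used as separate columns rather than averaged — the
simplest reading of the study design — and averaging by subject remains
available upstream of the pipeline.

## What the synthetic generator emulates — and what it does not

`generate_study()` draws each condition's columns from a multivariate
normal on log2 scale: per-gene means (baseline 8, plus planted log2 fold
changes for the In condition; Post means equal In means so the Post-vs-In
contrast is null by construction), common `noise_sd`, and a target
correlation matrix assembled from `background_cc` plus planted pair
entries. Indefinite targets are repaired by eigenvalue clipping at a
small floor followed by diagonal rescaling — a deterministic one-shot
repair rather than an iterative nearest-correlation algorithm; a planted
entry that drifts more than 0.02 under repair is treated as a
mis-specified design and errors. The truth ledger labels each planted
pair by running the package's own classification on the repaired
noise-free targets, so truth and selection agree exactly in the absence
of noise.

The generator reproduces the *shape* of a real study (default 10 subjects
× 2 replicates × 3 conditions = 20 columns per condition), approximately
Gaussian log intensities, planted correlation transitions spanning all
four sign categories and all three strength classes, and planted fold
changes. It does **not** model probe-level effects, array normalisation
artefacts, subject random effects (columns are exchangeable within a
condition; an intercept per subject was considered and left out to match
the replicates-as-columns reading), or heavy-tailed noise. Passing
recovery tests therefore demonstrates correctness of the screening
machinery, not robustness to microarray pathology.

Validation uses two problem sizes. At 1 000 columns per condition and
zero background correlation, planted panel-eligible transitions are
recovered with sensitivity ≥ 0.95 at a false-positive rate ≤ 0.01 —
the regime where sampling noise on r (≈ n^−1/2 ≈ 0.03) is negligible
against the 0.70 cut. At the real 20-column shape the same screen is
noisy by nature; the suite asserts only that planted transitions with
|ΔCC| ≥ 1.2 are recovered at sensitivity ≥ 0.5, documenting the
small-sample caveat instead of hiding it: at n = 20 a weak-side
correlation has a sampling SD around 0.2, so class boundaries are crossed
routinely. Simulations in the suite use 40 genes (20 planted disjoint
pairs), which keeps the full run in seconds while leaving 760 non-planted
pairs to estimate the false-positive rate.

## Numerical choices and degenerate inputs

* Zero-variance rows yield `NA` correlations (not errors); they are
  counted, reported, and excluded from summaries and selection.
* The |ΔCC| ≥ cut comparison carries a 1e−12 slack so that two-decimal
  published values sitting exactly at the cut are kept regardless of
  floating representation.
* Genome-scale inputs: all-pairs matrices over tens of thousands of rows
  are a memory hazard, so `correlation_summary_stream()` computes the
  global mean |CC| and class fractions in row blocks without
  materialising the full matrix. "Loss of genome regulation" is
  operationalised as this mean-|CC|/class-fraction summary — a stated
  proxy, since the underlying claim is usually shown only as heat maps.
* Ranked DEG reports break ties by |log2FC| descending, then p ascending,
  then row id.
* The packaged worked example contains one published row whose printed
  differential disagrees with its printed endpoints by 0.10
  (`ACSL4–GPT`); the fixture keeps the printed values verbatim and the
  suite asserts the discrepancy as a known deviation rather than
  silently "fixing" the source.

## Worked example

```{r}
pc <- astro_pair_cc()
rec <- classify_pairs(pc$gene_a, pc$gene_b, pc$cc_pre, pc$cc_in)
sel <- select_panel(rec)
nrow(rec); nrow(sel)
length(panel_genes(sel))
category_counts(rec)
```

The screen keeps 43 of 85 published pair rows and yields the 32-gene
panel; categories 2 and 3 dominate, the coordination-loss signature.

## Known limitations

* No statistical test accompanies the ΔCC cut, and no correction for the
  number of pairs screened — the screen is a reproducible rule, and its
  false-positive behaviour should be judged by the simulation results at
  the study's sample size.
* Pathway membership is consumed as input (GMT); enrichment itself is out
  of scope.
* The Poisson LRT on rescaled intensities inherits the count-model
  assumption; treat its p-values as a ranking device at microarray scale,
  or use the Welch option.
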