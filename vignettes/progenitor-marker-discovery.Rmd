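---
title: "Resolving hidden heterogeneity in a progenitor gate: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving hidden heterogeneity in a progenitor gate: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progmark)
```

## The problem

Flow-sorted progenitor populations are defined by a handful of surface
markers, and the cells inside one gate are routinely treated as
homogeneous. Transcriptomes say otherwise: a gate such as the common
myeloid progenitor (CMP) can contain a latent subpopulation that has
already committed to a downstream fate (the granulocyte–monocyte
progenitor, GMP, direction) while still satisfying the gate. `progmark`
implements a complete discovery loop for this situation:

1. **Signature derivation.** From bulk RNA-seq of the gate population and
   its downstream neighbor, take the top *k* genes by log-scale mean
   difference (log2 fold change on log2(TPM + 1)) as the population
   signature. *k* = 10 for discovery signatures, *k* = 200 for validation
   sets.
2. **Per-cell scoring.** Standardize each gene across single cells of the
   gate (Z-score, sample s.d.) and give every cell the **sum of Z-scores**
   over the signature. Cells sum to a dimensionless score whose
   population mean is exactly zero.
3. **Stratification.** Rank cells by score; the top and bottom thirds are
   the score-high and score-low strata. Score-low cells are the
   committed-like candidates.
4. **Marker discovery.** Per gene, a two-sided Wilcoxon rank-sum test plus
   the log2 fold change between score-low and score-high cells, BH
   adjustment over all tested genes, and a `fold change > 2, FDR < 0.05`
   cut. Candidates are then filtered to surface-molecule-encoding genes —
   a usable marker must be sortable.
5. **Validation.** GSEA of the downstream signature between strata: a
   weighted Kolmogorov–Smirnov running-sum score against a gene-label
   permutation null.

Cross-species transfer (`map_symbols()`) lets a signature derived in
mouse score human cells, either through an explicit ortholog table or the
standard symbol-case heuristic (`Sell` ↔ `SELL`).

## The summed Z-score

For gene $g$ and cell $c$ with log-expression $x_{gc}$,

$$ z_{gc} = \frac{x_{gc} - \bar x_{g\cdot}}{s_g}, \qquad
   \mathrm{score}_c = \sum_{g \in S} z_{gc}, $$

with $s_g$ the sample (n−1) standard deviation across all cells.
Standardization is **per gene across cells** — the only orientation under
which a per-cell sum over a gene set is well defined — and a zero-variance
gene contributes 0 because it carries no between-cell information. Two
consequences are load-bearing and tested: each nonconstant z-row has mean
0 and s.d. 1, so scores over all scored cells sum to zero; and scoring is
linear in the gene set (disjoint sets add).

Z-scores are always computed within one matrix. Scoring two datasets
(e.g. two species) means two separate standardizations; the package never
pools matrices.

## Stratification rules

`stratify_tertiles()` sorts by (score descending, cell identifier
ascending) and assigns exactly `floor(n/3)` cells to each extreme
stratum, the remainder to the middle. The identifier tie-break makes the
assignment a pure function of (score, id) pairs — shuffling column order
changes nothing, and fully tied scores still split deterministically.

`stratify_by_gene()` trisects by one gene's own expression with
lower-interpolation empirical quantiles at (1/3, 2/3) by default, naming
the strata `neg`/`int`/`high`; zero-expression cells are always `neg`
regardless of the quantile (with heavy dropout the lower quantile can sit
at 0, and a zero cell must never be called intermediate).

## The differential-expression engine

The two-stratum comparison uses an in-package Mann–Whitney test:
midranks for ties; an exact p-value (via the exact U null distribution)
when the combined sample size is ≤ 12 without ties; otherwise the normal
approximation with tie-corrected variance and continuity correction. BH
adjustment is the textbook step-up, applied over **all tested genes**
(standard BH semantics), not just reported ones. Genes with zero
expression in every cell of both strata have no defined test and are
skipped with a log line. A negative-binomial GLM engine in the style of
bulk DE tools was deliberately not used: the rank-sum test is the
standard nonparametric choice for a two-group single-cell comparison,
is assumption-light under dropout, and keeps the package self-contained.

"Most upregulated" is operationalized as significance-first ordering
(q ascending, then log2FC descending, then symbol); a pure fold-change
ordering is available via `order_by = "log2fc"` since either reading is
defensible.

## GSEA choices

The ranking metric is signal-to-noise, $(\mu_a - \mu_b)/(\sigma_a +
\sigma_b)$, with each $\sigma$ floored at $\max(0.2\,|\mu|,\ 0.2)$; groups
smaller than two fall back to the mean-difference metric. The running sum
weights hits by $|\mathrm{metric}|^p$ with $p = 1$ by default ($p = 0$
gives the classic KS statistic and is kept for oracle testing). The null
is **gene-label permutation**: `n_perm` random same-size gene sets drawn
from the ranked list. Phenotype permutation was rejected because the
pipeline routinely validates groups of three replicates, where phenotype
permutation is degenerate. The permutation p is one-sided in the
direction of the observed ES, computed against the same-sign half of the
null with add-one smoothing in numerator and denominator — that
convention keeps p in (0, 1], makes it uniform for a null set, and
matches the reference GSEA implementation. NES divides the observed ES by
the mean magnitude of same-sign null scores and is explicitly flagged
undefined (rather than silently NaN) when no null score shares the sign.

## What the synthetic-data generator emulates

`simulate_dataset()` produces the latent structure the analysis assumes,
plus a ground-truth record, so every stage is testable without any
download:

* **Counts** are negative-binomial with log-normal per-gene baseline
  means (meanlog 1.5, sdlog 1.0 — a median of ~4.5 expected counts per
  gene per cell) and log-normal per-cell library factors (sdlog 0.3).
* **Bulk replicates** (3 per population) are drawn at 100× single-cell
  depth with dispersion 0.02, against 0.3 for single cells — real bulk
  libraries are deeper and far less over-dispersed, and at 3 replicates
  this difference decides whether a 4-fold planted effect is separable
  from Poisson noise at all.
* **Dropout** applies only to single cells: an entry with pre-dropout
  mean $\mu$ is zeroed with probability
  $\mathrm{logit}^{-1}(-(\log\mu - m)\cdot s)$, midpoint $m = 0$ and slope
  $s = 1$, i.e. a one-count gene drops out half the time and a
  well-expressed gene almost never.
* **Planted structure.** A committed fraction (default 0.33) of cells,
  recorded by identifier after a seeded shuffle, carries: the downstream
  (GMP-like) 10-gene program up by 2 log2 units, the progenitor
  (CMP-like) program down by the same, three lineage-restricted genes
  (the neutrophil-protease analogs) switching from ~0.05 expected counts
  to full expression, and one surface-molecule gene co-regulated with the
  downstream program (+2 log2) — the marker the pipeline should nominate.
  Baseline means of planted classes are fixed generator constants
  (progenitor program 20, downstream program 8, marker 40 counts): the
  marker is modeled as a well-expressed surface gene, which is also what
  makes its detection statistics robust relative to the moderate-level
  program genes.
* **Bulk plants only the two programs.** The marker and the
  lineage-restricted genes are *not* differential between the bulk
  populations, so the 10-gene bulk signatures are exactly the planted
  programs, and the marker is discoverable only through single-cell
  heterogeneity — which is the phenomenon the pipeline exists to detect.
* **Surface annotation.** The planted marker plus 50 decoy genes are
  flagged as surface molecules, giving the surface filter a realistic
  null universe. What counts as "surface molecule-encoding" in real data
  is a curation decision; the annotation file externalizes it and the
  package never hard-codes a surface universe.

TPM here is column-proportional scaling to one million without
gene-length correction — lengths are neither simulated nor known for
these matrices — followed by log2(x + 1).

What the generator does **not** emulate: UMI chemistry, doublets, batch
effects, cell-cycle structure, gene length, or correlated co-expression
beyond the planted programs. The last point matters for interpreting the
200-gene validation sets: with only 10 truly differential genes per
program, 190 of 200 members of a validation set are bulk-noise picks, so
its enrichment is directionally correct but much weaker than a 200-gene
signature from real, pervasively correlated data. Passing tests show the
machinery is correct under the stated model, not that any real dataset
will behave as cleanly.

## Reproducibility and numerics

Every randomized operation takes an explicit seed and runs under a
save/restore of the caller's RNG state; identical parameters give
bit-identical output. `run_discovery()` derives per-stage seeds from one
master seed by fixed offsets so stages can be re-run individually. TSV
output uses `%.10g`, which round-trips doubles losslessly at the
precision the pipeline uses. Degenerate inputs fail loudly and early:
zero-total columns, double normalization, empty strata, all-tied ranking
inputs, sets covering an entire ranked list, and annotations with no
surface gene are all named errors rather than silent NaNs.

Ties are broken deterministically everywhere: by symbol in ranked lists
and signature derivation (after the pop-A mean), by cell identifier in
stratification.

## Problem sizes used by the test suite

Unit tests run on small matrices (tens of genes) against brute-force
oracles; recovery and calibration properties run on the generator's
default conditions (2000 genes × 300 cells, 3+3 bulk replicates) over 20
seeds, with 50-seed calibration checks for p-value uniformity. These
sizes make every planted effect comfortably detectable while keeping a
full suite run around two minutes; they are the package's reference
conditions, stated here so results are interpretable, and the acceptance
script (`scripts/acceptance.R`) recomputes the headline quantities at the
same sizes.

## Known limitations

* The summed Z-score is the only scoring scheme; rank-based (AUCell-like)
  scores and control-gene-bin corrections are out of scope.
* The DE engine is rank-sum only; no dispersion shrinkage, no covariates.
* The case heuristic for cross-species mapping is exactly that — a
  heuristic. Real orthology is many-to-many; supply an ortholog table for
  anything that matters.
* GSEA here has no cross-set FDR (the pipeline tests two sets) and no
  compatibility guarantee with any external tool's file formats beyond
  GMT.
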