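---
title: "Coevolution-based variant impact scoring: model, assumptions, and validation"
author: "coevoscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coevolution-based variant impact scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevoscore)
```

## The problem

Most variant-impact predictors assume that functionally important residues
are conserved, and therefore miss deleterious substitutions at
less-conserved sites. Yet many such sites exist: residues involved in
allosteric regulation, conformational change, or protein–protein interfaces
are often variable across homologs because substitutions at one site are
*compensated* by substitutions at cooperating sites. Those compensations
leave a footprint in a multiple sequence alignment (MSA): the substitution
patterns of the two columns covary. `coevoscore` scores missense variants
from exactly that footprint.

## The model

For a query protein of length $L$ with a query-anchored MSA:

1. **Covariation (McBASC).** For each pair of alignment columns $(i, j)$,
   build for each column the vector of McLachlan (1972) similarity scores
   over all unordered sequence pairs $(k, l)$, and take the Pearson
   correlation of the two vectors. Only sequence pairs with non-gap residues
   at both columns in both sequences contribute.
2. **Coupling selection (the 2L rule).** Rank all column pairs by
   covariation and keep the top $2L$; these are the protein's evolutionary
   couplings. Each residue $i$ then has a set $C_i$ of coupled partners.
3. **Coupling number (CN).** $|C_i|$, percentile-normalized within the
   protein to $[0, 1]$ via $(\mathrm{rank} - 1)/(L - 1)$ (average ranks for
   ties). CN $=$ 1 marks the most coupled residue. The normalization makes
   CN comparable across proteins with different coupling-count
   distributions.
4. **Cost of coupling (CC).** For a variant $\alpha \to \gamma$ at residue
   $i$, with $\beta$ the query residue at a coupled partner $j$ and
   $n_{i,j}(\cdot,\cdot)$ the amino-acid pair counts of the two columns,

   $$\Delta S_{i,j}(\alpha \to \gamma)
     = -\ln \frac{n_{i,j}(\gamma, \beta) + 1}{n_{i,j}(\alpha, \beta)},
   \qquad
   CC_i(\alpha \to \gamma)
     = \frac{\sum_{j \in C_i} \Delta S_{i,j}(\alpha \to \gamma)}{|C_i|}.$$

   $\Delta S$ is the exact change of the log-multinomial entropy
   $S = \ln\!\big(N! / \prod n!\big)$ when one count moves from
   $(\alpha,\beta)$ to $(\gamma,\beta)$ — the test suite verifies this
   identity against a log-gamma oracle to $10^{-9}$. High CC means the
   variant creates residue pairings that are rare among homologs.
5. **CE score.** $CE = CN \times CC$. A high CE needs both a highly coupled
   site (CN) and an evolutionarily unfavorable substitution at that site's
   partners (CC).

A single-column conservation analog, $CS = -\ln((n_i(\gamma)+1)/n_i(\alpha))$,
is provided for comparison and for union-rule integration.

## Alignment handling and filters

* The alignment is anchored to the query at read time: columns where the
  query has a gap are dropped, so column indices equal query residue
  positions and $L$ is the query length. A2M insert states (lowercase, `.`)
  are treated as gap-equivalent and dropped with their columns.
* Columns with a gap fraction **strictly above 20%** (`maxGapFrac = 0.2`)
  and completely conserved columns are masked and excluded from covariation.
  Masked sites still receive scores (their residues simply carry no
  couplings, so CC and CE are 0) and are flagged `masked_site` in the
  output — every variant remains scoreable.
* Homolog sets are filtered with `filterHomologs()`: global-alignment
  identity to the query strictly below 90%, length within 0.7–1.3 of the
  query (inclusive), and a minimum of 10 survivors; smaller sets are flagged
  insufficient rather than silently passed. Identity is defined as aligned
  matches divided by the shorter sequence length under a BLOSUM62
  Needleman–Wunsch alignment — a reproducible choice; any consistent
  definition serves, since the filter precedes the analysis proper.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `multiplier` | 2 | coupling budget per length unit; budget $= \mathrm{round}(m \times L)$ |
| `maxGapFrac` | 0.2 | strict column gap-fraction cutoff |
| `minSeqPairs` | 10 | minimum usable sequence pairs for a covariation score; sparser pairs score 0 |
| `maxIdentity`, `lenLo`, `lenHi`, `minN` | 0.9, 0.7, 1.3, 10 | homolog filters |
| activity cutoff | 0.5 | intolerant iff activity $<$ 50% of wild type (strict) |

## Numerical and degenerate-input conventions

* Pearson correlations of zero-variance similarity vectors are 0, not
  undefined, so invariant-ish columns carry zero couplings instead of
  poisoning the ranking; correlations are clamped to $[-1, 1]$ against
  floating-point drift.
* Ties at the $2L$ cutoff break deterministically by (score descending,
  $i$, $j$ ascending); coupling selection is monotone in the budget.
* $|C_i| = 0 \Rightarrow CC = 0$ (flagged `no_partners`), keeping every
  variant scoreable with a conservative value.
* The query row always contributes to pair counts, so the $\Delta S$
  denominator $n_{i,j}(\alpha, \beta) \ge 1$ whenever the stated wild type
  matches the query; a mismatch is an error (or a flagged row in batch
  scoring).
* Classifier thresholds use `score >= threshold`; the threshold scan over
  observed scores (plus one value above the maximum) is therefore
  exhaustive, and ties go to the smallest maximizer. MCC and precision fall
  back to 0 on empty marginals. Degenerate single-class cross-validation
  splits are redrawn from the continuing RNG stream.
* All stochastic functions take an explicit integer seed and restore the
  global RNG state (`withr::with_seed`).

## What the synthetic generator emulates — and what it does not

`generateCoupledMsa()` plants three column categories: covarying groups,
conserved columns, and background columns.

* **Covarying groups.** `plantedPair(i, j, states, w)` draws, per sequence,
  a compatible joint state (e.g. A–K or S–E) with probability `w`, and
  independent residues otherwise; `w` is the strength of compensation.
  `plantedClique(cols, states, w)` generalizes this to $k$ columns that
  switch state jointly, so every member residue gains $k - 1$ planted
  couplings. Cliques matter because the method's premise is that important
  sites are coupled to *many* sites: with isolated pairs every coupled
  residue has exactly one planted partner, coupling *counts* carry no
  signal, and only CC is testable. The validation suite uses isolated pairs
  for the coupling-recovery benchmark and cliques (sizes 8 and 5, plus
  isolated pairs) for the CE benchmark.
* **Defaults**, chosen once as typical of a usable protein-family
  alignment: mixing weight $w = 0.9$ (strong but imperfect compensation),
  per-cell gap rate 0.05, conserved-column dominant frequency 0.95, and
  4-letter per-column background sub-alphabets — the restricted alphabet
  keeps amino-acid pair-count tables dense at the alignment depths used in
  testing ($N \approx 200$, matching the reported average homolog count per
  protein).
* **Not emulated:** phylogenetic correlation between sequences (rows are
  exchangeable here, so no redundancy downweighting is exercised),
  alignment errors, indel structure beyond i.i.d. gaps, and chains of
  indirect coupling. Passing tests therefore demonstrate correctness of the
  statistics and the machinery, not real-protein performance; published
  benchmark numbers require the original curated MSAs and variant sets.

The labeled-dataset generator (`generateLabeledDataset()`) provides the
Gaussian two-score benchmark for the evaluation stack; its informative
score has closed-form AUC $\Phi(d/\sqrt{2})$ at effect size $d$, which the
suite checks empirically at $n = 2000$.

## Design choices where the design was open

* **McBASC estimator.** Plain Pearson correlation over unordered sequence
  pairs, diagonal excluded, no sequence weighting or redundancy
  downweighting, and no average-product correction — the classic
  substitution-correlation formulation. A sequence pair contributes to a
  column pair only if all four residues are non-gap, and column pairs with
  fewer than `minSeqPairs` usable sequence pairs score 0.
* **Masked-column scoring.** Gap-heavy and invariant columns are removed
  from the covariation analysis but their residues still participate in the
  CN percentile ranking (with count 0) and receive CC $= 0$; output rows
  are flagged. This keeps the per-variant contract total.
* **CS formulation.** The single-column specialization of $\Delta S$; the
  conservation score it stands in for is only described verbally in the
  method literature, so this analog is an assumption, stated as such.
* **ROC conventions.** Standard TPR $= TP/(TP+FN)$ and FPR
  $= FP/(FP+TN)$; AUC is the Mann–Whitney concordance probability with
  ties counted $1/2$, which equals trapezoidal ROC integration (verified
  against both a brute-force pair count and `pROC`).
* **Percentile normalization** is computed per protein over residues (not
  over variants), which is what makes CN distributions comparable across
  proteins.

## Problem sizes used in validation

The test and acceptance suites run entirely on synthetic data at desk
scale: toy alignments (4–10 sequences) for exact-oracle comparisons; the
coupling-recovery benchmark at $L = 50$, $N = 200$, 3 planted pairs over 50
seeds; the CE benchmark pooling 10 alignments of $L = 60$, $N = 200$; and
one realistic-size covariation run at $L = 300$, $N = 200$. Monte-Carlo
cross-validation examples use 100 repeats of 90/10 splits.

## Known limitations

* McBASC with plain Pearson estimation is sensitive to phylogenetic
  redundancy; with highly related homolog sets the couplings reflect shared
  ancestry as much as compensation. The homolog identity filter mitigates
  but does not remove this.
* The $+1$ smoothing in $\Delta S$ makes CC depend on alignment depth $N$;
  scores from alignments of very different depths are not directly
  comparable (CN's percentile normalization addresses this for CN only).
* No direct-coupling analysis: indirect (transitive) correlations are not
  deconvolved, by design — the method uses coupling *number*, not coupling
  strength, and is complementary to strength-based predictors.
* The random-forest integration reported alongside the union rule in the
  method literature is out of scope here; `monteCarloCV()` implements the
  threshold-union integration only.
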