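# coevoscore

Coevolution-based impact scores for protein missense variants.

Conservation-based predictors (SIFT-style) miss deleterious variants at
less-conserved sites — allosteric residues, specificity-determining
positions, protein–protein interfaces — where substitutions are tolerated
across evolution only because *compensatory* changes occur at cooperating
sites. Those compensations make the substitution patterns of alignment
columns covary. `coevoscore` turns that signal into a per-variant score for
anyone with a query-anchored multiple sequence alignment (MSA) and a list
of variants in protein coordinates.

## The score

For a query protein of length *L*:

1. **Covariation**: McLachlan-based substitution correlation (McBASC)
   between every pair of retained alignment columns — the Pearson
   correlation, over unordered sequence pairs, of McLachlan (1972)
   similarity vectors.
2. **Couplings**: the top **2L** column pairs by covariation are the
   protein's evolutionary couplings; residue *i* has partner set *C_i*.
3. **CN** (coupling number): |C_i|, percentile-normalized to [0, 1] within
   the protein — 1 is the most coupled residue.
4. **CC** (cost of coupling) of a variant α→γ at residue *i*, with β the
   query residue at partner *j* and *n* the column-pair amino-acid counts:

   ΔS_ij(α→γ) = −ln[(n_ij(γ,β) + 1) / n_ij(α,β)],  CC_i = Σ_{j∈C_i} ΔS_ij / |C_i|

5. **CE = CN × CC** — high when a *highly coupled* site receives a
   substitution whose new residue pairings are *rare* among homologs.

A single-column conservation analog (CS), the standard MSA filters (>20%
gap columns, invariant columns, homolog identity/length filters), a full
evaluation stack (ROC/AUC, accuracy-maximizing thresholds, union-rule score
integration, Monte-Carlo cross-validation), and a synthetic coevolving-MSA
generator are included.

## Worked example

Score variants on a synthetic alignment with a planted cooperative coupling
group (columns 5, 12, 23, 31), one planted covarying pair (8, 19), and a
conserved column (27):

```r
library(coevoscore)

sim <- generateCoupledMsa(
  L = 40, N = 150,
  plantedPairs = list(plantedClique(c(5, 12, 23, 31), w = 0.9),
                      plantedPair(8, 19, w = 0.9)),
  conserved = list(list(col = 27, aa = "G", freq = 0.95)),
  gapRate = 0.05, seed = 7)

scoreVariants(sim$alignment, c("M5W", "M5A", "G27W", "T37W"))
```

```
  token position wt alt couplingCount nPartners    CN   CC   CE flags     CS
1   M5W        5  M   W             6         6 0.872 3.52 3.07        4.174
2   M5A        5  M   A             6         6 0.872 1.36 1.19       -0.208
3  G27W       27  G   W             3         3 0.282 3.51 0.99        4.890
4  T37W       37  T   W             4         4 0.449 2.62 1.18        3.761
```

Reading the output: position 5 sits in the planted coupling group, so its
coupling number is high (CN 0.87). Mutating it to a residue never seen at
its partners (M5W) is evolutionarily costly (CC 3.52) and CE = 0.87 × 3.52
= 3.07 flags the variant. Mutating the same site to the *compensatory*
state residue (M5A) is cheap (CC 1.36, CE 1.19): the method knows which
substitutions the family has already absorbed — note CS cannot tell the
two apart in the right direction (CS −0.21 for M5A). Conversely the merely
*conserved* site 27 gets a high conservation score (CS 4.89) but a low CE
(0.99): it is conserved, not coupled. `CE = CN * CC` holds exactly on
every row.

File-based use: `readAlignment("family.fasta")` (aligned FASTA, A2M, or
Stockholm; the query defaults to the first record and all coordinates are
query-anchored), `parseVariants("vars.tsv")` (tokens like `K329E` or a
3-column TSV). A command-line wrapper with `compute`, `evaluate`, and
`simulate` subcommands is installed at
`system.file("scripts", "ce-score", package = "coevoscore")`.

## Scope notes

Homology search and alignment construction (PSI-BLAST, MUSCLE) are outside
the package: it consumes precomputed alignments or unaligned homolog sets.
See `vignettes/coevolution-scoring.Rmd` for the model, parameter defaults,
numerical conventions, and known limitations.
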