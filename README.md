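# cladesig

Comparative-genomics toolkit for deciding where a fast-evolving taxon
belongs in a reference phylogeny — the question posed, classically, by the
mycoplasmas (class *Mollicutes*), whose long branches destabilise trees and
whose placement among the low-G+C Gram-positive bacteria has to be argued
from several independent directions at once. cladesig implements those
directions as one tested pipeline:

* **Column signature statistic** — per alignment column, composition
  vectors **a**, **b** over the standard residue alphabet are compared by
  `S = ||a/||a|| − b/||b||||² = 2(1 − cos θ) ∈ [0, 2]` (0 = identical
  usage, 2 = disjoint residue sets), then weighted by the column's non-gap
  fraction `g` and half the conservation difference `d` to give
  `M = S·g·d/2 ∈ [0, 1]`. Group comparisons resample 10 taxa per group for
  1000 replicates and report mean ± sd, with a two-standard-deviation rule
  for calling the closest group.
* **Clade coherence of gene trees** — `min_clade_cover()` finds the minimum
  number of disjoint clades covering a taxonomic group, each clade
  tolerating up to 5 intruding leaves (horizontal-transfer allowance);
  one clade = monophyletic. `coherence_table()` sums cover sizes over
  reference groups per tree and contrasts trees with a monophyletic vs
  polyphyletic focal group (Welch one-sided t-test).
* **Alignment curation** — trim to the conserved core (>33% column
  conservation), detect variable regions (≥10 consecutive columns <33%),
  mask single-sequence insertions.
* **Gap profiles** — per-position gap frequencies of a taxon group in
  ungapped reference coordinates, seven-colour binning, and a
  region-absence test (e.g. the 16S V6 stem–loop, positions 1025–1036).
* **Codon-usage matching** — within-family chi-squared test of each gene
  against a modal usage (match at P ≥ 0.1), iterative modal-usage
  estimation, native/non-native partition for horizontal-transfer
  detection, mean coding G+C.
* **Dollo loss mapping** — minimum single-origin loss events for binary
  traits on a rooted tree (one loss per maximal all-absent clade).
* **Synthetic data** — seeded generators with ground truth for every
  stage: planted signature columns, fragmented focal clades salted with
  intruders, codon-usage mixtures, independent trait losses.

See the vignette (`vignettes/taxon-placement.Rmd`) for the models,
assumptions and design decisions.

## Worked example

```r
library(cladesig)

# A two-group alignment with 10% planted signature columns on a conserved core
sim <- simulate_alignment(n_per_group = 15, n_columns = 200,
                          categories = c(signature = 0.1, conserved = 0.7,
                                         random = 0.2),
                          conservation = 0.9, seed = 42)
compare_phyla(sim$alignment, sim$grouping, "A", "B",
              n = 10, reps = 200, seed = 42)
#> Signature comparison A vs B: 0.104+/-0.002 (n=10, 200 replicates)

# Coherence summary of the bundled AARS subtree counts
tab <- aars_subtree_counts()
coherence_summary(tab$cells, focal = "mollicutes_erysipelotrichia")
#> Clade-cover coherence table: 18 trees, focal group 'mollicutes_erysipelotrichia'
#>   monophyletic trees (n=8): mean sum 19.9 +/- 2.6 (sem)
#>   polyphyletic trees (n=10): mean sum 31.4 +/- 2.6 (sem)
#>   one-sided Welch t-test (poly > mono): t = 3.11, P = 0.0035

# Dollo losses for one trait
tr <- read_tree(text = "((a,b),(c,(d,e)));")
dollo_losses(tr, c(a = TRUE, b = FALSE, c = TRUE, d = FALSE, e = FALSE))
#> Dollo loss map: 2 loss event(s)
#>   loss 1: clade {b}
#>   loss 2: clade {d, e}
```

Reading the output: the resampled signature score 0.104 ± 0.002 sits well
above the conserved-core null (≈ 0.013 at these settings) because a tenth
of the columns distinguish the groups; the mean column score of a planted
signature column is 1, so a 10% planted fraction plus residual noise from
the free columns lands near 0.10. In the coherence table, trees in which
the focal group stays together (8 of 18) need markedly fewer subtrees to
describe seven reference groups (19.9 vs 31.4 on average) — those trees are
the more taxonomically reliable witnesses. The loss map places the two
independent losses on the pendant branch of `b` and the `(d,e)` clade.

## Command line

A thin CLI over the same functions ships in `inst/scripts/cladesig.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "cladesig.R", package = "cladesig"))')" \
  simulate --type alignment --seed 3 --out-dir out/
```

Subcommands: `simulate`, `prep`, `signature`, `gap-profile`, `coherence`,
`codon`, `losses`. Every run writes its resolved configuration
(`run_config.yaml`) next to its outputs.

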