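---
title: "Placing a fast-evolving taxon: column signatures, clade coherence and loss mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placing a fast-evolving taxon: column signatures, clade coherence and loss mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladesig)
```

## The problem

Lineages that evolve unusually fast — classically the mycoplasmas
(class *Mollicutes*) — accumulate so many substitutions that their long
branches destabilise phylogenetic inference, and their placement relative
to slower-evolving relatives (such as the walled *Erysipelotrichia* within
the *Firmicutes*) becomes contentious. cladesig implements a set of
complementary, tree- and alignment-based analyses that attack the placement
question from independent directions:

* a **conservation-weighted column signature statistic** that asks, per
  alignment column, how well the column distinguishes two taxon groups;
* a **clade-coherence metric** for gene trees — the minimum number of
  disjoint clades needed to encompass a taxonomic group, with an allowance
  for horizontally transferred intruders;
* **gap-frequency profiles** of rRNA alignments in ungapped reference
  coordinates, including a region-absence test (e.g. the V6 stem–loop);
* **codon-usage matching** of genes against modal usages for detecting
  horizontally acquired ("non-native") genes;
* **single-origin (Dollo) parsimony** mapping of binary trait losses onto a
  rooted tree.

Each stage has a seeded synthetic-data generator that emulates its input
with known ground truth, so the whole pipeline is testable without any
external data.

## The column signature statistic

For one alignment column and two taxon groups A and B, the counts of each
standard residue (4 nucleotides or 20 amino acids) among each group's rows
form composition vectors $\mathbf{a}$ and $\mathbf{b}$. The base statistic
is the squared distance between the unit-normalised vectors,

$$S \;=\; \left\lVert \tfrac{\mathbf{a}}{\lVert\mathbf{a}\rVert} -
\tfrac{\mathbf{b}}{\lVert\mathbf{b}\rVert} \right\rVert^2
\;=\; 2\,(1 - \cos\theta) \;\in\; [0, 2],$$

which is 0 when the two groups use residues in proportional frequencies and
2 exactly when their residue sets are disjoint (orthogonal vectors). $S$ is
deliberately insensitive to *within*-group conservation: an A/T-alternating
group against a G/C-alternating group scores the same 2 as two fully
conserved disjoint columns.

Because conserved columns carry the most information about deep ancestry,
the modified score reweights $S$ twice:

$$M \;=\; S \times g \times \frac{d}{2} \;\in\; [0, 1],$$

where $g$ is the fraction of sampled characters in the column that are
non-gap, and $d$ is the **conservation difference**: the largest
within-group residue frequency found in either group minus that residue's
frequency in the other group. For A = [W,W,W,Y] and B = [A,L,V,W] the top
frequency is W at 0.75 in A; W occurs at 0.25 in B, so $d = 0.5$. $M = 1$
requires disjoint residue usage, full conservation in at least one group
and no gaps.

Conventions worth knowing:

* Ambiguity codes (IUPAC nucleotide codes beyond ACGT; X/B/Z/J/U/O for
  proteins) count as gaps in every statistic — only the standard residue
  alphabet enters the composition vectors.
* A column in which either group has no residues cannot be compared; it is
  flagged `skipped` and excluded from column averages.
* When several (residue, group) pairs tie for the maximum frequency, $d$
  takes the pair giving the largest difference, with ties broken by
  alphabet order and then group order, so results are deterministic.

### Group comparisons by resampling

`compare_phyla()` implements the group-level protocol: draw `n = 10` taxa
from each group uniformly without replacement, average $M$ over usable
columns, and repeat for `reps = 1000` replicates (sd uses denominator
$R-1$). When the grouping carries species ids, one strain per species (the
lexicographically smallest taxon id) is kept before sampling. A set of
comparisons against one focal group is summarised by
`closest_group_call()`: the group with the smallest mean is closest, and
group $i$ is "within two standard deviations" of the closest group $m$
when $|\bar{x}_i - \bar{x}_m| \le 2\sqrt{s_i^2 + s_m^2}$.

### Null behaviour and calibration

The statistic has a small-sample null bias: when both groups are drawn from
one shared composition with *no* conservation, sampling noise alone yields
a mean $M$ of roughly 0.07 at $n = 10$ per group; the null mean falls
toward 0 as the shared conservation rises, because the conservation
difference $d$ vanishes when both groups agree on the consensus. The
calibration tests therefore model the null as a curated core alignment —
80% conserved-shared columns and 20% free columns — which is what the
method sees in practice: the curation filters (below) trim alignments to
regions exceeding 33% conservation, and the conserved cores of rRNA and
aminoacyl-tRNA synthetase (AARS) alignments are dominated by conserved
positions. Under that null the resampled mean is ≈ 0.013; on fully planted
disjoint columns it is exactly 1. Comparisons between groups should be read
relative to such a baseline, not against an idealised 0.

## Alignment curation filters

Three filters precede signature analysis, all operating on per-column
conservation (the fraction of non-gap rows sharing the most frequent
residue; undefined for all-gap columns):

* `trim_to_conserved()` removes leading **and trailing** columns up to the
  first/last column whose conservation strictly exceeds the threshold
  (default 0.33). The symmetric treatment of both ends is this package's
  reading of end-trimming; alignment ends are where sequence starts
  misalign regardless of orientation.
* `find_variable_regions()` reports maximal runs of at least `min_run = 10`
  consecutive columns below the threshold, as 1-based closed intervals.
  Columns with undefined conservation count as unconserved. Realignment of
  the detected regions is out of scope — the package only detects and
  reports them.
* `mask_single_sequence_insertions()` replaces columns with exactly one
  residue-bearing row by gaps everywhere. The operation preserves alignment
  length and is idempotent.

## Gap profiles in reference coordinates

`gap_frequencies()` computes, for each position of an ungapped reference
sequence (*E. coli* numbering, in the 16S use case), the fraction of a
group's rows that are gapped in the corresponding column. Columns where the
reference itself is gapped (insertions relative to the reference) are
excluded. Frequencies are binned into seven classes with half-open
boundaries $[0, 0.001), [0.001, 0.05), [0.05, 0.2), [0.2, 0.35),
[0.35, 0.5), [0.5, 0.75), [0.75, 1]$ — at face value the conventional
legend's categories overlap at 0.75, so the top bin is closed to make the
bins a partition; a frequency of exactly 0.75 is "red".

`region_absent()` tests whether a taxon completely lacks a reference
interval (e.g. the V6 stem–loop, positions 1025–1036): every mapped
position must be a gap. A tolerance (default 0) admits lightly occupied
intervals for curation noise.

## Clade coherence of gene trees

Given a gene tree rooted on an outgroup (`root_on_outgroup()`),
`min_clade_cover()` computes the minimum number of pairwise-disjoint clades
whose union contains every leaf of a taxonomic group, where each chosen
clade tolerates up to `budget = 5` foreign ("intruder") leaves — an
allowance for horizontal transfer into the group. A group coverable by one
clade is monophyletic in this relaxed sense; needing more clades makes it
polyphyletic.

Because the clades of a rooted tree form a laminar family, the per-clade
budget optimum has a clean form: it equals the number of *maximal*
budget-eligible clades containing at least one group leaf. These are
pairwise disjoint, no single eligible clade can contain two of them, and
every group leaf sits in one (a leaf alone is a clade with zero foreign
leaves). The implementation does one preorder pass; tests verify it against
an exhaustive search over all disjoint covers.

The budget phrase "up to five unrelated sequences in a group" is ambiguous
between per-clade and whole-cover accounting; `mode = "per-clade"` is the
default and `mode = "total"` implements the alternative reading via an
exact dynamic program with the foreign budget as knapsack state. Cover
size is monotone non-increasing in the budget in both modes. When several
optimal covers exist, the reported one prefers larger clades, with ties
broken by smallest leaf label.

`coherence_table()` fills a trees × groups table of cover sizes, sums each
tree's row over the *reference* groups (missing cells — groups
underrepresented in a tree — are excluded from that row's sum), partitions
trees by whether the focal group's cell equals 1, and compares the two
partitions' sums with a one-sided Welch two-sample t-test (polyphyletic
mean larger). Welch's test is used because the partitions are small and
their variances need not be equal; the standard error of the mean uses
denominator $n-1$. The package ships a reference dataset
(`aars_subtree_counts()`) of subtree counts for 18 AARS protein trees and
eight taxonomic groups, whose summary reproduces the published per-tree
sums (e.g. Ala 14, Trp 52), partition means 19.9 ± 2.6 (sem, 8 trees)
versus 31.4 ± 2.6 (10 trees), and a significant one-sided difference
(P < 0.05).

## Codon-usage matching

`chisq_match()` compares a gene's codon counts to a reference usage
*conditionally on the gene's amino-acid composition*: within each
synonymous family the expected count of a codon is the family's observed
total times the reference frequency of that codon within the family. This
removes protein composition from the comparison, leaving pure synonymous
preference. Families with fewer than two synonyms (Met, Trp) or fewer than
two observations contribute nothing; degrees of freedom add
(synonyms with positive expectation − 1) per contributing family; no
continuity correction is applied. A gene matches when the upper-tail
p-value is at least 0.1. Genes with no contributing family are flagged
untestable and excluded from match percentages.

`modal_usage()` estimates the usage matched by the largest number of a
genome's genes: initialise at the genome-total usage, then alternate
testing all genes and re-estimating the profile from the matching genes'
pooled counts until the matched set stabilises. On strong mixtures (a
large horizontally acquired fraction with very different usage) the
genome-total profile can be matched by no gene; the iteration then reseeds
from the best-agreeing tenth of the genes and continues, which lets the
mode be climbed from the densest region of usage space rather than the
mixture average. The matched-set size typically grows and then settles,
but can shed an occasional gene as the profile sharpens — stabilisation,
not monotonicity, is the convergence criterion.

`native_partition()` labels genes matching their own genome's modal usage
native (candidates for vertical inheritance) and the rest non-native
(candidates for horizontal acquisition). `percent_matching_any()` scores a
genome against a panel of reference modal usages. `mean_gc()` reports the
unweighted mean per-gene G+C percentage of a coding-sequence set.

Only the standard genetic code is used. This is a documented limitation
for mycoplasmas, which recode UGA as tryptophan; since stop codons are
excluded from counts, UGA-Trp usage is simply invisible to the statistic
rather than mis-assigned.

## Dollo loss mapping

`dollo_losses()` assumes a binary trait was present in the root ancestor
and can only be lost (single-origin parsimony, the natural model for
multi-gene pathways whose repeated re-invention is implausible). The
minimum-loss reconstruction places one loss on the edge subtending each
maximal all-absent clade; the count is provably minimal under the
single-gain constraint, and a polytomy with several all-absent children
yields one loss per child. An all-absent trait is an error (the origin
cannot be placed). `loss_table()` applies this per trait and reports the
range of loss counts.

Note an identifiability limit that the synthetic-data tests respect: two
sibling losses that jointly delete their entire parent clade leave the same
tip pattern as one ancestral loss, so no single-origin method can recover
them separately. Planted-truth tests therefore require planted losses to be
non-nested *and* to leave a present tip in each loss branch's parent clade.

## Synthetic data generators

All generators are pure functions of their arguments including an integer
seed, and return ground-truth labels alongside the data.

* `simulate_alignment()` plants three column categories: `signature`
  (disjoint residue halves between groups, conserved at level
  `conservation` within each group), `conserved` (one residue shared by all
  rows — these columns score exactly 0) and `random` (uniform residues).
  Cells are gapped independently with `gap_prob`. The defaults (80%
  conserved-shared for null alignments) emulate a trimmed conserved core;
  what the generator does *not* model is phylogenetic autocorrelation
  among rows, indel structure, or rate variation along the sequence, so a
  passing calibration bounds sampling noise, not model misspecification on
  real alignments.
* `simulate_tree()` arranges random binary background blocks and focal
  fragments along a ladder backbone, grafts each fragment's intruders
  strictly inside it, and attaches an outgroup at the root (branch lengths
  are all 1; every metric here is topology-only). The construction
  guarantees the planted fragment count is exactly the number of maximal
  focal clades, and is recoverable by `min_clade_cover()` whenever
  intruders per fragment ≤ budget < smallest separating block
  (≈ background/(fragments+1) leaves).
* `simulate_genes()` draws amino acids uniformly over the 20 families and
  synonymous codons multinomially from a profile; a fraction of genes uses
  a second, "foreign" profile. Stock profiles range from realistic 3:1
  weak-ending biases (`at_rich`, typical of low-G+C firmicutes) to
  disjoint-support pairs (`at_only`/`gc_only`) for planted-transfer
  scenarios. At 300 codons per gene the within-family chi-squared test
  runs near its nominal level (≈ 90% matches at P ≥ 0.1 against the
  generating profile); shorter genes lose power and are flagged, not
  dropped.
* `simulate_losses()` loses each trait independently on every branch with a
  fixed probability; tips below any loss are absent.

## Problem sizes and numerical choices

The test suite exercises: exhaustive clade-cover equivalence on 200 random
trees of 5–12 leaves at budgets 0/3/5 in both modes; planted-fragment
recovery over 100 seeds × {1,2,3} fragments × {0,5,6} intruders at budget
5; null/planted signature calibration at 20 taxa per pool, 300 columns,
200 replicates; codon calibration at 500 genes × 300 codons; and
exhaustive Dollo equivalence on 100 random trees of 5–10 leaves. These
sizes were chosen so each property is measured well inside its sampling
noise while the whole suite runs in about a minute.

Numerical conventions: $S$ is computed as $2(1 - \cos\theta)$ so disjoint
supports give exactly 2 in floating point; frequencies are compared for
ties by exact double equality (safe because correctly rounded ratios of
equal rationals are identical); all user-facing coordinates are 1-based
closed intervals; and resampling uses R's default generator with one
`set.seed()` per entry point.

## Limitations

* The signature statistic's null bias at low conservation means absolute
  scores are only comparable between alignments of similar conservation
  and gap structure.
* The clade-cover metric conditions on the tree being correct; it measures
  coherence, not uncertainty, and carries no branch support.
* Codon-usage matching assumes the standard code and equilibrium usage;
  recently acquired genes ameliorate toward host usage over time and
  eventually become undetectable.
* Dollo mapping cannot separate losses that merge in the tip pattern (see
  above) and does not model trait regain.
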