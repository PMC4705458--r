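---
title: "Circumscribing candidate taxa for uncultured marine microbes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circumscribing candidate taxa for uncultured marine microbes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctuscope)
```

## The problem

Environmental SSU rRNA surveys of the ocean are dominated by sequences
from organisms that have never been cultivated and therefore have no
place in classical taxonomy. `ctuscope` circumscribes *candidate
taxonomic units* (CTUs) for this unnamed diversity: clusters of
sequences that satisfy a rank-specific identity threshold **and** form a
monophyletic clade on a phylogenetic tree, named in a standardized
format so they can be referred to, counted, and screened ecologically.
The package consumes the artifacts a curated rRNA database pipeline
produces (aligned FASTA with metadata, Newick trees with outgroups,
clade-by-sample count tables); it does not build alignments, infer
trees, or classify amplicons.

## The model and its stages

### Marine mining

A sequence enters the analysis set when

* its **isolation source** text classifies as marine water column under
  an ordered keyword rule set (exclusion patterns first, so "marine
  sediment" or "soil under seawater tank" can never leak in through a
  marine keyword; empty or untraceable sources are non-marine);
* its **organism name** marks it as environmental ("uncultured",
  "clone", ...) and its strain field is empty or clone-like — a
  culture-collection strain such as "DSM 1234" overrides the name;
* it passes **quality filters**: Pintail ≥ 75, sequence quality ≥ 75,
  alignment quality ≥ 90 (inclusive, as "minimum of" thresholds), and
  ungapped length strictly above 1200 bp (Bacteria) or 900 bp
  (Archaea). Missing quality values fail: only vetted sequences are
  retained.

Guide-tree clades are selected wholesale under the 50% rule: a clade
with at least half marine water-column members, the remainder drawn only
from other marine sources, is marked entirely; a single non-marine
member disqualifies it. The denominator is all clade members, before
quality filtering, since traceability and vetting are separate
questions. The original study's exact keyword expression is not public;
the shipped vocabulary is an editable stand-in, and the synthetic
metadata generator draws from the same vocabulary, which is why mining
is self-consistent (100% precision/recall) on fixtures — a property of
the fixture world, not evidence about real SILVA metadata.

### Identity clustering

Columns pass a 10% base conservation filter: a column is kept iff its
most frequent unambiguous base (T≡U) occurs in at least 10% of all
sequences, gaps counting in the denominator. Pairwise identity is
`matches / comparable columns` over kept columns where both sequences
carry unambiguous bases; terminal gap runs, internal gap columns and
ambiguity codes are excluded, and a pair with no comparable columns gets
distance 100. The reference clustering tool's exact gap handling is
version-dependent and undocumented; this definition is declared here and
frozen by tests rather than inferred from source.

Clustering is agglomerative **furthest neighbor** (complete linkage):
the distance between clusters is the maximum member distance, and the
pair at minimum distance merges first. Ties are broken by the smallest
member id (then the partner's smallest id), making the merge history a
pure function of the distance matrix. Nested partitions are cut at the
rank cutoffs `100 − identity`:

| rank | identity % | cutoff |
|---|---|---|
| Phylum | 75 | 25 |
| Class | 78.5 | 21.5 |
| Order | 82 | 18 |
| Family | 86.5 | 13.5 |
| Genus | 94.5 | 5.5 |

Merges at exactly the cutoff join (≤, with 10⁻⁹ absolute tolerance).
Complete linkage is monotone, so the partitions are provably nested, and
the suite checks the whole path against a brute-force oracle and against
an independent implementation (`stats::hclust`) on tie-free matrices.

### CTU recognition and naming

The tree is rooted on the outgroup's MRCA edge; if the outgroup is not
monophyletic the edge placing most outgroup leaves (fewest in-group
leaves on ties) on one side is used, with a warning. Outgroup leaves
never join CTUs. Each in-group leaf is colored by its OTU id; a CTU is a
**maximal monochromatic clade**: a node whose in-group descendants share
one OTU id, under a parent whose in-group descendants do not. Only whole
tree nodes count, so a monochromatic subset of a polytomy's children
yields one component per child subtree — unresolved nodes are never
silently resolved. Consequently a coherent OTU gives one CTU and a
polyphyletic OTU splits into components.

Names are `<Context>.<Rank><otu>` or `<Context>.<Rank><otu>-<component>`
when the OTU split. Both OTU numbers and component numbers are assigned
in preorder of the rooted tree (first-encountered leaf), so names do not
depend on input record order. Without a context taxon, phylum-rank CTUs
are named `Phylum<k>` and serve as context for their descendants
(`Phylum1.Order1`). The hyphen-suffix semantics — components of one
split OTU — are an interpretation of the published figures, flagged as
such. A CTU is `known` when **any** member carries a known-clade
annotation, because masking removes whole clades that contain known
material; everything else remains a novel candidate, and summary counts
are reported both in total and restricted to CTUs with ≥ 2 sequences
(singletons are named but flagged).

### Clade ecology

Counts aggregate to relative abundance at the analysis rank (order by
default), unclassified mass tracked separately. The site-association
test uses the difference of means statistic — mean relative abundance in
the target category minus the mean elsewhere — with a one-sided
permutation null: `p = (1 + #{perm ≥ obs}) / (n_perm + 1)`, permutations
shared across clades and categories within a call so a seed reproduces
every p-value bit-exactly. The published analysis names an indicator
species package without specifying the statistic variant; the difference
of means matches the verbal null ("relative frequency not higher in the
target group") and is the default, with an IndVal-style `sqrt(A × B)`
variant behind a flag. No multiplicity correction is applied by default
(reported tables used raw p < 0.05); Benjamini–Hochberg is available.
Spearman correlations use midranks and the t-approximation
`t = ρ√((n−2)/(1−ρ²))`, missing values excluded pairwise, pairs with
fewer than 3 complete observations or zero variance skipped with a
reason.

## What the synthetic world is — and is not

The generator's defaults are a fixed "smoke" world: 120 in-group
sequences in 3 orders × 2 families × 2 genera × 10 leaves, 5 cultivated
outgroup sequences, alignment length 1200, 10% contaminant metadata, 40
samples in 4 water-body categories at 10,000 reads, a 5-fold indicator
enrichment and one monotone depth gradient. Trees are ultrametric with
node heights chosen so *expected* observed distances sit at the planted
divergences (2 / 8 / 15.75 / 23 percent within genus / between genera /
between families / between orders — each at least 2 points clear of the
genus, family and order cutoffs). Because Jukes–Cantor transition
probabilities compose exactly along paths, planting heights in
substitution units gives the intended expected distances without
approximation.

Three deliberate asymmetries of this world:

* **Domain is archaeal by default.** The bacterial length rule is strict
  (> 1200 bp) and the alignment is 1200 columns, so a bacterial default
  world would fail its own length filter once gap columns are injected.
  The archaeal rule (> 900 bp) matches the fixture scale; the bacterial
  branch of the filter is exercised by explicit unit fixtures instead.
* **Class/phylum structure is unconstrained.** The gap between the order
  (18) and class (21.5) cutoffs is only 3.5 points, so no placement of
  the between-order divergence can hold a 2-point margin on both sides.
  Recovery guarantees therefore cover genus, family and order — the
  ranks the downstream analyses use — and between-order divergence sits
  at 23, leaving class and phylum composition free to vary by seed
  (which also means phylum-level OTUs can legitimately split across the
  in-group root polytomy and carry component suffixes).
* **Realized margins are enforced, not assumed.** Complete linkage
  reacts to the extreme realized pairwise distance. At length 1200 the
  binomial noise of a single pair is about ±1 point, and the maximum
  over the ~400 cross-family pairs inside an order overshoots its
  expectation by 1.5–2 points, so with expected distances alone the
  order cutoff would be crossed in roughly a third of seeds. The bundle
  generator therefore checks, per fixture, that realized distances
  bracket the genus/family/order cutoffs (with a 0.25-point guard band
  absorbing conservation-mask differences between the full and mined
  sequence sets) and regenerates from the next derived seed if not —
  deterministically, so a bundle is still a pure function of its
  parameters. The attempt number and realized extremes are recorded in
  `realized_margins.tsv`.

The world does **not** emulate chimeras, alignment error, primer or
classification bias, non-uniform base composition, rate variation, or
correlated environmental gradients. A green recovery test establishes
that the pipeline's logic is correct under its stated assumptions — not
that real SILVA data are this clean.

Ecology noise is a single shared Dirichlet baseline with per-sample
Dirichlet overdispersion (precision 200) and multinomial counting;
`dispersion = 0` switches to deterministic expected counts, which is the
regime where the "noiseless monotone gradient ⇒ ρ = 1" limit holds
exactly. Sequencing depth (10,000) matters only through relative
structure.

## Numerical choices

* Cutoff inclusivity ≤ with 10⁻⁹ tolerance; quality thresholds
  inclusive, length thresholds strict, mirroring "minimum of 75" versus
  "> 900 bp" phrasing.
* Tie-breaks in agglomeration are lexicographic on member ids; OTU ids
  from `cut_partitions()` number by first member in record order, while
  *names* renumber in tree preorder — the former keeps the clustering
  module self-contained, the latter makes names input-order invariant.
* Permutation p-values can never drop below `1/(n_perm + 1)`; the
  default 999 permutations bound p at 0.001 (the published permutation
  count is unstated).
* Degenerate inputs: empty conservation mask, fewer than 2 sequences,
  all-gap pairs (distance 100), zero-read samples (excluded with
  warning), constant rows in min–max scaling (mapped to 0), zero-variance
  correlation pairs (skipped) all have declared behavior under test.

## Known limitations

* The keyword vocabulary is a stand-in; real SILVA isolation-source text
  is messier than any fixed list.
* Distances are alignment-based only; no model correction beyond the
  observed-identity definition (the thresholds are defined on identity,
  so this is intentional).
* Very large inputs: the distance matrix is dense O(n²) and clustering
  O(n³) in pure R — adequate for per-phylum sets of a few thousand
  sequences, not for the full database.
* The per-phylum workflow of the original study (one tree per phylum,
  conservation filter per phylum) is respected in spirit: the pipeline
  treats whatever sequence set it is given as one analysis unit.
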