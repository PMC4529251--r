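---
title: "Mapping duplication waves and hybridization signals in phylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping duplication waves and hybridization signals in phylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A whole-genome duplication (WGD) leaves a cohort of paralog pairs
("ohnologs") that all duplicated in the same period. Given a *phylome* --
the collection of gene-family trees for every gene of a seed genome --
each duplication node can be dated *relatively*: it must be younger than
the lineages that branched off before it and older than the lineages that
diverged after it. Mapping every duplication onto a reference species tree
and normalizing per branch yields a duplication-density profile whose
peaks mark bursts of duplication.

The twist this package is built around is the allopolyploidy signature.
If the genome doubling arose from an *interspecies hybridization*, the two
homeologous gene copies are not true paralogs: they coalesce at the
divergence of the two parental lineages, which necessarily predates the
hybridization itself. A phylome from an ancient allopolyploid therefore
shows a duplication peak *older* than the event, at the parental
divergence branch, and its genes affiliate with two different sister
lineages roughly evenly. An autopolyploid shows neither: its peak sits on
the event branch and its genes group overwhelmingly with the closest
relative. `hybridscan` implements the detection machinery, the
classification of sister-clade affiliations, divergence and synteny
corroboration, and a simulator that generates phylomes under either
scenario with known ground truth.

## Duplication detection and age mapping

A node of a rooted gene tree is called a **duplication** by the
species-overlap rule when at least one pair of its child subtrees shares a
species: one species on both sides of a split can only be explained by a
duplication at or above it. The event's relative age is the species-tree
MRCA of all species below the node, and the event is assigned to the
branch above that MRCA (`detect_duplications()`). On multifurcations the
rule generalizes naturally: any child pair sharing a species marks the
node; each node yields one event regardless of how many species recur.

As an independent mapper, `lca_reconcile()` implements classical LCA
reconciliation: `M(node)` is the species-tree MRCA of the node's
descendant species, and a node is a duplication iff it maps to the same
species-tree node as one of its children. On binary, loss-free gene trees
the two mappers provably coincide, which the test suite exercises on
hundreds of simulated trees; reconciliation is restricted to binary trees
and refuses polytomies.

**Density normalization.** For a seed-lineage branch `b`,
`density_profile()` divides the duplications mapped to `b` by the number
of *informative* trees: those containing at least one species that
diverged before `b`. A tree with no species older than `b` cannot witness
a duplication at `b`, so such trees are excluded from the numerator as
well -- otherwise a branch's density could exceed one duplication per
informative gene. The root is the mapping point for events older than
every split; "deeper than the root" being empty, every tree counts as
informative there. Densities over an empty denominator are reported `NA`,
never 0.

**Supports.** Supports are stored in `[0, 1]`; values above 1 are treated
as percentages and divided by 100 at parse time, so one threshold
semantics serves aLRT-like, bootstrap, and posterior supports. Wherever a
threshold applies, a node with *missing* support fails the filter -- the
conservative reading of "only clades with support above the threshold are
considered". Defaults: 0 (no filter) for whole-phylome densities, 0.95
for ohnolog-pair analyses, 0.5 for the monophyly consistency test.

## Sister-clade topology classification

`classify_seed_topology()` formalizes the A/B/C scan. A tree is
`excluded` when it lacks homologs of parental clade A, of clade B, or of
the outgroups -- without all three the placement question is undefined.
Otherwise the tree is rooted with the outgroups and the seed sequence's
sister clade is read off: all sister species in clade A gives `A`, all in
B gives `B`, a mix of both gives `C`. Calls whose enclosing clade falls
below the support threshold are `unsupported`.

Two design points were genuinely open and are resolved as follows:

* **Sister of a seed paralog.** In complete phylomes the immediate sister
  can consist solely of further seed-species paralogs; the scan then
  ascends until a clade containing non-seed species is found. Reduced
  phylomes exclude seed paralogs by construction, so the rule is inert
  there.
* **Outgroup-containing sisters.** `C` means a ZT/KLE-style *parental*
  mix only; a sister containing any outgroup species is classified
  `excluded`, not `C`.

For conserved ohnolog pairs, `classify_ohnolog_pair()` classifies each
copy separately after pruning the other copy, and annotates whether the
pair is monophyletic (its joint MRCA clade contains no parental
sequence). The nine labels follow: same-letter calls with suffix `1`
(monophyletic -- post-event divergence or gene conversion) or `2`
(non-monophyletic), plus the unordered mixed labels `A-B`, `A-C`, `B-C`.
The suffix semantics are this package's operationalization of the
nine-topology scheme; sources differ in detail and the choice is recorded
here deliberately.

## Divergence measures

`kimura_distance()` implements the protdist-style Kimura protein
distance: with `D` the fraction of differing sites over gap-free columns,
`d = -ln(1 - D - D^2/5)`. Columns with a gap in either sequence are
excluded from `D`. The correction saturates near `D = 0.85`; a saturated
pair raises an error at the single-pair level, while
`distance_matrix()` substitutes a finite ceiling (below). The normalized
alignment score divides the global BLOSUM62 score (affine gaps, open 11,
extend 1) of seed vs partner by the seed's self-score; only this ratio is
meaningful, standing in for a search-tool score ratio. Populations of
pair divergences are compared with the two-sample Kolmogorov-Smirnov test
(`compare_populations()`), the appropriate distribution-free test when
two cohorts of duplication ages are contrasted.

## Synteny scanning

Gene orders are plain tables (species, gene, chromosome, 0-based
position, ortholog group); adjacency is orientation-agnostic and
chromosome ends are not adjacencies. `detect_clade_breaks()` scans a
reference ordering from *each* clade and reports adjacencies conserved in
every scorable member of one clade and present in no scorable member of
the other, so swapping the clades returns the same adjacency set with the
labels exchanged. A gene whose two flanking adjacencies are clade-broken
while its flanks are adjacent to each other in the other clade is
reported separately as a single-gene translocation.
`classify_break_inheritance()` then asks, per polyploid genome, which
clade's local arrangement its orthologs follow, accepting either copy of
a duplicated region. `breakpoint_distance()` provides an unsigned
breakpoint count over shared single-copy ortholog groups as the
desk-scale substitute for rearrangement-scenario counting (which needs an
external solver and is out of scope).

## The simulator

`simulate_phylome()` generates gene families along a species tree under
three scenarios:

* `none` -- one copy per species;
* `autoWGD` -- the clade below the event branch is duplicated at the
  branch midpoint; each copy is lost per species with `loss_prob`;
* `hybridization` -- one homeolog set keeps the clade's true position
  (parent-A descent); the second is grafted as sister to the parent-B
  clade, depth-matched so its tips stay clock-like. The two sets coalesce
  at the parental-divergence branch, which is exactly where the apparent
  duplication maps -- the hybridization branch itself collects no events.

Branch lengths receive multiplicative lognormal noise (sd 0.2, mean 1) so
trees are not perfectly clock-like. The seed species always retains at
least one copy, since a phylome is seeded on its genes. Ground truth
(scenario, true mapping branch, per-copy retention, observability) is
emitted per family.

**Sequences.** `evolve_sequences()` uses a stationary-frequency
replacement model: a site hit along a branch is redrawn from the
amino-acid stationary distribution. Site rates come from a discretized
gamma (shape `rate_alpha = 1`, 16 categories, mean 1) so branch lengths
are calibrated in substitutions per site at `rate_scale = 1`. The
`rate_scale` knob exists because mutation-frequency-driven simulators are
traditionally rescaled until alignments look realistic; with gamma
mean-one rates the calibrated default is simply 1. Indels are
single-residue insertions/deletions at rate `indel_freq` (default 3e-4)
per site per unit branch length, and the alignment is tracked exactly
through them. The model deliberately omits empirical exchangeability
matrices: all downstream statistics operate on mismatch fractions, for
which replace-with-stationary is sufficient and analytically transparent
(its expected mismatch is `(1 - E_r[e^{-rt}]) * (1 - sum p_i^2)`, which
the tests verify by Monte Carlo).

**Planted artifacts.** `apply_lba()` bifurcates the seed terminal branch
at its midpoint: the original copy keeps the far half ("cut in half"),
the new paralog evolves `lba_multiplier` times the original branch
length. With the default multiplier 10 the two copies' rate ratio is
20-fold -- the strongest acceleration the study design describes; a
mid-branch split is used because a zero-length stem would make the
planted sister relationship metrically invisible.
`apply_gene_conversion()` overwrites a uniformly placed contiguous window
covering fraction `f` of the alignment columns of one paralog with the
other's homologous residues; contiguity reflects the mechanism of
conversion tracts.

**Gene orders.** `simulate_gene_orders()` keeps clade A on the ancestral
order and plants `k` clade-B rearrangements as suffix-segment
translocations to another chromosome's end. Each such event breaks
exactly one ancestral adjacency, so `k` planted events are `k` detectable
breaks; interior inversions would break two adjacencies each and make
counting ambiguous. Polyploid genomes are single-copy mosaics whose
chromosomes descend from a recorded parent (optionally with a fraction of
genes retained in duplicate), keeping inheritance truth unambiguous.

## Inference stage

The simulate-infer-map loop is closed by Kimura distances plus neighbor
joining (`infer_gene_tree()`), with site-resampled bootstrap supports on
request. NJ recovers additive matrices exactly and ties are broken
deterministically by taxon order. ML and Bayesian inference are
deliberately out of scope -- the pipeline contract is method-agnostic and
externally inferred trees can be imported via `parse_newick()`.

**Saturation ceiling.** Saturated pairs (Kimura correction undefined) are
set to 2.0 substitutions/site, just above the largest value the
correction can produce (about 1.9 at its domain boundary). A ceiling far
beyond the tree diameter would inject pseudo-distances that dominate the
NJ criterion and systematically misplace fast-evolving sequences; placing
it at the attainable boundary keeps saturated pairs "very far" without
distorting the remaining geometry.

## Control experiments and their regime

`lba_experiment()` and `conversion_sweep()` run the two validation
simulations end to end. Both default to the 12-taxon reduced species
tree (the seed, both ZT species, all five KLE species, four outgroups)
and to `rate_scale = 0.3`: such control simulations are run on genes with
one-to-one orthologs in *every* species considered -- a strongly
conservation-biased set, distinctly slower than the genome average --
and this scale puts the deepest pairwise divergences near `D = 0.3` and,
critically, keeps the accelerated paralog below the distance-saturation
bound. Beyond that bound no distance-based method retains any placement
signal, so a faster regime would test saturation, not long-branch
attraction. Sequence lengths default to 450 (a typical full-length yeast
protein) for the LBA experiment and 300 for the conversion sweep.

Under these conditions the LBA experiment places the seed-pair
duplication on the true terminal branch in the large majority of 200
families, with every ancestral artifactual peak smaller -- and the
conversion sweep finds that overwriting 20% of one paralog with the other
already makes younger-than-truth mappings the majority outcome,
consistent with partial gene conversion rejuvenating apparent duplication
ages far more effectively than rate acceleration distorts them.

## Problem sizes

The shipped tests use phylomes of 150-320 families for recovery and
topology-signature checks, 20 replicate phylomes of 200 families for the
autopolyploidy argmax check, 500 simulated trees for the
mapper-equivalence check, and 200 families for each of the two
sequence-level experiments; these sizes give comfortable margins for
every property asserted while keeping a full run of the suite in the
low minutes.

## What the simulator does and does not emulate

It emulates: lineage-specific rates (branch lengths plus lognormal
noise), site-rate heterogeneity, stochastic gene loss after doubling,
indels, rate-accelerated paralogs, partial gene conversion, and
clade-specific gene-order rearrangements with polyploid inheritance. It
does not emulate incomplete lineage sorting, gene flow other than the
single planted hybridization, empirical amino-acid exchangeabilities,
codon structure, alignment error, or assembly artifacts. Passing tests
therefore show that the *algorithms* recover planted signals under
realistic noise of the modelled kinds -- not that real phylomes are free
of the unmodelled ones. In particular, distance/NJ inference is more
sensitive to long-branch attraction than the likelihood methods used on
real data; the LBA control documents the regime in which the distance
stage is trustworthy rather than claiming immunity.

## Known limitations

* The species-overlap rule treats any recurring species as evidence of
  duplication; widespread horizontal transfer or contamination would
  inflate counts.
* LCA reconciliation is point-estimate only; bound-interval dating is not
  implemented.
* The nine-way pair classification follows this package's suffix
  semantics (see above) and may differ from other operationalizations.
* Breakpoint distance is a lower-bound-style surrogate, not a
  rearrangement scenario.
* Saturated distance pairs carry essentially no placement information;
  results involving branches beyond ~1.9 substitutions/site should be
  read accordingly.
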