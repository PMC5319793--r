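---
title: "Models and methods for comparative A-to-I editing analysis"
author: "editevol maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for comparative A-to-I editing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editevol)
```

# Scope

`editevol` analyses the evolution of adenosine-to-inosine (A-to-I) RNA
editing across a species phylogeny. Inosine is read as guanosine, so
editing appears as A-to-G mismatches between RNA reads and the genome,
and the *editing level* of a site is G/(A+G) among the reads covering it.
The package covers the stages downstream of read alignment: site discovery
and validation from per-site pileup counts, editing-level quantification
across platforms, cis-regulatory modelling (the ADAR triplet motif and the
double-stranded RNA stem formed with an editing complementary sequence,
ECS), parsimony dating of editing events, conservation-based constraint
classification, random-forest models of editing change, and 3'UTR
functional analyses (expression shifts and miRNA seed-match changes).
Alignment, genome-to-genome orthology mapping, site annotation and
differential-expression fitting are consumed as inputs, not reimplemented.

All stages are exercised end to end on a bundled synthetic-data generator
whose assumptions are documented below, so the full pipeline is testable
without external data.

# Site discovery and validation

Variant calls require at least 2 supporting reads (counts are assumed to
be pre-filtered at base and mapping quality 20, upstream of this package);
sites in bidirectionally transcribed regions are discarded. Shared
variants between two species are collected through an orthology map over
a grid of minimum-level cutoffs, and the working cutoff is the smallest
one at which at least 80% of shared variants are A-to-G — raising the
cutoff purifies the A-to-G fraction at the cost of sensitivity, and the
full fraction-versus-cutoff curve is returned for inspection.

Validation against an ADAR-null sample treats a candidate (more than two
altered reads and level at least 1.5% in the wild type) as genuine when
the null sample shows no altered reads; otherwise a two-sided Fisher's
exact test compares A-to-G occurrences between wild type and null, with
Benjamini-Hochberg correction at 0.05 across the batch. The two support
thresholds (at least 2 reads for calling; more than 2 for validation
candidates) are deliberately kept as separate constants; they enter the
two procedures with different roles.

Editing levels are G/(A+G); an entry needs 20 reads (RNA-seq) or 50 reads
(mmPCR-seq, a microfluidic multiplex PCR assay for targeted deep
quantification). mmPCR-seq measurements are kept only when two biological
replicates each reach 50 reads and differ by at most 10 percentage
points; where both platforms measured a site, the targeted measurement
wins. A site that is not an A in the genomic DNA of a species has, by
definition, editing level 0 there. The *representative level* of a site
is its maximum across all qualifying datasets — editing is often tissue-
and stage-specific, so the maximum, not the mean, reflects a site's
capacity to be edited.

# Cis-regulatory modelling

**Motif.** The ADAR triplet motif matrix is built from the -1/+1
neighbours of highly edited sites (level at least 50%), with an additive
pseudocount (default 0.5) and a uniform background. Triplet scores are
log2 odds summed over the two positions, affinely rescaled to 0–10; a
degenerate matrix (zero score range) yields all-zero scores with an
explicit flag rather than a division by zero. Because per-species
matrices are nearly identical, downstream scoring uses their arithmetic
mean (renormalized). Cross-species site pairs are classed as
Presence/Absence (anchor at least 10% in some dataset, other at most
1.5% in all) or Presence/Presence (both at least 10%); the asymmetry test
counts, among pairs with differing triplet scores, how often the anchor
scores higher, against a symmetric binomial null.

**Structure.** The editing stem is predicted by a banded complementarity
search rather than a thermodynamic folder: maximal runs of consecutive
complementary pairs (Watson-Crick plus G:U wobble) are enumerated along
the anti-diagonals of the self-pairing matrix of the ±200 bp window, with
the minimum hairpin loop (4 nt) enforced during the search, and chained
across bulges of up to 12 nt per side by a dynamic program with affine
junction penalties (open 12, extend 4 per base, match 2) so that gluing
short chance runs onto a stem never profits. An ECS passes the filter
with at least 20 paired bases and a maximum bulge of 8. This substitution
preserves exactly the properties downstream code consumes — the base-pair
list, the pass/fail filters and the 8 structural features — and the
search is validated against exhaustive enumeration on small windows. The
distal (intronic) search first smooths the conservation track with a
51-bp moving average, collects blocks of at least 20 bases scoring at
least 0.90 within 2,500 bp of the site, and folds each block against the
site segment with the same filters; only proximal ECSs feed the
cross-species analyses, since distal predictions are conditioned on
conservation in one species and would bias comparisons toward it.

The free energy of a fixed pairing uses a nearest-neighbour stacking
table (standard Watson-Crick values; representative negative constants
for wobble-containing stacks) plus a logarithmic bulge/internal-loop
penalty, `3.2 + 1.1 log(L)` kcal/mol. The helix initiation constant is
omitted and the result clamped at 0 so any paired duplex reports a
non-positive energy; absolute values are therefore not comparable to a
full thermodynamic model — only orderings and filter outcomes are used.
Two-segment (distal) duplexes are treated as joined by a 100-adenosine
linker that contributes no pairs. The 8 features are: free energy, stem
length (editing-side span of the outermost pairs), max bulge (longest
unpaired run inside the stem on either side, taken per side when both
strands bulge at one loop), percent paired, distance from the site to the
closest stem edge (measured along the editing side), total paired bases,
and paired bases downstream and upstream of the site.

**Random forests.** Editing presence/absence in a second species is
modelled with classification forests and editing level with regression
forests, over the anchor level, the motif-score change and the changes of
the 8 structural features (other species minus anchor). For
Presence/Absence rows the anchor's ECS must pass the filter (the other
species' need not — its stem may genuinely be gone); for
Presence/Presence rows a pass in either species suffices. A species
without a passing ECS contributes its best folded-but-failing candidate,
or zeros if nothing folded; a strict-exclusion mode is available. The
default forest size is 1,000 trees with 3 features per split — out-of-bag
estimates stabilise well below the heavyweight 10,000-tree setting, which
remains available through `pipelineConfig(rf_ntree = 10000)`. Importance
is the permutation accuracy drop (classification) or the permutation
increase in MSE (regression), divided by its standard deviation; the
explained variation is `R^2 = 1 - MSE_oob / Var(outcome)`, and the full
versus reduced (anchor level only, one feature per split) comparison is
reported with a 20-refit seed-resampling interval. Forests have no native
sign for a predictor's direction of association; where one is wanted it
should be read from the per-feature marginal rank correlation.

# Evolutionary analyses

Editing-level divergence between two species is `1 - Spearman's rho`
over shared sites with defined levels (mid-ranks via the Pearson formula,
because levels of unedited sites tie at 0 frequently). Trees come from
Saitou–Nei neighbor joining; negative branch lengths, which NJ can emit
on noisy input, are clamped to 0 with the deficit moved to the sister
branch, preserving path lengths — the topology is the object of interest.
Divergence–time regression uses ordinary least squares plus a rank
correlation; species pairs without a supplied divergence time are simply
excluded.

A site's status in a species is *edited* when its level reaches 2% in at
least one dataset, *unedited* when every dataset covers it with at least
20 reads and stays at or below 1.5% (or the DNA base is not A), and
*undefined* otherwise — insufficient coverage never asserts absence.
Dating follows parsimony: editing events rarely arise independently on
different lineages, so a site's age is the most distantly related species
in which it is also edited, intervening losses allowed; sites defined in
fewer than 5 comparison species are left undated. Clustering is a
nearest-neighbour criterion (30/40/50 bp) with a bootstrap standard
deviation (1,000 resamples) as the error bar.

The generic two-group kernel is a two-sided Mann-Whitney U test
(Wilcoxon signed-rank when paired). For combined sample sizes up to 25
the p-value is exact, from a rank-sum distribution computed by dynamic
programming over doubled mid-ranks — unlike the textbook exact test this
handles ties; above 25 the tie-corrected normal approximation is used.

# Constraint classification

The S region of a site spans 15 bp upstream to 30 bp downstream (46
bases, in transcribed-strand orientation — the definition is asymmetric
and the paper-style convention of which side is "upstream" is taken to be
5' on the sense strand); the F region is the two flanking 46-bp intervals
pooled. Sites with mean conservation above 0.9 in both regions are
*highly constrained*; of the rest, sites whose S region distribution is
significantly higher than the F region's (two-sample Kolmogorov-Smirnov,
BH-corrected p below 0.05 across the batch classified in one call) are
*moderately constrained*; the others are unconstrained. The KS p-value is
asymptotic — adequate at 30–92 bases per region. Flanking windows falling
into a disallowed genic context (non-CDS for coding sites, CDS overlap
for 3'UTR sites) are excluded through a position mask. Assuming lowly
edited (below 1.5%) sites are neutral, the excess fraction of constrained
sites among edited versus lowly edited sites estimates the fraction of
likely-functional editing events, with a Fisher's exact p-value on the
2x2 counts.

# 3'UTR function

Expression comparisons test the log2 fold change (editing-deficient
mutant versus wild type, fitted upstream) of 3'UTR-edited gene groups
against control genes with the rank kernel; grouping uses only sites at
least 5% edited with at least 20 reads. The nascent-versus-polyA
comparison restricts to sites with 20 reads in both datasets and nascent
level above 5%, and contrasts the per-site difference between 3'UTR and
CDS sites. miRNA target scanning reimplements the canonical seed-match
types only (8mer, 7mer-m8, 7mer-A1; seed = positions 2–8; matches
classified exclusively by their strongest type) — context scores would
require trained parameters and the question asked is only whether an
A-to-G edit creates or destroys a putative site. Each edit is evaluated
independently; combinatorial multi-edit variants are not enumerated. Only
miRNAs above 0.1% of miRNA reads are scanned.

# The synthetic-data generator

The generator replaces the study's sequencing archives with data whose
statistical structure matches what each stage assumes; it defines the
package's study conditions and is itself tested code.

* **Phylogeny and levels.** Six species with published divergence times
  (5.4 to 62.9 Myr from the anchor) plus a 40-Myr stem lineage above the
  root so that ancestral sites shared by all species exist. Sites are
  born once, on a branch chosen with probability proportional to branch
  length (a neutral-origin default); species diverging before the birth
  have level 0. Levels evolve as a Gaussian random walk with standard
  deviation `0.04 * sqrt(branch length in Myr)`, *reflected* into [0,1]
  (reflection preserves variance near the boundaries where truncation
  would not). Birth levels follow a logistic link on the planted cis
  features — stem paired-base count and motif strength — plus noise,
  bounded below at 5%, the level at which sites enter the targeted
  panel; with the cis effects set to 0 the link degenerates and planted
  features are independent of levels, giving the null construction used
  in testing.
* **Reads.** Coverage is negative binomial with mean 100 (matching the
  observed 95–127 reads per site; dispersion size 5, typical RNA-seq
  overdispersion) and the G count is binomial at
  `level + 0.01 (1 - level)` — a 1% A-to-G sequencing error; remaining
  reads are A with C/T errors at 0.5% each. An ADAR-null sample carries
  errors only.
* **Sequences.** One contig per site (600 nt, site at 300), motif triplet
  written at -1/+1. Structured sites (80%) get a perfect inverted repeat
  of 22–40 pairs with a poly-A loop (4–12 nt) and two-base poly-A flank
  blocks; because A cannot pair with A, the planted stem is exactly
  recoverable, which is what makes the feature-equality tests sharp.
  Real stems have wobbly boundaries and bulges; the filters and chaining
  are exercised on those shapes separately. In species where a site is
  absent, the 5' motif base is mutated and the ECS arm scrambled with
  probability 0.8 each, so Presence/Absence pairs lose at least one
  planted property. Since every site owns its window, planting collisions
  cannot occur by construction.
* **Conservation.** Background Beta(2,2) (mean 0.5); "high" sites get
  Beta(19,1) (mean 0.95) over S and F regions, "moderate" sites over the
  S region only, in a 20/20/60 mix.
* **Expression and miRNAs.** Control genes draw
  `log2fc ~ Normal(0, 0.5)`; genes with one edited 3'UTR site are
  shifted by +0.5, with two or more by +1.0. A synthetic 10-miRNA panel
  (8 above the 0.1% expression filter) is bundled; a configurable subset
  (default half) of the stemless 3'UTR sites gets a near-match 8mer whose
  A-to-G edit completes the seed match — stemless, so a planted stem and
  a planted seed site never overwrite each other.
* **Determinism.** All draws flow from one seed through per-module
  substreams (hash of module name plus seed), so regenerating one table
  never perturbs another and identical configurations are byte-identical.

What passing tests on these data do *not* show: robustness to alignment
artifacts, splice contamination, strand misassignment, batch effects
between platforms, or non-neutral editing-level evolution — none of which
the generator emulates.

# Numerical choices and problem sizes

Testing runs the tree-recovery study at 50 replicates of 1,000 sites and
coverage 100; dating is validated under the targeted-panel emulation
(coverage 2,400, birth levels at least 5%, no drift — parsimony dating
assumes presence is preserved along descent, so the dating check isolates
status-calling error from level evolution, which is exercised separately
by the divergence analyses); stem recovery uses 500 planted and 500
shuffled windows; constraint recovery uses 300 sites; the end-to-end run
uses the default 6-species, 1,000-site dataset. These sizes give stable
pass/fail behaviour at a few minutes of compute and are stated here as
the package's chosen study sizes.

Ties in rank tests use mid-ranks throughout. The discovery cutoff grid is
{1, 1.5, 2, 3, 5, 10, 15, 20}%. Degenerate inputs are contracts, not
surprises: empty pileups give empty tables; undefined track positions are
NA, never 0; a fully masked S region is unevaluable; an anchor-unedited
site cannot be dated; zero-variance outcomes refuse an R².

# Limitations

The stem finder reports one optimal chain per region, not an ensemble of
structures, and its energies are rank-order quantities only. The motif
model is the immediate triplet; longer-range sequence preferences are out
of scope. Orthology quality is taken at face value from the input map.
The functional-fraction estimate inherits the assumption that lowly
edited sites are neutral; if some are functional it is an underestimate.
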