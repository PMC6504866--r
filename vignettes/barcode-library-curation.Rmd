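---
title: "Curating and delimiting a DNA barcode reference library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and delimiting a DNA barcode reference library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The problem

Quarantine identification of insect pests — the motivating case is
lepidopteran stemborers of sugarcane and cereals — leans on COI barcode
reference libraries assembled from many sources: freshly sequenced vouchers,
public-database downloads, and donated datasets. Such libraries arrive with
uneven sampling (a few species sequenced hundreds of times, many as
singletons), genus-only identifications, under-length fragments, and a small
but consequential rate of misidentified records. Before the library can
support diagnostic barcoding, it has to be curated (filtered, deduplicated,
screened for label errors) and its species-level structure has to be
audited: does a barcode gap exist, do algorithmic species delimitations
agree with the named taxonomy, and how much of the apparent structure is a
sampling artefact?

`barcodegap` implements that whole audit as composable, tested stages, plus
a synthetic library generator so every stage can be validated against
planted truth without downloading anything.

## Distances

All analyses run on pairwise evolutionary distances under **pairwise
deletion**: for each sequence pair, only columns where both records carry an
unambiguous A/C/G/T are compared, so gaps, `N` and IUPAC ambiguity codes
cost information only locally. With transition proportion $P$ and
transversion proportion $Q$ over the $L$ compared sites, the Kimura
2-parameter distance is

$$ d_{K2P} = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q). $$

The Tamura–Nei (TN93) model additionally separates purine
($P_1$: A$\leftrightarrow$G) and pyrimidine ($P_2$: C$\leftrightarrow$T)
transitions and uses empirical base frequencies. We estimate those
frequencies **per pair over the pair's compared sites**, consistent with the
pairwise-deletion convention; pooling frequencies across the whole alignment
(as some tools do) changes distances in the fourth decimal place. TN93
reduces exactly to K2P when all four frequencies are $1/4$ and $P_1 = P_2$,
and the test suite asserts this reduction to $10^{-9}$.

Saturated pairs (a logarithm argument at or below zero) and non-overlapping
pairs are *flagged undefined* (`NA`) rather than raising an error: one
rogue pair must not kill a whole-matrix run. Undefined pairs are excluded
from minima/maxima with a warning, treated as non-edges by clustering, and
rejected explicitly by neighbor joining, which needs a complete matrix.

Distances are stored as proportions (substitutions/site) everywhere and
rendered as percentages only in prose.

## Haplotype collapsing

Tree-based delimitation methods misbehave on duplicate sequences, so the
library is collapsed to unique haplotypes first. Collapse runs in two
passes. Pass 1 treats two records as duplicates when they agree at every
column where both are unambiguous *and* the shorter record's informative
positions sit inside the longer record's informative span — the
subset-of-a-longer-read case. Ambiguity codes match anything in this test;
that is deliberate, because a strict byte-equality pass would let an
`N`-bearing copy of a haplotype survive. Pass 2 re-checks survivors with the
plain 100%-identity-over-overlap rule and absorbs the residue.

From each duplicate set the longest record is kept (ties broken by
lexicographically smallest id, which makes the kept *set* independent of
input order). One guarantee is imposed on top: when a duplicate set spans
records labelled as *different identified species* — identical sequences,
conflicting determinations — one representative is kept per species name.
Without this rule a shared haplotype could silently delete a species from
the reference library; with it, `assert_species_preserved()` holds by
construction, and the conflict remains visible to the misidentification
screen downstream. Multiplicities (how many records each kept haplotype
represents) are preserved in a `haplotype_map` and reused by the
sampling-effort regression.

## Barcode-gap delimitation

`detect_gap()` sorts a distance distribution and scans consecutive gaps
$g_i = d_{i+1} - d_i$. A gap is *significant* when it exceeds $X$ times the
mean of the preceding window of up to ten gaps — a local slope estimate, so
significance adapts to the density of the distribution. The prior maximal
intraspecific distance (`pmid`) bounds the within-species class: only gaps
**ending** at or above the prior are candidates. This orientation matters:
a prior placed inside the barcode gap (above all intraspecific, below all
interspecific distances) must still find the gap, while a prior above every
distance must find nothing and collapse the data to one taxon. The first
significant gap wins and its midpoint becomes the clustering threshold.

`abgd_partition()` applies this recursively: split by single linkage at the
detected threshold, then re-scan each group's own sub-distribution with the
same prior, so different taxa can receive different thresholds. Recursion
stops when no gap is found, a detected threshold fails to disconnect the
group, or a depth cap (default 20) is reached. This is a reimplementation of
the recursive barcode-gap idea, not a byte-compatible port of any
particular program: its contract, enforced by the test suite, is recovery
of planted truth — adjusted Rand index 1 against the generating partition
in at least 95 of 100 simulated libraries whose interspecific/intraspecific
ratio is 10.

`single_linkage_partition()` is also exposed directly (the
distance-threshold OTU clustering underlying RESL-style methods, without
the proprietary refinement), and partitions produced by external tools
(GMYC, bPTP, mPTP, RESL) are ingested as two-column TSV files, so the
congruence machinery treats internal and external delimitations
identically.

## Congruence categories

Each named species is compared against each partition and classified, with
`S` its identified sequences and `C` the clusters they touch:
**SINGLE** ($|S|=1$, cluster pure), **MATCH** (one pure cluster),
**MERGE** (one impure cluster), **SPLIT** (several clusters, all pure),
**COMPLEX** (several clusters, impurity somewhere). Unidentified sequences
(`"Genus sp."`, `"aff."`, `"cf."` material) are transparent: they never
make a cluster impure and are never classified themselves, since a
reference library routinely holds unplaced specimens inside otherwise clean
clusters. The per-species tally across methods flags *high congruence*
when all, or all but one, methods agree (the all-but-one case is reported
parenthesised, e.g. `(Split)`). Method-versus-consensus scoring uses the
modal category per species; species with tied modes are skipped rather than
broken arbitrarily.

The classifier is verified exhaustively: against an independently coded
census-based classifier over *all* 203 set partitions of six sequences
against three reference species.

## Misidentification screening

In practice, curators find mislabelled records by expert inspection of
tree positions. The package operationalizes that judgement as an explicit,
tunable distance rule: a record is flagged when it is far from every record
sharing its label (minimum conspecific distance above `t_self`, default
0.05, or the label has no second bearer) *and* within `t_other` (default
0.02) of some other identified species. The defaults bracket the empirical
barcode gap in curated COI libraries, where intraspecific divergence mostly
sits below 5% and interspecific above it; both thresholds are parameters,
not constants. Severity reports the rank of the conflict (congeneric,
cross-genus, or cross-family when a genus-to-family map is supplied). Flags
are advisory: the pipeline writes them to a TSV, a curator confirms, and a
two-column correction file feeds back into the next run via
`apply_corrections()`. Nothing is relabelled automatically.

On simulated libraries with a planted gap and 2% label swaps, the default
rule recovers the swaps with precision and recall at or above 0.9 (pooled
over 100 seeds); this is asserted in the acceptance tests.

## Sampling-effort regression

More heavily sampled species give delimiters more opportunities to split.
To quantify this, each species classified MATCH or SPLIT contributes a
point (specimens sampled, clusters touched); singletons are excluded
because they cannot split, and merged/complex taxa because their cluster
count is not a clean "taxa delimited" measure. Specimen counts use full
pre-collapse multiplicities when a haplotype map is supplied — the effort
that was actually expended — with the analyzed-dataset count as the
fallback. The fit is ordinary least squares with the slope F-test on
$(1, n-2)$ degrees of freedom, and `leave_one_out_r2()` exposes
single-point leverage, the diagnostic for a lone heavily split outlier
dominating an otherwise weak trend. No multiple-testing correction is
applied across methods.

## The synthetic generator

`sim_config()` defaults define the study conditions the package is
validated under: 64 nominal species, 667 aligned bp, geometrically skewed
sampling with mean 20 (yielding ~1300 records, deep series and singletons
alike), AT-rich insect mitochondrial base composition (0.31/0.16/0.15/0.38),
transition/transversion rate ratio 4, leaf branches of 0.004 expected
substitutions/site against species branches of 0.04 (the planted
order-of-magnitude barcode gap), 2% label swaps, 16% genus-only labels, and
2% records truncated to 450 bp — below the 486 bp inclusion standard, so
the length filter has real work. Species are grouped three to a synthetic
genus so misidentification severities exercise their rank structure.

The genealogy is a **star**: each individual is an independent draw from
its species ancestor, and each ancestor from a common root. Substitution
events are Poisson in number, sites are drawn with replacement (multiple
hits and back-mutations occur, so the distance corrections are genuinely
exercised), and each event is a transition with probability
$\kappa/(\kappa+2)$. What the generator does **not** emulate: coalescent
genealogy within species (no shared intraspecific structure), rate
heterogeneity across sites, indels, NUMTs/pseudogenes, or
geographically structured divergence. Passing tests therefore demonstrate
correctness of the machinery under a clean barcode-gap regime, not
robustness to introgression or deep conspecific splits — precisely the
situations a real audit is meant to surface, not resolve automatically.

Everything is reproducible byte-for-byte from the config seed, and
`truth_report()` scores flags and partitions against the recorded ground
truth (precision/recall, adjusted Rand index, congruence rates).

## Numerical and interface choices

* Coordinates are 1-based inclusive (`crop_alignment(start, width)`) and
  group ids are dense `1..k`, the R conventions; messages and tables follow
  suit.
* Epithets are judged unidentified by matching the first epithet token
  against `sp`/`aff`/`cf`/`nr` with optional trailing dot or number — a raw
  prefix match would misclassify genuine epithets such as *speciosa*.
* Two header dialects are parsed (`id|Genus epithet` and whitespace
  BOLD-style), since merged libraries carry both.
* Neighbor joining is deterministic (Q-ties broken by smallest index pair)
  and clamps negative branch estimates to zero with the deficit moved to
  the sister branch, preserving path lengths; it reproduces additive
  matrices exactly and is a dependency-free stand-in where an external ML
  tree is not supplied, not a claim of equivalence to one.
* Bootstrap standard errors resample alignment columns (not sequences),
  with 500 replicates by default and deterministic seeding.

## Validation scale

The test and acceptance suites run at desk scale: replicate suites use 8–10
species at 5–6 specimens each and 600 bp over 100 seeds, and the headline
acceptance run generates the full 64-species, ~1300-sequence library once.
These sizes keep the full validation under a minute while leaving every
combinatorial property (monotonicity, refinement, order invariance,
exhaustive classifier agreement) asserted exactly.

## Known limitations

The two-pass duplicate semantics is one consistent reading of
"maximum differences = 0" deduplication; other tools' tie-breaking can keep
a different (equally valid) representative. The barcode-gap recursion is an
approximation whose fidelity target is planted-truth recovery, not
agreement with any particular binary. The misidentification rule is a
deliberately simple two-threshold operationalization of expert judgement;
records that are wrong but *within* `t_other` of nothing (e.g. a mislabelled
singleton far from everything) are not flaggable by construction. And the
archived empirical stemborer library whose per-species distance tables two
of the acceptance checks compare against is third-party data not
redistributed here; those checks run only when that alignment is placed
under `inst/extdata/` (see the test file for the expected names).
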