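# barcodegap

Curation and distance-based species delimitation for DNA barcode reference
libraries.

Reference libraries of COI barcodes — the kind assembled for quarantine
identification of insect pests such as sugarcane stemborers — mix freshly
sequenced vouchers with public-database downloads. They arrive unevenly
sampled (singletons next to species with a hundred records), partly
identified to genus only, padded with under-length fragments, and salted
with misidentifications. `barcodegap` implements the audit such a library
needs before it can be trusted for diagnostics:

* **Curation** — FASTA ingestion with taxonomy-aware headers, the
  greater-than-486 bp inclusion filter with a curator allowlist, window
  cropping, and two-pass haplotype collapsing that provably never
  eliminates a named species (`collapse_haplotypes`,
  `assert_species_preserved`).
* **Distances** — Kimura 2-parameter and Tamura–Nei (1993) pairwise
  distances under pairwise deletion,
  `d_K2P = -½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)`,
  with per-pair empirical base frequencies for TN93, flagged-undefined
  saturation handling, per-species barcode-gap summaries (maximum/mean
  intraspecific divergence, nearest non-conspecific and the minimum
  distance to it), and column-bootstrap standard errors.
* **Delimitation** — recursive barcode-gap partitioning across a prior grid
  (the prior maximal intraspecific distance bounds the within-species
  class; the first gap exceeding `X` times the local mean gap sets the
  threshold, recursively per group), plus single-linkage threshold
  clustering, plus ingestion of external GMYC/bPTP/mPTP/RESL partitions as
  TSV.
* **Congruence** — each named species classified against each partition as
  MATCH / SINGLE / MERGE / SPLIT / COMPLEX, cross-method agreement tables
  with high-congruence flags, and method-versus-consensus scoring.
* **Screening** — distance-rule misidentification flags (far from its own
  label, close to another species) with severity ranks and a
  curator-in-the-loop correction file.
* **Sampling-effort regression** — taxa delimited per species regressed on
  specimens sampled (OLS with slope F-test, leave-one-out r²).
* **Simulation** — a synthetic library generator with planted barcode gap,
  skewed sampling, label errors and ground truth, so the whole pipeline is
  testable end to end.
* **Trees** — deterministic neighbor joining, outgroup rooting, and
  monophyly checks in which unidentified specimens are transparent.

## A worked example

```r
library(barcodegap)

cfg <- sim_config(n_species = 12, mean_samples = 8, seed = 42)
sim <- simulate_library(cfg)
sim$alignment
#> barcode_alignment: 95 sequences x 667 columns
#>   identified to species: 75 ( 12 species )

aln <- apply_length_filter(sim$alignment, min_bp = 486)
col <- collapse_haplotypes(aln)
dm  <- distance_matrix(col$alignment, "K2P")

flags <- flag_misidentifications(dm, col$alignment$labels)
flags[, c("id", "labeled_species", "nearest_other_species", "severity")]
#>        id labeled_species nearest_other_species      severity
#> 1 sim0025 Genus02 taxon06       Genus02 taxon05 species_level
#> 2 sim0069 Genus02 taxon06       Genus03 taxon09   genus_level
```

Both flagged records are planted label errors: they sit within 0.01
substitutions/site of another species but far from everything sharing their
own label. Excluding them, the per-species summaries show the barcode gap
(maximum intraspecific divergence well below the minimum distance to the
nearest other species):

```r
summ <- species_summaries(dm, col$alignment$labels, exclude = flags$id)
head(summ[, c("species", "n", "max_intra", "min_inter", "nearest_species")], 4)
#>           species n  max_intra  min_inter nearest_species
#> 1 Genus01 taxon01 6 0.01516789 0.06783572 Genus01 taxon02
#> 2 Genus01 taxon02 1         NA 0.05474157 Genus03 taxon08
#> 3 Genus01 taxon03 5 0.01214020 0.06298458 Genus01 taxon02
#> 4 Genus02 taxon04 8 0.01518243 0.06292555 Genus03 taxon08

part <- abgd_partition(dm, pmid = 0.0129, X = 1.5)
keep <- !(col$alignment$labels$id %in% flags$id)
table(classify_all_species(part, col$alignment$labels[keep, ])$category)
#>  MATCH SINGLE  SPLIT
#>      9      2      1
```

At a prior of 0.0129 the delimiter reproduces the named taxonomy for 11 of
12 species (the split species carries genuinely deep planted variation plus
the removed flags). `run_pipeline()` chains all of the above from a single
YAML-able config and writes every table plus a manifest.

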