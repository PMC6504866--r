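# Fixture builders and independent oracles shared across the suite.

# build a barcode_alignment from sequences + header strings ("id|Genus epithet")
make_aln <- function(seqs, headers) {
  labels <- barcodegap::parse_taxon_labels(headers)
  seqs <- toupper(seqs)
  names(seqs) <- labels$id
  structure(list(seqs = seqs, labels = labels,
                 n_col = max(nchar(seqs))),
            class = "barcode_alignment")
}

# wrap a raw symmetric matrix as a distance_matrix
make_dm <- function(d, ids = NULL, model = "K2P") {
  if (is.null(ids)) ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("t", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d, model = model), class = "distance_matrix")
}

# random symmetric distance matrix (no NAs)
random_dm <- function(n, max_d = 0.3) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, max_d)
  d <- d + t(d)
  make_dm(d)
}

# brute-force connected components at threshold (edge iff d <= thr)
brute_components <- function(d, thr) {
  n <- nrow(d)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && !is.na(d[i, j]) && d[i, j] <= thr && comp[j] != comp[i]) {
        old <- comp[j]; comp[comp == old] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# dense first-occurrence normalization: equal iff same grouping
norm_grouping <- function(g) as.integer(factor(as.character(g), levels = unique(as.character(g))))

# all set partitions of n elements as restricted-growth strings
all_set_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxg) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return(invisible()) }
    for (g in seq_len(maxg + 1L)) grow(c(prefix, g), max(maxg, g))
  }
  grow(integer(), 0L)
  out
}

# independent congruence classifier: per-cluster species census first,
# then category decisions from the counts (different route from the package)
brute_classify <- function(assignment, labels, species) {
  cov <- names(assignment)
  lab <- labels[match(cov, labels$id), , drop = FALSE]
  idsp <- ifelse(!is.na(lab$identified) & lab$identified, lab$species, "")
  census <- tapply(idsp, assignment, function(v) unique(v[nzchar(v)]))
  S <- cov[idsp == species]
  C <- unique(assignment[S])
  impure <- any(vapply(as.character(C), function(g)
    length(setdiff(census[[g]], species)) > 0, TRUE))
  if (length(C) >= 2L) { if (impure) "COMPLEX" else "SPLIT" }
  else if (impure) "MERGE"
  else if (length(S) == 1L) "SINGLE"
  else "MATCH"
}

# brute-force monophyly via enumeration of all rooted clades
brute_monophyletic <- function(tree, labels, species) {
  lab <- labels[match(tree$tip.label, labels$id), , drop = FALSE]
  tip_sp <- ifelse(!is.na(lab$identified) & lab$identified, lab$species, "")
  target <- tree$tip.label[tip_sp == species]
  if (length(target) == 1L) return(TRUE)
  clades <- ape::prop.part(tree)
  tipsets <- lapply(clades, function(ix) tree$tip.label[ix])
  containing <- Filter(function(ts) all(target %in% ts), tipsets)
  smallest <- containing[[which.min(lengths(containing))]]
  sp_in <- tip_sp[match(smallest, tree$tip.label)]
  !any(sp_in != "" & sp_in != species)
}

# small simulated library under the planted-gap study conditions
quick_sim <- function(seed, n_species = 8, k = 5, L = 600,
                      mislabel = 0, unid = 0, short = 0) {
  cfg <- barcodegap::sim_config(
    n_species = n_species, sampling = "fixed", mean_samples = k, L = L,
    mislabel_rate = mislabel, unidentified_rate = unid,
    short_rate = short, short_len = if (short > 0) round(L * 0.7) else 450L,
    seed = seed)
  barcodegap::simulate_library(cfg)
}
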