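#' Configuration for the synthetic barcode-library generator
#'
#' Defaults emulate the statistical structure of a large, unevenly sampled
#' COI stemborer reference library: 64 nominal species at 667 aligned bp,
#' geometrically skewed sampling (many shallow species, a few deep ones,
#' singletons), a planted barcode gap (interspecific divergence an order of
#' magnitude above intraspecific), AT-rich insect mitochondrial base
#' composition, transition-biased substitution, ~2\% species-label errors,
#' a fraction of genus-only ("sp.") identifications, and occasional
#' under-length records.
#'
#' @param n_species number of nominal species (default 64).
#' @param sampling \code{"geometric"} (skewed, min 1) or \code{"fixed"}.
#' @param mean_samples mean specimens per species (default 20; the fixed
#'   count when \code{sampling = "fixed"}).
#' @param L aligned length in bp (default 667).
#' @param delta_intra expected substitutions/site on each leaf branch from
#'   its species ancestor (default 0.004; a conspecific pair then diverges
#'   by about twice this).
#' @param delta_inter expected substitutions/site from the root to each
#'   species ancestor (default 0.04; ten times \code{delta_intra}, the
#'   planted barcode gap).
#' @param kappa transition/transversion rate ratio (default 4, a typical
#'   insect mitochondrial value).
#' @param base_freqs equilibrium base frequencies A,C,G,T (default the
#'   AT-rich insect COI composition 0.31, 0.16, 0.15, 0.38).
#' @param mislabel_rate fraction of records written with a wrong species
#'   label (default 0.02).
#' @param unidentified_rate fraction degraded to genus-only "sp." labels
#'   (default 0.16).
#' @param short_rate fraction truncated to \code{short_len} bp (default 0.02).
#' @param short_len length of truncated records (default 450, below the
#'   486 bp inclusion standard).
#' @param species_per_genus species grouped per synthetic genus (default 3),
#'   giving misidentification severities a rank structure.
#' @param seed integer seed; every downstream draw flows from it.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_species = 64L, sampling = c("geometric", "fixed"),
                       mean_samples = 20, L = 667L,
                       delta_intra = 0.004, delta_inter = 0.04,
                       kappa = 4, base_freqs = c(A = 0.31, C = 0.16,
                                                 G = 0.15, T = 0.38),
                       mislabel_rate = 0.02, unidentified_rate = 0.16,
                       short_rate = 0.02, short_len = 450L,
                       species_per_genus = 3L, seed = NULL) {
  sampling <- match.arg(sampling)
  stopifnot(n_species >= 1L, mean_samples >= 1, L >= 1L,
            delta_intra >= 0, delta_inter > delta_intra,
            kappa > 0, length(base_freqs) == 4L,
            abs(sum(base_freqs) - 1) < 1e-8,
            mislabel_rate >= 0, mislabel_rate < 1,
            unidentified_rate >= 0, unidentified_rate < 1,
            short_rate >= 0, short_rate < 1, short_len >= 1L,
            short_rate == 0 || short_len < L)
  if (n_species < 2L && mislabel_rate > 0)
    stop("mislabel_rate > 0 needs at least 2 species to swap between")
  structure(list(n_species = as.integer(n_species), sampling = sampling,
                 mean_samples = mean_samples, L = as.integer(L),
                 delta_intra = delta_intra, delta_inter = delta_inter,
                 kappa = kappa, base_freqs = base_freqs,
                 mislabel_rate = mislabel_rate,
                 unidentified_rate = unidentified_rate,
                 short_rate = short_rate, short_len = as.integer(short_len),
                 species_per_genus = as.integer(species_per_genus),
                 seed = seed),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")
TS_PARTNER <- c(A = "G", C = "T", G = "A", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), C = c("A", "G"),
                    G = c("C", "T"), T = c("A", "G"))

# Poisson number of substitution events, sites drawn with replacement so
# multiple hits (and back-mutations) occur, transition chosen with
# probability kappa/(kappa+2) against the two transversion alternatives.
mutate_seq <- function(seq, n_events, kappa) {
  if (n_events == 0L) return(seq)
  L <- length(seq)
  pos <- sample.int(L, n_events, replace = TRUE)
  is_ts <- stats::runif(n_events) < kappa / (kappa + 2)
  for (k in seq_len(n_events)) {
    b <- seq[pos[k]]
    seq[pos[k]] <- if (is_ts[k]) TS_PARTNER[[b]]
    else TV_PARTNERS[[b]][sample.int(2L, 1L)]
  }
  seq
}

#' Simulate a barcode library with ground truth
#'
#' Star-shaped genealogy: a root sequence is drawn from the equilibrium
#' base frequencies; each species ancestor accumulates
#' Poisson(L * delta_inter) substitution events from the root, and each
#' individual Poisson(L * delta_intra) events from its ancestor. Label
#' errors, genus-only degradations and under-length truncations (leading /
#' trailing gaps) are then injected, all recorded in the truth object.
#' Byte-identical output for a given seed.
#'
#' @param cfg a \code{sim_config}.
#' @return list with \code{alignment} (a \code{barcode_alignment} carrying
#'   the \emph{written} labels) and \code{truth}, a \code{sim_truth} list:
#'   \code{true_species} (named by id), \code{true_partition},
#'   \code{injected_errors} (id, true_species, written_species),
#'   \code{ancestors}, \code{unidentified_ids}, \code{short_ids}.
#' @export
simulate_library <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  L <- cfg$L
  root <- sample(BASES, L, replace = TRUE, prob = cfg$base_freqs)
  genus_of <- function(s) sprintf("Genus%02d", (s - 1L) %/% cfg$species_per_genus + 1L)
  sp_names <- vapply(seq_len(cfg$n_species), function(s)
    paste0(genus_of(s), " taxon", sprintf("%02d", s)), "")
  k_per <- if (cfg$sampling == "fixed") rep(round(cfg$mean_samples), cfg$n_species)
  else 1L + stats::rgeom(cfg$n_species, prob = 1 / cfg$mean_samples)
  ancestors <- lapply(seq_len(cfg$n_species), function(s)
    mutate_seq(root, stats::rpois(1L, L * cfg$delta_inter), cfg$kappa))
  N <- sum(k_per)
  ids <- sprintf("sim%04d", seq_len(N))
  seqs <- character(N)
  true_sp <- character(N)
  idx <- 0L
  for (s in seq_len(cfg$n_species)) for (k in seq_len(k_per[s])) {
    idx <- idx + 1L
    seqs[idx] <- paste(
      mutate_seq(ancestors[[s]], stats::rpois(1L, L * cfg$delta_intra),
                 cfg$kappa), collapse = "")
    true_sp[idx] <- sp_names[s]
  }
  names(true_sp) <- ids

  written <- true_sp
  err_idx <- which(stats::runif(N) < cfg$mislabel_rate)
  for (i in err_idx)
    written[i] <- sample(setdiff(sp_names, true_sp[i]), 1L)
  injected <- data.frame(id = ids[err_idx],
                         true_species = unname(true_sp[err_idx]),
                         written_species = unname(written[err_idx]),
                         stringsAsFactors = FALSE)
  remaining <- setdiff(seq_len(N), err_idx)
  unid_idx <- remaining[stats::runif(length(remaining)) < cfg$unidentified_rate]
  for (i in unid_idx)
    written[i] <- paste(sub(" .*$", "", true_sp[i]), "sp.")
  short_idx <- which(stats::runif(N) < cfg$short_rate)
  for (i in short_idx) {
    start <- sample.int(L - cfg$short_len + 1L, 1L)
    ch <- strsplit(seqs[i], "")[[1L]]
    keep <- seq(start, start + cfg$short_len - 1L)
    ch[setdiff(seq_len(L), keep)] <- "-"
    seqs[i] <- paste(ch, collapse = "")
  }

  labels <- parse_taxon_labels(paste0(ids, "|", written))
  aln <- new_alignment(seqs, labels)
  truth <- structure(list(
    true_species = true_sp,
    true_partition = new_partition(true_sp, method = "truth"),
    injected_errors = injected,
    ancestors = vapply(ancestors, paste, "", collapse = ""),
    unidentified_ids = ids[unid_idx],
    short_ids = ids[short_idx]),
    class = "sim_truth")
  list(alignment = aln, truth = truth)
}

#' Score pipeline outputs against simulation ground truth
#'
#' @param truth a \code{sim_truth}.
#' @param flags optional \code{misid_flags} (precision/recall vs injected
#'   label errors).
#' @param partitions optional list of \code{barcode_partition}s (adjusted
#'   Rand index vs the true partition, over shared ids).
#' @param labels optional label data frame; with \code{partitions}, adds the
#'   fraction of species classified MATCH or SINGLE per partition.
#' @return a \code{truth_scorecard} list: \code{misid_precision},
#'   \code{misid_recall}, \code{ari} (named), \code{match_single_rate}
#'   (named).
#' @export
truth_report <- function(truth, flags = NULL, partitions = NULL,
                         labels = NULL) {
  out <- list(misid_precision = NA_real_, misid_recall = NA_real_,
              ari = NULL, match_single_rate = NULL)
  if (!is.null(flags)) {
    err <- truth$injected_errors$id
    fl <- flags$id
    tp <- length(intersect(fl, err))
    out$misid_precision <- if (length(fl)) tp / length(fl) else NA_real_
    out$misid_recall <- if (length(err)) tp / length(err) else NA_real_
  }
  if (!is.null(partitions)) {
    out$ari <- vapply(partitions, function(p) {
      shared <- intersect(names(p$assignment), names(truth$true_species))
      mclust::adjustedRandIndex(p$assignment[shared],
                                truth$true_species[shared])
    }, 1)
    if (!is.null(labels)) {
      out$match_single_rate <- vapply(partitions, function(p) {
        cls <- classify_all_species(p, labels)
        mean(cls$category %in% c("MATCH", "SINGLE"))
      }, 1)
    }
  }
  structure(out, class = "truth_scorecard")
}
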