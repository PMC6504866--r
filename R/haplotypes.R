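#' Collapse identical sequences to a haplotypes dataset
#'
#' Two-pass deduplication. Pass 1: records are duplicates when they are
#' identical over every column where both carry an unambiguous base
#' (gaps, N and IUPAC ambiguity codes match anything) \emph{and} the
#' shorter record's unambiguous positions fall inside the informative span
#' (first to last unambiguous column) of the longer. Pass 2 re-checks the
#' survivors with the plain 100\%-identity-over-overlap criterion, catching
#' residual matches whose ambiguity structure hid them from pass 1.
#'
#' From each duplicate set, the record with the greatest ungapped length is
#' kept (ties: lexicographically smallest id). When a duplicate set spans
#' more than one identified species name, one representative is kept per
#' species, so that no identified species can be eliminated by collapsing;
#' unidentified duplicates of identified records are absorbed.
#'
#' @param aln a \code{barcode_alignment} (equal-width; crop first).
#' @return list with \code{alignment} (the haplotypes dataset, input order)
#'   and \code{map}, a \code{haplotype_map} data frame with columns
#'   \code{kept_id}, \code{multiplicity} (sequences represented, including
#'   itself) and \code{removed_ids} (comma-joined).
#' @export
collapse_haplotypes <- function(aln) {
  n <- length(aln$seqs)
  if (!n) stop("empty alignment")
  enc <- encode_alignment(aln)
  pc <- pairwise_counts(enc)
  mism <- pc$L - pc$match
  len <- ungapped_lengths(aln)
  ids <- aln$labels$id
  species <- ifelse(aln$labels$identified, aln$labels$species, "")

  first_u <- apply(enc$valid, 1L, function(v) {
    w <- which(v > 0); if (length(w)) w[1L] else NA_integer_ })
  last_u <- apply(enc$valid, 1L, function(v) {
    w <- which(v > 0); if (length(w)) w[length(w)] else NA_integer_ })

  represents <- stats::setNames(rep(list(character()), n), ids)

  run_pass <- function(active, require_span) {
    m <- length(active)
    if (m < 2L) return(active)
    sub <- mism[active, active, drop = FALSE]
    pairs <- which(upper.tri(sub) & sub == 0, arr.ind = TRUE)
    if (require_span && nrow(pairs)) {
      ok <- logical(nrow(pairs))
      for (k in seq_len(nrow(pairs))) {
        i <- active[pairs[k, 1L]]; j <- active[pairs[k, 2L]]
        ok[k] <- (first_u[i] >= first_u[j] && last_u[i] <= last_u[j]) ||
                 (first_u[j] >= first_u[i] && last_u[j] <= last_u[i])
      }
      pairs <- pairs[ok, , drop = FALSE]
    }
    if (!nrow(pairs)) return(active)
    comp <- components_from_pairs(m, pairs[, 1L], pairs[, 2L])
    keep <- rep(TRUE, m)
    for (cid in unique(comp)) {
      members <- which(comp == cid)
      if (length(members) < 2L) next
      gidx <- active[members]
      keep[members] <- FALSE
      kept_here <- integer()
      for (sp in unique(species[gidx])) {
        cand <- gidx[species[gidx] == sp]
        if (sp == "" && any(species[gidx] != "")) next
        best <- cand[order(-len[cand], ids[cand])][1L]
        keep[match(best, active)] <- TRUE
        kept_here <- c(kept_here, best)
      }
      removed_here <- setdiff(gidx, kept_here)
      for (r in removed_here) {
        tgt <- kept_here[species[kept_here] == species[r]]
        if (!length(tgt)) tgt <- kept_here
        tgt <- tgt[order(-len[tgt], ids[tgt])][1L]
        represents[[ids[tgt]]] <<- c(represents[[ids[tgt]]],
                                     ids[r], represents[[ids[r]]])
        represents[[ids[r]]] <<- character()
      }
    }
    active[keep]
  }

  active <- run_pass(seq_len(n), require_span = TRUE)
  active <- run_pass(active, require_span = FALSE)

  kept_ids <- ids[active]
  removed <- represents[kept_ids]
  map <- data.frame(kept_id = kept_ids,
                    multiplicity = 1L + lengths(removed),
                    removed_ids = vapply(removed, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  class(map) <- c("haplotype_map", "data.frame")
  out <- structure(list(seqs = aln$seqs[active],
                        labels = aln$labels[active, , drop = FALSE],
                        n_col = aln$n_col),
                   class = "barcode_alignment")
  list(alignment = out, map = map)
}

#' Check that collapsing eliminated no identified species
#'
#' @param before,after \code{barcode_alignment}s, \code{after} a subset of
#'   \code{before} by id.
#' @return \code{TRUE} when the identified species-name sets are equal,
#'   otherwise \code{FALSE} with attribute \code{"missing"} listing the
#'   species present before but absent after.
#' @export
assert_species_preserved <- function(before, after) {
  sp_before <- unique(before$labels$species[before$labels$identified])
  sp_after <- unique(after$labels$species[after$labels$identified])
  missing <- setdiff(sp_before, sp_after)
  ok <- length(missing) == 0L
  if (!ok) attr(ok, "missing") <- missing
  ok
}

#' Write a haplotype map as TSV
#' @param map a \code{haplotype_map}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_haplotype_map <- function(map, path) write_tsv(map, path)
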