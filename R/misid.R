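#' Flag likely misidentified sequences from their distance neighborhood
#'
#' A sequence is flagged when its species label conflicts with its genetic
#' neighborhood: it is far from every sequence sharing its label (minimum
#' distance above \code{t_self}, or it is the sole bearer of the label)
#' \emph{and} it sits within \code{t_other} of some other identified
#' species. The default thresholds bracket the empirical barcode gap in
#' well-curated COI libraries (intraspecific divergence mostly below 0.05,
#' interspecific mostly above). Flags are advisory: write them out, have a
#' curator confirm, and feed a correction file back in with
#' \code{\link{apply_corrections}}.
#'
#' Severity reflects the taxonomic rank of the conflict: nearest other
#' species congeneric with the label = \code{species_level}; different
#' genus = \code{genus_level}; different family = \code{family_level}
#' (requires \code{family_map}, a named vector genus -> family).
#'
#' @param m a \code{distance_matrix}.
#' @param labels label data frame (as in \code{aln$labels}).
#' @param t_self distance above which a sequence no longer "belongs" to its
#'   own label (default 0.05).
#' @param t_other distance within which it is claimed by another species
#'   (default 0.02).
#' @param family_map optional named character vector mapping genus to family.
#' @return a \code{misid_flags} data frame (possibly empty): \code{id},
#'   \code{labeled_species}, \code{nearest_own}, \code{nearest_other_species},
#'   \code{nearest_other}, \code{severity}, \code{evidence}.
#' @export
flag_misidentifications <- function(m, labels, t_self = 0.05, t_other = 0.02,
                                    family_map = NULL) {
  lab <- .dm_check_labels(m, labels)
  d <- m$d
  ident <- lab$identified
  rows <- list()
  for (i in which(ident)) {
    sp <- lab$species[i]
    own <- which(ident & lab$species == sp)
    own <- setdiff(own, i)
    nearest_own <- if (length(own)) {
      v <- d[i, own]; v <- v[!is.na(v)]
      if (length(v)) min(v) else NA_real_
    } else NA_real_
    oth <- which(ident & lab$species != sp)
    if (!length(oth)) next
    v <- d[i, oth]
    if (all(is.na(v))) next
    k <- oth[which.min(v)]
    nearest_other <- d[i, k]
    far_from_own <- is.na(nearest_own) || nearest_own > t_self
    claimed <- nearest_other <= t_other
    if (!(far_from_own && claimed)) next
    other_sp <- lab$species[k]
    own_genus <- lab$genus[i]
    oth_genus <- lab$genus[k]
    severity <- if (identical(own_genus, oth_genus)) "species_level"
    else if (!is.null(family_map) &&
             own_genus %in% names(family_map) &&
             oth_genus %in% names(family_map) &&
             family_map[[own_genus]] != family_map[[oth_genus]]) "family_level"
    else "genus_level"
    evidence <- sprintf(
      "labelled %s but %.4f from %s (own label %s away)",
      sp, nearest_other, other_sp,
      if (is.na(nearest_own)) ">NA (sole bearer)" else sprintf("%.4f", nearest_own))
    rows[[length(rows) + 1L]] <- data.frame(
      id = lab$id[i], labeled_species = sp, nearest_own = nearest_own,
      nearest_other_species = other_sp, nearest_other = nearest_other,
      severity = severity, evidence = evidence, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), labeled_species = character(),
               nearest_own = numeric(), nearest_other_species = character(),
               nearest_other = numeric(), severity = character(),
               evidence = character(), stringsAsFactors = FALSE)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("misid_flags", "data.frame")
  out
}

#' Write misidentification flags as TSV
#' @param flags a \code{misid_flags} data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_misid_flags <- function(flags, path) write_tsv(flags, path)

#' Read a curator's correction file
#'
#' Format: two tab-separated columns, id and corrected species binomial,
#' \code{#} comments allowed.
#'
#' @param path correction file path.
#' @return data frame: \code{id}, \code{corrected_species}.
#' @export
read_corrections <- function(path) {
  if (!file.exists(path)) stop("correction file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 2L)) stop("malformed correction row in ", path)
  data.frame(id = vapply(parts, `[[`, "", 1L),
             corrected_species = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Apply label corrections to an alignment
#'
#' @param aln a \code{barcode_alignment}.
#' @param corrections data frame from \code{\link{read_corrections}}.
#' @return the relabelled \code{barcode_alignment}.
#' @export
apply_corrections <- function(aln, corrections) {
  idx <- match(corrections$id, aln$labels$id)
  if (anyNA(idx))
    stop("correction refers to unknown id(s): ",
         paste(corrections$id[is.na(idx)], collapse = ", "))
  parsed <- parse_taxon_labels(paste0(corrections$id, "|",
                                      corrections$corrected_species))
  aln$labels[idx, c("genus", "epithet", "species", "identified")] <-
    parsed[, c("genus", "epithet", "species", "identified")]
  aln
}
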