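#' @keywords internal
"_PACKAGE"

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

# first epithet token that marks an identification-to-genus-only label:
# "sp", "sp.", "sp. 2", "aff. grisescens", "cf", "nr" ... but not "speciosa"
is_placeholder_epithet <- function(epithet) {
  first <- sub("[ _].*$", "", trimws(epithet))
  grepl("^(sp|aff|cf|nr)\\.?([0-9]+)?$", first, ignore.case = TRUE)
}

#' Parse taxonomic labels from FASTA headers
#'
#' Headers carry an id and an optional binomial, either pipe-separated
#' (\code{"id|Genus epithet"}) or whitespace-separated BOLD style
#' (\code{"id Genus epithet"}). A record is \emph{identified} when both genus
#' and epithet are present and the epithet is not a placeholder such as
#' \code{"sp."}, \code{"aff."}, \code{"cf."} or \code{"nr."}.
#'
#' @param headers character vector of FASTA header lines (without \code{">"}).
#' @return data frame with columns \code{id}, \code{genus}, \code{epithet},
#'   \code{species} (binomial, \code{""} when absent) and \code{identified}.
#' @export
parse_taxon_labels <- function(headers) {
  headers <- trimws(headers)
  has_pipe <- grepl("|", headers, fixed = TRUE)
  id <- ifelse(has_pipe,
               sub("\\|.*$", "", headers),
               sub("[ \t].*$", "", headers))
  rest <- ifelse(has_pipe,
                 sub("^[^|]*\\|", "", headers),
                 sub("^[^ \t]+[ \t]*", "", headers))
  rest <- trimws(rest)
  genus <- sub("[ \t].*$", "", rest)
  epithet <- ifelse(grepl("[ \t]", rest), sub("^[^ \t]+[ \t]+", "", rest), "")
  epithet <- trimws(epithet)
  identified <- nzchar(genus) & nzchar(epithet) & !is_placeholder_epithet(epithet)
  species <- ifelse(nzchar(genus) & nzchar(epithet),
                    paste(genus, epithet), "")
  data.frame(id = id, genus = genus, epithet = epithet,
             species = species, identified = identified,
             stringsAsFactors = FALSE)
}

new_alignment <- function(seqs, labels) {
  stopifnot(is.character(seqs), is.data.frame(labels),
            length(seqs) == nrow(labels))
  ids <- labels$id
  if (any(!nzchar(ids))) stop("empty sequence id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (length(seqs)) {
    wid <- nchar(seqs)
    if (length(unique(wid)) > 1L)
      stop("sequences differ in aligned length (", paste(range(wid), collapse = "-"), ")")
  }
  names(seqs) <- ids
  structure(list(seqs = seqs, labels = labels,
                 n_col = if (length(seqs)) nchar(seqs[[1L]]) else 0L),
            class = "barcode_alignment")
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat("barcode_alignment:", length(x$seqs), "sequences x", x$n_col, "columns\n")
  cat("  identified to species:", sum(x$labels$identified),
      "(", length(unique(x$labels$species[x$labels$identified])), "species )\n")
  invisible(x)
}

#' @export
length.barcode_alignment <- function(x) length(x$seqs)

#' Number of non-gap characters per sequence
#' @param aln a \code{barcode_alignment}.
#' @return named integer vector of ungapped lengths (bp).
#' @export
ungapped_lengths <- function(aln) {
  nchar(gsub("-", "", aln$seqs, fixed = TRUE))
}

validate_seq_chars <- function(seqs, ids) {
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "")[[1L]]
    bad <- which(!ch %in% IUPAC_CHARS)
    if (length(bad))
      stop("non-IUPAC character '", ch[bad[1L]], "' in sequence '", ids[i],
           "' at position ", bad[1L])
  }
  invisible(TRUE)
}

#' Read an aligned FASTA barcode library
#'
#' Sequences are uppercased and RNA \code{U} is mapped to \code{T}; IUPAC
#' ambiguity codes and \code{-} gaps are retained. Headers are parsed with
#' \code{\link{parse_taxon_labels}}. Sequences need not share a length at
#' read time (pre-crop libraries are accepted); width consistency is enforced
#' by the operations that require it.
#'
#' @param path path to a FASTA file.
#' @return a \code{barcode_alignment}.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fa <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                       whole.header = TRUE),
    error = function(e) stop("no sequences in ", path))
  if (!length(fa)) stop("no sequences in ", path)
  headers <- vapply(fa, function(s) attr(s, "Annot"), "")
  headers <- sub("^>", "", headers)
  seqs <- toupper(vapply(fa, as.character, ""))
  seqs <- chartr("U", "T", seqs)
  labels <- parse_taxon_labels(headers)
  validate_seq_chars(seqs, labels$id)
  # widths may differ pre-crop: store ragged as-is, n_col = max width
  ids <- labels$id
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  names(seqs) <- ids
  structure(list(seqs = seqs, labels = labels, n_col = max(nchar(seqs))),
            class = "barcode_alignment")
}

#' Write a barcode alignment to FASTA
#'
#' Headers are written as \code{id|Genus epithet} (or bare \code{id} when no
#' label is attached), the dialect \code{\link{read_alignment}} parses back.
#'
#' @param aln a \code{barcode_alignment}.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(aln, path) {
  hdr <- ifelse(nzchar(aln$labels$genus),
                paste0(aln$labels$id, "|",
                       trimws(paste(aln$labels$genus, aln$labels$epithet))),
                aln$labels$id)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$seqs))
    writeLines(c(paste0(">", hdr[i]), aln$seqs[[i]]), con)
  invisible(path)
}

#' Subset an alignment by sequence ids (order preserved)
#' @param aln a \code{barcode_alignment}.
#' @param ids ids to keep, in \code{aln} order.
#' @return a \code{barcode_alignment}.
#' @export
subset_alignment <- function(aln, ids) {
  keep <- aln$labels$id %in% ids
  new_alignment(unname(aln$seqs[keep]), aln$labels[keep, , drop = FALSE])
}

#' Apply the minimum-barcode-length inclusion filter
#'
#' Keeps records with strictly more than \code{min_bp} non-gap bases. Records
#' whose id is in \code{allowlist} are retained regardless of length (the
#' curator's escape hatch for short but taxonomically important sequences).
#'
#' @param aln a \code{barcode_alignment}.
#' @param min_bp minimum barcode length in bp; default 486, the minimum
#'   barcode standard length.
#' @param allowlist ids exempt from the filter.
#' @return filtered \code{barcode_alignment}, input order preserved.
#' @export
apply_length_filter <- function(aln, min_bp = 486, allowlist = character()) {
  stopifnot(min_bp > 0)
  len <- ungapped_lengths(aln)
  keep <- len > min_bp | aln$labels$id %in% allowlist
  structure(list(seqs = aln$seqs[keep],
                 labels = aln$labels[keep, , drop = FALSE],
                 n_col = aln$n_col),
            class = "barcode_alignment")
}

#' Crop all sequences to a fixed alignment window
#'
#' @param aln a \code{barcode_alignment} (all sequences must span the window).
#' @param start 1-based first column of the window.
#' @param width window width in columns; the result has \code{width} columns.
#' @return cropped \code{barcode_alignment}.
#' @export
crop_alignment <- function(aln, start = 1L, width) {
  if (width < 1L) stop("crop width must be >= 1 column")
  if (start < 1L || start + width - 1L > min(nchar(aln$seqs)))
    stop("crop window [", start, ", ", start + width - 1L,
         "] out of range for alignment of ", min(nchar(aln$seqs)), " columns")
  seqs <- substr(aln$seqs, start, start + width - 1L)
  new_alignment(unname(seqs), aln$labels)
}

# ---- partitions ------------------------------------------------------------

#' Construct a species-delimitation partition
#'
#' @param groups named vector (names = sequence ids) of group labels; labels
#'   are normalized to dense integers 1..k in first-appearance order.
#' @param method short method name, e.g. \code{"ABGD"}, \code{"GMYC-single"}.
#' @param params named list of method parameters.
#' @return a \code{barcode_partition}.
#' @export
new_partition <- function(groups, method = "unknown", params = list()) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named by sequence id")
  dense <- as.integer(factor(as.character(groups),
                             levels = unique(as.character(groups))))
  names(dense) <- names(groups)
  structure(list(method = method, params = params,
                 assignment = dense, n_groups = max(dense, 0L)),
            class = "barcode_partition")
}

#' @export
print.barcode_partition <- function(x, ...) {
  cat("barcode_partition [", x$method, "]: ", length(x$assignment),
      " sequences in ", x$n_groups, " groups\n", sep = "")
  invisible(x)
}

#' Read a delimitation partition from TSV
#'
#' Expected layout: two tab-separated columns (sequence id, group id), with
#' optional \code{#}-prefixed metadata lines; a \code{#method=NAME} line sets
#' the partition's method name. Rows repeating an id with the same group are
#' deduplicated with a warning; conflicting repeats are an error.
#'
#' @param path TSV path.
#' @return a \code{barcode_partition}.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("partition file not found: ", path)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  method <- "unknown"
  m <- grep("^#method=", meta, value = TRUE)
  if (length(m)) method <- sub("^#method=", "", m[1L])
  if (!length(body)) stop("no assignments in partition file ", path)
  parts <- strsplit(body, "\t")
  if (any(lengths(parts) < 2L)) stop("malformed partition row in ", path)
  id <- vapply(parts, `[[`, "", 1L)
  grp <- vapply(parts, `[[`, "", 2L)
  key <- paste(id, grp, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate identical assignment rows in ", path, "; deduplicated")
    keep <- !duplicated(key)
    id <- id[keep]; grp <- grp[keep]
  }
  if (anyDuplicated(id)) {
    bad <- unique(id[duplicated(id)])
    stop("id(s) assigned to more than one group: ", paste(bad, collapse = ", "))
  }
  names(grp) <- id
  new_partition(grp, method = method)
}

#' Write a partition as TSV
#' @param p a \code{barcode_partition}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_partition <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#method=", p$method), con)
  if (length(p$params))
    writeLines(paste0("#", names(p$params), "=",
                      vapply(p$params, function(v) paste(format(v), collapse = ","), "")),
               con)
  writeLines(paste(names(p$assignment), p$assignment, sep = "\t"), con)
  invisible(path)
}

#' Write a data frame as a TSV summary table
#' @param df data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
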