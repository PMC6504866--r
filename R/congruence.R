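CONGRUENCE_CATEGORIES <- c("MATCH", "SINGLE", "MERGE", "SPLIT", "COMPLEX")

#' Classify one species against a delimitation partition
#'
#' Let S be the species' identified sequences inside the partition's
#' coverage and C the clusters they touch. A cluster is \emph{impure} when it
#' contains an identified sequence of another species; unidentified
#' sequences never make a cluster impure and are never classified
#' themselves. Categories:
#' \itemize{
#'   \item \code{SINGLE}: |S| = 1 and its cluster is pure (a matching
#'     singleton);
#'   \item \code{MATCH}: one cluster, pure;
#'   \item \code{MERGE}: one cluster, impure (lumped with other species);
#'   \item \code{SPLIT}: several clusters, all pure;
#'   \item \code{COMPLEX}: several clusters, at least one impure.
#' }
#'
#' @param p a \code{barcode_partition}.
#' @param labels label data frame (as in \code{aln$labels}).
#' @param species species binomial.
#' @return data frame row: \code{species}, \code{method}, \code{category},
#'   \code{n_clusters_touched}, \code{impure}.
#' @export
classify_species <- function(p, labels, species) {
  cov <- names(p$assignment)
  lab <- labels[labels$id %in% cov, , drop = FALSE]
  S <- lab$id[lab$identified & lab$species == species]
  if (!length(S))
    stop("species '", species, "' absent from the partition's coverage")
  clusters <- unique(p$assignment[S])
  impure <- vapply(clusters, function(g) {
    members <- cov[p$assignment == g]
    mlab <- lab[match(members, lab$id), , drop = FALSE]
    any(!is.na(mlab$identified) & mlab$identified & mlab$species != species)
  }, TRUE)
  nC <- length(clusters)
  category <-
    if (nC == 1L && !any(impure)) { if (length(S) == 1L) "SINGLE" else "MATCH" }
    else if (nC == 1L) "MERGE"
    else if (!any(impure)) "SPLIT"
    else "COMPLEX"
  data.frame(species = species, method = p$method, category = category,
             n_clusters_touched = nC, impure = any(impure),
             stringsAsFactors = FALSE)
}

#' Classify every identified species against a partition
#' @inheritParams classify_species
#' @return data frame, one row per species (see \code{\link{classify_species}}).
#' @export
classify_all_species <- function(p, labels) {
  cov <- names(p$assignment)
  lab <- labels[labels$id %in% cov, , drop = FALSE]
  species <- unique(lab$species[lab$identified])
  do.call(rbind, lapply(species, function(s) classify_species(p, labels, s)))
}

title_case <- function(x) paste0(toupper(substring(x, 1, 1)),
                                 tolower(substring(x, 2)))

#' Congruence of reference taxonomy with a set of delimitations
#'
#' Per species, counts how many partitions put it in each category, and
#' flags high congruence: when all methods agree the category is reported in
#' capitals; when all but one agree it is reported in parentheses (e.g.
#' \code{"(Split)"}); otherwise no flag.
#'
#' @param partitions list of \code{barcode_partition}s (>= 1; for the
#'   high-congruence flag to be meaningful use several).
#' @param labels label data frame.
#' @return a \code{congruence_table} data frame: \code{species}, one count
#'   column per category, \code{majority} and \code{high_congruence}.
#' @export
congruence_table <- function(partitions, labels) {
  stopifnot(length(partitions) >= 1L)
  cls <- lapply(partitions, classify_all_species, labels = labels)
  species <- sort(unique(unlist(lapply(cls, `[[`, "species"))))
  nm <- length(partitions)
  rows <- lapply(species, function(s) {
    cats <- vapply(cls, function(df) {
      v <- df$category[df$species == s]
      if (length(v)) v else NA_character_
    }, "")
    counts <- vapply(CONGRUENCE_CATEGORIES, function(cc) sum(cats == cc, na.rm = TRUE), 0L)
    top <- which.max(counts)
    flag <-
      if (counts[top] == nm) toupper(CONGRUENCE_CATEGORIES[top])
      else if (counts[top] == nm - 1L && nm >= 2L)
        paste0("(", title_case(CONGRUENCE_CATEGORIES[top]), ")")
      else ""
    cbind(data.frame(species = s, stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)),
          data.frame(majority = CONGRUENCE_CATEGORIES[top],
                     high_congruence = flag, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  names(out)[2:6] <- tolower(CONGRUENCE_CATEGORIES)
  class(out) <- c("congruence_table", "data.frame")
  out
}

#' Score each delimitation method against the cross-method consensus
#'
#' The consensus category for a species is the modal category across
#' methods; species with tied modes are skipped. A method's score is the
#' number of species where its category differs from the consensus.
#'
#' @param partitions list of at least 3 \code{barcode_partition}s; names (or
#'   method fields) identify methods.
#' @param labels label data frame.
#' @return data frame: \code{method}, \code{disagreements},
#'   \code{n_species_scored}.
#' @export
method_consensus_score <- function(partitions, labels) {
  stopifnot(length(partitions) >= 3L)
  meth <- if (!is.null(names(partitions)) && all(nzchar(names(partitions))))
    names(partitions) else
      make.unique(vapply(partitions, `[[`, "", "method"))
  cls <- lapply(partitions, classify_all_species, labels = labels)
  species <- sort(unique(unlist(lapply(cls, `[[`, "species"))))
  catmat <- vapply(cls, function(df)
    df$category[match(species, df$species)], character(length(species)))
  catmat <- matrix(catmat, nrow = length(species))
  scored <- 0L
  dis <- stats::setNames(integer(length(partitions)), meth)
  for (k in seq_along(species)) {
    cats <- catmat[k, ]
    tab <- table(cats[!is.na(cats)])
    if (!length(tab)) next
    top <- max(tab)
    modal <- names(tab)[tab == top]
    if (length(modal) != 1L) next   # tie: skip the species entirely
    scored <- scored + 1L
    dis <- dis + as.integer(!is.na(cats) & cats != modal)
  }
  data.frame(method = meth, disagreements = unname(dis),
             n_species_scored = scored, stringsAsFactors = FALSE)
}
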