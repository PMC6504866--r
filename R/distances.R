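#' Site-pattern counts for a sequence pair under pairwise deletion
#'
#' Counts are taken only over columns where both sequences carry an
#' unambiguous base (A/C/G/T); gaps, N and ambiguity codes are deleted
#' pairwise. Transitions are A<->G and C<->T; every other mismatch is a
#' transversion.
#'
#' @param a,b aligned sequence strings of equal length (or single-record
#'   subsets of a \code{barcode_alignment}).
#' @return list with \code{L} (compared sites), \code{P} (total transition
#'   proportion), \code{Q} (transversion proportion), \code{P1} (purine
#'   transition proportion), \code{P2} (pyrimidine transition proportion)
#'   and \code{freqs} (empirical base frequencies over the compared sites of
#'   both sequences).
#' @export
site_counts <- function(a, b) {
  if (inherits(a, "barcode_alignment")) a <- a$seqs[[1L]]
  if (inherits(b, "barcode_alignment")) b <- b$seqs[[1L]]
  if (nchar(a) != nchar(b)) stop("sequences differ in aligned length")
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  bases <- c("A", "C", "G", "T")
  ok <- ca %in% bases & cb %in% bases
  ca <- ca[ok]; cb <- cb[ok]
  L <- length(ca)
  if (!L)
    return(list(L = 0L, P = NA_real_, Q = NA_real_, P1 = NA_real_,
                P2 = NA_real_, freqs = rep(NA_real_, 4L)))
  diff <- ca != cb
  ts1 <- diff & ((ca == "A" & cb == "G") | (ca == "G" & cb == "A"))
  ts2 <- diff & ((ca == "C" & cb == "T") | (ca == "T" & cb == "C"))
  P1 <- sum(ts1) / L
  P2 <- sum(ts2) / L
  Q <- sum(diff & !ts1 & !ts2) / L
  fr <- (table(factor(ca, bases)) + table(factor(cb, bases))) / (2 * L)
  list(L = L, P = P1 + P2, Q = Q, P1 = P1, P2 = P2,
       freqs = stats::setNames(as.numeric(fr), bases))
}

#' Kimura 2-parameter distance from site counts
#'
#' \deqn{d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q)}
#' Saturated pairs (a log argument at or below zero) yield \code{NA}, the
#' package's undefined-distance flag, never an error.
#'
#' @param c a list as returned by \code{\link{site_counts}}, or a transition
#'   proportion \code{P} if \code{Q} is supplied.
#' @param Q transversion proportion (when \code{c} is numeric \code{P}).
#' @return distance in substitutions/site, or \code{NA} when undefined.
#' @export
k2p <- function(c, Q = NULL) {
  if (is.list(c)) { P <- c$P; Q <- c$Q; if (!is.null(c$L) && c$L == 0) return(NA_real_) }
  else P <- c
  if (is.na(P) || is.na(Q)) return(NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Tamura-Nei (1993) distance from site counts
#'
#' Uses empirical base frequencies estimated from the pair's compared sites.
#' Reduces to the Kimura 2-parameter distance when all four frequencies are
#' 0.25 and the two transition classes are balanced. Degenerate frequency
#' configurations or saturated log arguments yield \code{NA}.
#'
#' @param c list as returned by \code{\link{site_counts}} (needs \code{P1},
#'   \code{P2}, \code{Q} and \code{freqs}).
#' @return distance in substitutions/site, or \code{NA} when undefined.
#' @export
tn93 <- function(c) {
  if (!is.null(c$L) && c$L == 0) return(NA_real_)
  P1 <- c$P1; P2 <- c$P2; Q <- c$Q
  if (anyNA(c(P1, P2, Q))) return(NA_real_)
  f <- c$freqs
  piA <- f[["A"]]; piC <- f[["C"]]; piG <- f[["G"]]; piT <- f[["T"]]
  piR <- piA + piG; piY <- piC + piT
  term <- function(coef, w) {
    if (coef <= 0) return(0)
    if (w <= 0) return(NA_real_)
    -coef * log(w)
  }
  t1 <- if (piA * piG == 0) { if (P1 > 0) NA_real_ else 0 } else
    term(2 * piA * piG / piR, 1 - piR * P1 / (2 * piA * piG) - Q / (2 * piR))
  t2 <- if (piC * piT == 0) { if (P2 > 0) NA_real_ else 0 } else
    term(2 * piC * piT / piY, 1 - piY * P2 / (2 * piC * piT) - Q / (2 * piY))
  c3 <- 2 * (piR * piY -
             (if (piR > 0) piA * piG * piY / piR else 0) -
             (if (piY > 0) piC * piT * piR / piY else 0))
  t3 <- if (piR * piY == 0) { if (Q > 0) NA_real_ else 0 } else
    term(c3, 1 - Q / (2 * piR * piY))
  t1 + t2 + t3
}

#' Pairwise distance matrix for an alignment
#'
#' All pairs under pairwise deletion, fully vectorized. Saturated or
#' non-overlapping pairs are flagged undefined (\code{NA}) and reported in a
#' warning; downstream consumers treat them as "not comparable".
#'
#' @param aln a \code{barcode_alignment} with at least two records.
#' @param model \code{"K2P"} (default), \code{"TN93"} or \code{"p"}
#'   (uncorrected proportion of differing sites).
#' @return a \code{distance_matrix}: list with \code{ids}, symmetric matrix
#'   \code{d} (zero diagonal, \code{NA} = undefined) and \code{model}.
#' @export
distance_matrix <- function(aln, model = c("K2P", "TN93", "p")) {
  model <- match.arg(model)
  if (length(aln$seqs) < 2L) stop("need at least 2 sequences")
  enc <- encode_alignment(aln)
  pc <- pairwise_counts(enc)
  L <- pc$L
  P <- ifelse(L > 0, pc$ts / L, NA_real_)
  Q <- ifelse(L > 0, pc$tv / L, NA_real_)
  if (model == "p") {
    d <- P + Q
  } else if (model == "K2P") {
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    d <- ifelse(!is.na(w1) & w1 > 0 & w2 > 0,
                -0.5 * log(pmax(w1, .Machine$double.xmin)) -
                  0.25 * log(pmax(w2, .Machine$double.xmin)),
                NA_real_)
  } else {
    P1 <- ifelse(L > 0, pc$tsR / L, NA_real_)
    P2 <- ifelse(L > 0, pc$tsY / L, NA_real_)
    piA <- ifelse(L > 0, pc$fA / (2 * L), NA_real_)
    piC <- ifelse(L > 0, pc$fC / (2 * L), NA_real_)
    piG <- ifelse(L > 0, pc$fG / (2 * L), NA_real_)
    piT <- ifelse(L > 0, pc$fT / (2 * L), NA_real_)
    piR <- piA + piG; piY <- piC + piT
    g1 <- piA * piG; g2 <- piC * piT
    w1 <- ifelse(g1 > 0, 1 - piR * P1 / (2 * g1) - Q / (2 * piR), NA_real_)
    w2 <- ifelse(g2 > 0, 1 - piY * P2 / (2 * g2) - Q / (2 * piY), NA_real_)
    w3 <- ifelse(piR * piY > 0, 1 - Q / (2 * piR * piY), NA_real_)
    t1 <- ifelse(g1 == 0, ifelse(P1 > 0, NA_real_, 0),
                 ifelse(w1 > 0, -(2 * g1 / piR) * log(pmax(w1, .Machine$double.xmin)),
                        NA_real_))
    t2 <- ifelse(g2 == 0, ifelse(P2 > 0, NA_real_, 0),
                 ifelse(w2 > 0, -(2 * g2 / piY) * log(pmax(w2, .Machine$double.xmin)),
                        NA_real_))
    c3 <- 2 * (piR * piY - ifelse(piR > 0, g1 * piY / piR, 0) -
                 ifelse(piY > 0, g2 * piR / piY, 0))
    t3 <- ifelse(piR * piY == 0, ifelse(Q > 0, NA_real_, 0),
                 ifelse(w3 > 0, -c3 * log(pmax(w3, .Machine$double.xmin)), NA_real_))
    d <- t1 + t2 + t3
  }
  diag(d) <- 0
  dimnames(d) <- list(enc$ids, enc$ids)
  n_undef <- sum(is.na(d[upper.tri(d)]))
  if (n_undef > 0)
    warning(n_undef, " sequence pair(s) have undefined (saturated or ",
            "non-overlapping) distances; flagged NA")
  structure(list(ids = enc$ids, d = d, model = model),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix [", x$model, "]: ", length(x$ids), " sequences, ",
      sum(is.na(x$d[upper.tri(x$d)])), " undefined pair(s)\n", sep = "")
  invisible(x)
}

# intra/inter index helpers
.dm_check_labels <- function(m, labels) {
  if (!all(m$ids %in% labels$id))
    stop("labels missing for id(s): ",
         paste(setdiff(m$ids, labels$id), collapse = ", "))
  labels[match(m$ids, labels$id), , drop = FALSE]
}

#' Per-species barcode-gap summaries
#'
#' For every identified species: sample size, maximum and mean intraspecific
#' distance, nearest non-conspecific species and the minimum distance to it.
#' Unidentified sequences, and any ids in \code{exclude} (typically
#' misidentification flags), are removed before summarizing. Undefined
#' distances are dropped from minima/maxima with a warning.
#'
#' @param m a \code{distance_matrix}.
#' @param labels label data frame (as in \code{aln$labels}).
#' @param exclude ids to drop before summarizing.
#' @param tree optional rooted \code{phylo}; adds a \code{monophyletic}
#'   column via \code{\link{is_monophyletic}}.
#' @return data frame with one row per species: \code{species}, \code{n},
#'   \code{max_intra}, \code{mean_intra}, \code{nearest_species},
#'   \code{min_inter}, \code{monophyletic}.
#' @export
species_summaries <- function(m, labels, exclude = character(), tree = NULL) {
  lab <- .dm_check_labels(m, labels)
  keep <- lab$identified & !(lab$id %in% exclude)
  if (!any(keep)) stop("no identified sequences to summarize")
  d <- m$d[keep, keep, drop = FALSE]
  sp <- lab$species[keep]
  species <- unique(sp)
  if (anyNA(d[upper.tri(d)]))
    warning("undefined distances excluded from species summaries")
  res <- lapply(species, function(s) {
    own <- which(sp == s)
    oth <- which(sp != s)
    if (length(own) >= 2L) {
      dd <- d[own, own, drop = FALSE][upper.tri(diag(length(own)))]
      dd <- dd[!is.na(dd)]
      max_intra <- if (length(dd)) max(dd) else NA_real_
      mean_intra <- if (length(dd)) mean(dd) else NA_real_
    } else {
      max_intra <- NA_real_; mean_intra <- NA_real_
    }
    if (length(oth)) {
      cross <- d[own, oth, drop = FALSE]
      per_oth_sp <- tapply(seq_along(oth), sp[oth], function(ix)
        suppressWarnings(min(cross[, ix], na.rm = TRUE)))
      per_oth_sp[!is.finite(per_oth_sp)] <- NA
      nn <- names(per_oth_sp)[which.min(per_oth_sp)]
      mi <- suppressWarnings(min(per_oth_sp, na.rm = TRUE))
      if (!is.finite(mi)) { nn <- NA_character_; mi <- NA_real_ }
    } else {
      nn <- NA_character_; mi <- NA_real_
    }
    mono <- if (!is.null(tree))
      tryCatch(is_monophyletic(tree, labels, s), error = function(e) NA)
    else NA
    data.frame(species = s, n = length(own), max_intra = max_intra,
               mean_intra = mean_intra, nearest_species = nn,
               min_inter = mi, monophyletic = mono,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("species_summary", "data.frame")
  out
}

#' Minimum and mean distance between every species pair
#'
#' Supports the low-interspecific-divergence report (species pairs whose
#' minimum distance falls below a diagnostic threshold such as 0.03).
#'
#' @inheritParams species_summaries
#' @param threshold optional; keep only pairs with minimum distance below it.
#' @return data frame: \code{species_a}, \code{species_b}, \code{min_dist},
#'   \code{mean_dist}.
#' @export
species_pair_minima <- function(m, labels, exclude = character(),
                                threshold = NULL) {
  lab <- .dm_check_labels(m, labels)
  keep <- lab$identified & !(lab$id %in% exclude)
  d <- m$d[keep, keep, drop = FALSE]
  sp <- lab$species[keep]
  species <- sort(unique(sp))
  rows <- list()
  for (i in seq_along(species)) for (j in seq_len(i - 1L)) {
    a <- which(sp == species[i]); b <- which(sp == species[j])
    cross <- as.numeric(d[a, b, drop = FALSE])
    cross <- cross[!is.na(cross)]
    if (!length(cross)) next
    rows[[length(rows) + 1L]] <- data.frame(
      species_a = species[j], species_b = species[i],
      min_dist = min(cross), mean_dist = mean(cross),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species_a = character(), species_b = character(),
               min_dist = numeric(), mean_dist = numeric())
  if (!is.null(threshold)) out <- out[out$min_dist < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bootstrap standard error of an alignment statistic
#'
#' Alignment columns are resampled with replacement (the MEGA convention);
#' the statistic is recomputed per replicate and the SE is the standard
#' deviation across replicates. Replicates where the statistic is undefined
#' are dropped and counted.
#'
#' @param aln a \code{barcode_alignment}.
#' @param statistic function taking a \code{barcode_alignment} and returning
#'   a single numeric (see \code{\link{stat_mean_intraspecific}}).
#' @param reps bootstrap replicates (default 500).
#' @param seed integer seed for reproducibility.
#' @return the SE, with attribute \code{n_used} = replicates retained.
#' @export
bootstrap_se <- function(aln, statistic, reps = 500L, seed = NULL) {
  stopifnot(reps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  L <- unique(nchar(aln$seqs))
  if (length(L) != 1L) stop("alignment must be equal-width for bootstrapping")
  chars <- strsplit(aln$seqs, "")
  vals <- vapply(seq_len(reps), function(r) {
    cols <- sample.int(L, L, replace = TRUE)
    seqs <- vapply(chars, function(ch) paste(ch[cols], collapse = ""), "")
    tryCatch(statistic(new_alignment(unname(seqs), aln$labels)),
             error = function(e) NA_real_)
  }, 1)
  used <- sum(!is.na(vals))
  se <- stats::sd(vals[!is.na(vals)])
  attr(se, "n_used") <- used
  se
}

#' Statistic builders for bootstrap standard errors
#'
#' \code{stat_mean_intraspecific(species)} returns the mean within-species
#' distance of one species; \code{stat_mean_between(a, b)} the mean distance
#' between two species. Both subset the alignment to the relevant sequences
#' before computing, so they stay cheap inside the bootstrap loop.
#'
#' @param species,a,b species binomials.
#' @param model distance model passed to \code{\link{distance_matrix}}.
#' @return a function of a \code{barcode_alignment} returning a numeric.
#' @export
stat_mean_intraspecific <- function(species, model = "K2P") {
  force(species); force(model)
  function(aln) {
    ids <- aln$labels$id[aln$labels$identified & aln$labels$species == species]
    if (length(ids) < 2L) return(NA_real_)
    sub <- subset_alignment(aln, ids)
    d <- suppressWarnings(distance_matrix(sub, model)$d)
    mean(d[upper.tri(d)], na.rm = TRUE)
  }
}

#' @rdname stat_mean_intraspecific
#' @export
stat_mean_between <- function(a, b, model = "K2P") {
  force(a); force(b); force(model)
  function(aln) {
    ia <- aln$labels$id[aln$labels$identified & aln$labels$species == a]
    ib <- aln$labels$id[aln$labels$identified & aln$labels$species == b]
    if (!length(ia) || !length(ib)) return(NA_real_)
    sub <- subset_alignment(aln, c(ia, ib))
    d <- suppressWarnings(distance_matrix(sub, model)$d)
    mean(d[sub$labels$species == a, sub$labels$species == b], na.rm = TRUE)
  }
}

#' Write a distance matrix as lower-triangle TSV or square PHYLIP
#'
#' @param m a \code{distance_matrix}.
#' @param path output path.
#' @param format \code{"tsv"} (lower triangle with ids) or \code{"phylip"}
#'   (square, relaxed names).
#' @return \code{path}, invisibly.
#' @export
write_distance_matrix <- function(m, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  n <- length(m$ids)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "phylip") {
    writeLines(sprintf("%d", n), con)
    for (i in seq_len(n))
      writeLines(paste(c(m$ids[i], sprintf("%.8f", m$d[i, ])), collapse = "\t"),
                 con)
  } else {
    for (i in seq_len(n)) {
      row <- if (i > 1) sprintf("%.8f", m$d[i, seq_len(i - 1L)]) else character()
      writeLines(paste(c(m$ids[i], row), collapse = "\t"), con)
    }
  }
  invisible(path)
}
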