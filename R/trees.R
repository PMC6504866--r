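#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Deterministic:
#' ties in Q are broken by the smallest (row, column) index pair in the
#' current join order. Negative estimated branch lengths are clamped to zero
#' with the deficit transferred to the sister branch, preserving path
#' lengths. The result is an unrooted \code{ape} \code{phylo} with a
#' trifurcating root node.
#'
#' @param m a \code{distance_matrix} with no undefined entries.
#' @return an \code{ape::phylo} tree, leaf names = sequence ids.
#' @export
nj_tree <- function(m) {
  n <- length(m$ids)
  if (n < 3L) stop("need at least 3 sequences for neighbor joining")
  if (anyNA(m$d))
    stop("distance matrix has undefined entries; impute or drop those ",
         "sequences before tree building")
  D <- m$d
  frag <- m$ids      # newick fragment per active node
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(D) > 3L) {
    mm <- nrow(D)
    r <- rowSums(D)
    Q <- (mm - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (mm - 2))
    lj <- D[i, j] - li
    l <- clamp_pair(li, lj)
    newfrag <- paste0("(", frag[i], ":", fmt(l[1L]), ",",
                      frag[j], ":", fmt(l[2L]), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(mm), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    D <- D2
  }
  # resolve the final three nodes around the (trifurcating) root
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  l <- pmax(c(l1, l2, l3), 0)
  nwk <- paste0("(", frag[1L], ":", fmt(l[1L]), ",",
                frag[2L], ":", fmt(l[2L]), ",",
                frag[3L], ":", fmt(l[3L]), ");")
  ape::read.tree(text = nwk)
}

#' Root a tree on an outgroup
#'
#' Places the root on the branch separating the outgroup from the ingroup.
#' The outgroup must be a single leaf or form a clade of the unrooted tree.
#'
#' @param t an \code{ape::phylo}.
#' @param outgroup_ids leaf names of the outgroup.
#' @return a rooted \code{phylo}.
#' @export
root_on_outgroup <- function(t, outgroup_ids) {
  missing <- setdiff(outgroup_ids, t$tip.label)
  if (length(missing))
    stop("outgroup leaves not in tree: ", paste(missing, collapse = ", "))
  rooted <- tryCatch(
    ape::root(t, outgroup = outgroup_ids, resolve.root = TRUE),
    error = function(e)
      stop("outgroup is not monophyletic in the unrooted tree; offending ",
           "leaves: ", paste(outgroup_ids, collapse = ", ")))
  rooted
}

#' Read / write Newick trees
#'
#' Thin wrappers over \code{ape}; support values are tolerated and kept as
#' node labels.
#'
#' @param path Newick file path.
#' @param t an \code{ape::phylo}.
#' @return \code{read_newick}: a \code{phylo}; \code{write_newick}:
#'   \code{path}, invisibly.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @export
write_newick <- function(t, path) {
  ape::write.tree(t, file = path)
  invisible(path)
}

#' Test species monophyly on a rooted tree
#'
#' A species is monophyletic when the smallest clade containing all of its
#' leaves contains no \emph{identified} leaf of another species. Unidentified
#' leaves (e.g. \code{"Genus sp."} or \code{"aff."} material) are transparent:
#' they sit inside the clade without breaking monophyly.
#'
#' @param t a rooted \code{ape::phylo}.
#' @param labels label data frame (as in \code{aln$labels}); rows are matched
#'   to tree leaves by \code{id}. Leaves without a label row are treated as
#'   unidentified.
#' @param species the species binomial to test.
#' @return logical.
#' @export
is_monophyletic <- function(t, labels, species) {
  lab <- labels[match(t$tip.label, labels$id), , drop = FALSE]
  tip_sp <- ifelse(!is.na(lab$identified) & lab$identified, lab$species, "")
  tips <- t$tip.label[tip_sp == species]
  if (!length(tips))
    stop("species '", species, "' has no identified leaves in the tree")
  if (length(tips) == 1L) return(TRUE)
  mrca <- ape::getMRCA(t, tips)
  clade_tips <- ape::extract.clade(t, mrca)$tip.label
  clade_sp <- tip_sp[match(clade_tips, t$tip.label)]
  !any(clade_sp != "" & clade_sp != species)
}
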