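# Internal numeric encoding of an alignment.
#
# Columns holding anything other than an unambiguous A/C/G/T (gaps, N, IUPAC
# ambiguity codes) are treated as missing for comparison purposes; per-consumer
# semantics (pairwise deletion, any-base matching) are built on these
# indicators.
#
# Returns: list with
#   base  n x L integer matrix, A=1 C=2 G=3 T=4, 0 = not an unambiguous base
#   ind   list of four n x L 0/1 indicator matrices (A, C, G, T)
#   valid n x L 0/1 matrix (unambiguous base present)
encode_alignment <- function(aln) {
  n <- length(aln$seqs)
  if (!n) stop("empty alignment")
  L <- unique(nchar(aln$seqs))
  if (length(L) > 1L)
    stop("alignment is ragged (", paste(range(nchar(aln$seqs)), collapse = "-"),
         " columns); crop first")
  chm <- matrix(unlist(strsplit(aln$seqs, ""), use.names = FALSE),
                nrow = n, ncol = L, byrow = TRUE)
  base <- matrix(0L, n, L)
  base[chm == "A"] <- 1L
  base[chm == "C"] <- 2L
  base[chm == "G"] <- 3L
  base[chm == "T"] <- 4L
  ind <- lapply(1:4, function(b) {
    m <- matrix(0, n, L)
    m[base == b] <- 1
    m
  })
  valid <- ind[[1]] + ind[[2]] + ind[[3]] + ind[[4]]
  list(base = base, ind = ind, valid = valid, n = n, L = L,
       ids = aln$labels$id)
}

# Pairwise counts over both-unambiguous columns, fully vectorized.
# Returns matrices (n x n): L (compared sites), match, ts (transitions),
# tsR (A<->G), tsY (C<->T), tv (transversions), and per-pair base-occurrence
# counts fA..fT (number of occurrences of each base across BOTH sequences
# over the pair's compared sites).
pairwise_counts <- function(enc) {
  ind <- enc$ind; V <- enc$valid
  Lp <- tcrossprod(V)
  match <- tcrossprod(ind[[1]]) + tcrossprod(ind[[2]]) +
    tcrossprod(ind[[3]]) + tcrossprod(ind[[4]])
  tsR <- tcrossprod(ind[[1]], ind[[3]])  # A in i, G in j
  tsR <- tsR + t(tsR)
  tsY <- tcrossprod(ind[[2]], ind[[4]])
  tsY <- tsY + t(tsY)
  ts <- tsR + tsY
  tv <- Lp - match - ts
  # base b count for pair (i,j): sites valid in both where i has b, plus where j has b
  f <- lapply(1:4, function(b) {
    m <- tcrossprod(ind[[b]], V)  # i has b, j valid
    m + t(m)
  })
  list(L = Lp, match = match, ts = ts, tsR = tsR, tsY = tsY, tv = tv,
       fA = f[[1]], fC = f[[2]], fG = f[[3]], fT = f[[4]])
}

# union-find over 1..n
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}
components_from_pairs <- function(n, ii, jj) {
  parent <- uf_new(n)
  for (k in seq_along(ii)) parent <- uf_union(parent, ii[k], jj[k])
  vapply(seq_len(n), function(i) uf_find(parent, i), 1L)
}
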