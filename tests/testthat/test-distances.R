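test_that("site counts use pairwise deletion and classify substitution types", {
  a <- strrep("A", 100)
  expect_equal(site_counts(a, a), site_counts(a, a))
  sc <- site_counts(a, a)
  expect_equal(sc$L, 100L)
  expect_equal(sc$P, 0)
  expect_equal(sc$Q, 0)

  # 10 A<->G transitions and 5 A<->C transversions in 100 sites
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  sc <- site_counts(a, b)
  expect_equal(sc$P, 0.10)
  expect_equal(sc$Q, 0.05)
  expect_equal(sc$P1, 0.10)
  expect_equal(sc$P2, 0)

  # N or gap in either record removes the column from L
  c1 <- paste0("N", strrep("A", 98), "-")
  sc <- site_counts(a, c1)
  expect_equal(sc$L, 98L)
})

test_that("K2P matches the closed form and flags saturation", {
  expect_equal(k2p(0, 0), 0)
  # -1/2 ln(0.75) - 1/4 ln(0.90), evaluated independently
  expect_equal(k2p(0.10, 0.05), -0.5 * log(0.75) - 0.25 * log(0.90),
               tolerance = 1e-12)
  expect_equal(k2p(0.10, 0.05), 0.170181165, tolerance = 1e-9)
  expect_true(is.na(k2p(0.5, 0)))       # log of zero: undefined, no error
  expect_true(is.na(k2p(0.2, 0.5)))
  expect_true(is.na(k2p(list(L = 0L, P = NA, Q = NA))))
})

test_that("TN93 reduces to K2P under equal frequencies (1000 random draws)", {
  set.seed(7)
  for (r in 1:1000) {
    repeat {
      P1 <- runif(1, 0, 0.12); P2 <- P1
      Q <- runif(1, 0, 0.12)
      if (1 - 2 * (P1 + P2) - Q > 0.05 && 1 - 2 * Q > 0.05) break
    }
    sc <- list(L = 1000L, P = P1 + P2, Q = Q, P1 = P1, P2 = P2,
               freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
    expect_equal(tn93(sc), k2p(P1 + P2, Q), tolerance = 1e-9)
  }
})

test_that("TN93 handles zero divergence and saturation", {
  sc0 <- list(L = 100L, P = 0, Q = 0, P1 = 0, P2 = 0,
              freqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
  expect_equal(tn93(sc0), 0)
  sat <- list(L = 100L, P = 0.5, Q = 0.4, P1 = 0.5, P2 = 0,
              freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_true(is.na(tn93(sat)))
})

test_that("distance_matrix agrees with the per-pair oracle and with ape", {
  sim <- quick_sim(21, n_species = 4, k = 3, L = 300)
  aln <- sim$alignment
  for (model in c("p", "K2P", "TN93")) {
    dm <- distance_matrix(aln, model)
    expect_true(isSymmetric(dm$d))
    expect_equal(unname(diag(dm$d)), rep(0, length(aln)))
    # independent per-pair recomputation through site_counts
    for (pair in list(c(1, 2), c(3, 7), c(5, 12))) {
      sc <- site_counts(aln$seqs[[pair[1]]], aln$seqs[[pair[2]]])
      exp <- switch(model, p = sc$P + sc$Q, K2P = k2p(sc), TN93 = tn93(sc))
      expect_equal(unname(dm$d[pair[1], pair[2]]), exp, tolerance = 1e-12)
    }
  }
  # cross-check against ape::dist.dna on the same data
  bin <- ape::as.DNAbin(lapply(strsplit(tolower(aln$seqs), ""), identity))
  names(bin) <- aln$labels$id
  dm <- distance_matrix(aln, "K2P")
  ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  expect_equal(unname(dm$d), unname(ref[aln$labels$id, aln$labels$id]),
               tolerance = 1e-8)
  # TN93 estimates base frequencies per pair (the pairwise-deletion
  # convention); handing ape just the pair makes its frequency pool agree
  dmt <- distance_matrix(aln, "TN93")
  for (pair in list(c(1, 2), c(2, 9), c(4, 11))) {
    ref2 <- ape::dist.dna(bin[pair], model = "TN93", pairwise.deletion = TRUE)
    expect_equal(unname(dmt$d[pair[1], pair[2]]), as.numeric(ref2),
                 tolerance = 1e-8)
  }
})

test_that("three identical records give a zero matrix; K2P inflates p", {
  s <- strrep("ACGT", 25)
  aln <- make_aln(c(s, s, s), c("a|X a", "b|X b", "c|X c"))
  expect_true(all(distance_matrix(aln, "K2P")$d == 0))

  sim <- quick_sim(22, n_species = 5, k = 3, L = 400)
  dp <- distance_matrix(sim$alignment, "p")$d
  dk <- distance_matrix(sim$alignment, "K2P")$d
  expect_true(all(dk >= dp - 1e-12, na.rm = TRUE))
})

test_that("species summaries report intra/inter structure and handle singletons", {
  s <- strrep("ACGT", 25)           # 100 bp
  mut <- function(s, n, from = "A", to = "G") {
    ch <- strsplit(s, "")[[1]]
    ix <- which(ch == from)[seq_len(n)]
    ch[ix] <- to
    paste(ch, collapse = "")
  }
  aln <- make_aln(c(s, s, mut(s, 10), mut(s, 11), mut(s, 22, "C", "A")),
                  c("a1|Alpha one", "a2|Alpha one",
                    "b1|Beta two", "b2|Beta two", "c1|Gamma three"))
  dm <- distance_matrix(aln, "p")
  su <- species_summaries(dm, aln$labels)
  a <- su[su$species == "Alpha one", ]
  expect_equal(a$max_intra, 0)           # identical members
  expect_equal(a$n, 2L)
  b <- su[su$species == "Beta two", ]
  expect_equal(b$max_intra, 0.01)
  g <- su[su$species == "Gamma three", ]
  expect_true(is.na(g$max_intra))        # singleton: intra fields empty
  expect_false(is.na(g$min_inter))
  # nearest-neighbour minima are symmetric for the two-species restriction
  expect_equal(a$min_inter, 0.10)
  expect_equal(a$nearest_species, "Beta two")
  expect_equal(b$min_inter, 0.10)
})

test_that("flagged and unidentified sequences are excluded before summarizing", {
  sim <- quick_sim(23, n_species = 5, k = 4, L = 400, unid = 0.2)
  dm <- distance_matrix(sim$alignment, "K2P")
  su <- species_summaries(dm, sim$alignment$labels)
  expect_true(all(su$n <= 4))
  expect_false(any(grepl(" sp\\.", su$species)))
  one <- su$species[1]
  drop_id <- sim$alignment$labels$id[sim$alignment$labels$species == one][1]
  su2 <- species_summaries(dm, sim$alignment$labels, exclude = drop_id)
  expect_equal(su2$n[su2$species == one], su$n[su$species == one] - 1L)
})

test_that("planted barcode gap separates intra from inter in the summaries", {
  for (seed in 1:5) {
    sim <- quick_sim(seed + 200)
    dm <- distance_matrix(sim$alignment, "K2P")
    su <- species_summaries(dm, sim$alignment$labels)
    multi <- su[su$n >= 2, ]
    expect_true(all(multi$max_intra < multi$min_inter))
  }
})

test_that("species pair minima support the low-divergence threshold report", {
  sim <- quick_sim(24, n_species = 6, k = 3, L = 400)
  dm <- distance_matrix(sim$alignment, "K2P")
  pm <- species_pair_minima(dm, sim$alignment$labels)
  expect_equal(nrow(pm), choose(6, 2))
  su <- species_summaries(dm, sim$alignment$labels)
  for (i in seq_len(nrow(su)))
    expect_equal(min(pm$min_dist[pm$species_a == su$species[i] |
                                 pm$species_b == su$species[i]]),
                 su$min_inter[i], tolerance = 1e-12)
  thr <- stats::median(pm$min_dist)
  expect_true(all(species_pair_minima(dm, sim$alignment$labels,
                                      threshold = thr)$min_dist < thr))
})

test_that("bootstrap SE is deterministic, zero for identical data, and stable", {
  s <- strrep("ACGT", 50)
  ident <- make_aln(c(s, s, s), c("a|X a", "b|X a", "c|X a"))
  stat <- stat_mean_intraspecific("X a", "K2P")
  expect_equal(as.numeric(bootstrap_se(ident, stat, reps = 30, seed = 1)), 0)

  sim <- quick_sim(25, n_species = 2, k = 4, L = 200)
  sp <- sim$alignment$labels$species[1]
  stat <- stat_mean_intraspecific(sp, "K2P")
  se1 <- bootstrap_se(sim$alignment, stat, reps = 100, seed = 99)
  se2 <- bootstrap_se(sim$alignment, stat, reps = 100, seed = 99)
  expect_identical(se1, se2)

  # 500 replicates land within 20% of an oversampled (5000-rep) estimate
  se500 <- as.numeric(bootstrap_se(sim$alignment, stat, reps = 500, seed = 7))
  se5000 <- as.numeric(bootstrap_se(sim$alignment, stat, reps = 5000, seed = 8))
  expect_lt(abs(se500 - se5000) / se5000, 0.2)
})
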