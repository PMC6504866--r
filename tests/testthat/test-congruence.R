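ref_labels <- parse_taxon_labels(c("a|Alpha one", "b|Alpha one", "c|Beta two"))

test_that("category definitions behave on the worked three-sequence cases", {
  # partition matches taxonomy: multi-member species MATCH, singleton SINGLE
  p <- new_partition(c(a = 1, b = 1, c = 2))
  expect_equal(classify_species(p, ref_labels, "Alpha one")$category, "MATCH")
  expect_equal(classify_species(p, ref_labels, "Beta two")$category, "SINGLE")

  # everything lumped: both MERGE
  p2 <- new_partition(c(a = 1, b = 1, c = 1))
  expect_equal(classify_species(p2, ref_labels, "Alpha one")$category, "MERGE")
  expect_equal(classify_species(p2, ref_labels, "Beta two")$category, "MERGE")

  # {a,c},{b}: Alpha is split with one impure part, Beta merged
  p3 <- new_partition(c(a = 1, c = 1, b = 2))
  r3 <- classify_species(p3, ref_labels, "Alpha one")
  expect_equal(r3$category, "COMPLEX")
  expect_equal(r3$n_clusters_touched, 2L)
  expect_true(r3$impure)
  expect_equal(classify_species(p3, ref_labels, "Beta two")$category, "MERGE")

  expect_error(classify_species(p, ref_labels, "Gamma three"), "absent")
})

test_that("unidentified sequences never make a cluster impure", {
  labs <- parse_taxon_labels(c("a|Alpha one", "b|Alpha one", "u|Alpha sp."))
  p <- new_partition(c(a = 1, b = 1, u = 1))
  expect_equal(classify_species(p, labs, "Alpha one")$category, "MATCH")
  expect_false("Alpha sp." %in% classify_all_species(p, labs)$species)
})

test_that("classifier agrees with the brute-force census on every partition of 6", {
  labs <- parse_taxon_labels(c("a|S one", "b|S one", "c|S one",
                               "d|T two", "e|T two", "f|U three"))
  ids <- labs$id
  parts <- all_set_partitions(6)
  expect_length(parts, 203L)
  for (rg in parts) {
    p <- new_partition(setNames(rg, ids))
    for (sp in c("S one", "T two", "U three")) {
      expect_equal(classify_species(p, labs, sp)$category,
                   brute_classify(p$assignment, labs, sp),
                   info = paste(paste(rg, collapse = ""), sp))
    }
  }
})

test_that("classification is invariant to relabeling and sequence order", {
  labs <- parse_taxon_labels(c("a|S one", "b|S one", "c|T two", "d|T two"))
  p <- new_partition(c(a = 1, b = 2, c = 2, d = 3))
  relab <- new_partition(c(d = 30, c = 20, b = 20, a = 10))
  for (sp in c("S one", "T two"))
    expect_equal(classify_species(p, labs, sp)$category,
                 classify_species(relab, labs, sp)$category)
})

test_that("refining a partition never introduces impurity", {
  set.seed(61)
  labs <- parse_taxon_labels(paste0(letters[1:8], "|",
                                    rep(c("S one", "T two"), each = 4)))
  for (r in 1:30) {
    rg <- sample(1:4, 8, replace = TRUE)
    p <- new_partition(setNames(rg, letters[1:8]))
    # split one multi-member cluster into two
    tab <- table(p$assignment)
    big <- as.integer(names(tab)[tab >= 2][1])
    if (is.na(big)) next
    members <- names(p$assignment)[p$assignment == big]
    moved <- sample(members, 1)
    rg2 <- p$assignment
    rg2[moved] <- max(rg2) + 1L
    p2 <- new_partition(rg2)
    for (sp in c("S one", "T two")) {
      before <- classify_species(p, labs, sp)
      after <- classify_species(p2, labs, sp)
      # a split can only touch more clusters, and purity can only improve
      expect_gte(after$n_clusters_touched, before$n_clusters_touched)
      if (!before$impure) expect_false(after$impure)
      if (before$category == "MATCH")
        expect_true(after$category %in% c("MATCH", "SPLIT", "SINGLE"))
    }
  }
})

test_that("congruence table counts categories and flags high congruence", {
  labs <- parse_taxon_labels(c("a|S one", "b|S one", "c|T two"))
  match_p <- new_partition(c(a = 1, b = 1, c = 2))
  split_p <- new_partition(c(a = 1, b = 2, c = 3))
  twelve <- rep(list(match_p), 12)
  tab <- congruence_table(twelve, labs)
  s1 <- tab[tab$species == "S one", ]
  expect_equal(s1$match, 12L)
  expect_equal(s1$high_congruence, "MATCH")
  expect_equal(tab$high_congruence[tab$species == "T two"], "SINGLE")

  eleven <- c(rep(list(split_p), 11), list(match_p))
  tab2 <- congruence_table(eleven, labs)
  s1 <- tab2[tab2$species == "S one", ]
  expect_equal(s1$split, 11L)
  expect_equal(s1$match, 1L)
  expect_equal(s1$high_congruence, "(Split)")

  sixsix <- c(rep(list(split_p), 6), rep(list(match_p), 6))
  tab3 <- congruence_table(sixsix, labs)
  expect_equal(tab3$high_congruence[tab3$species == "S one"], "")
  expect_equal(sum(tab3[tab3$species == "S one",
                        c("match", "single", "merge", "split", "complex")]),
               12L)
})

test_that("consensus scoring counts disagreements and skips tied species", {
  labs <- parse_taxon_labels(c("a|S one", "b|S one", "c|T two", "d|T two"))
  match_p <- new_partition(c(a = 1, b = 1, c = 2, d = 2))
  split_p <- new_partition(c(a = 1, b = 2, c = 3, d = 3))

  sc <- method_consensus_score(list(m1 = match_p, m2 = match_p, m3 = match_p),
                               labs)
  expect_equal(sc$disagreements, c(0L, 0L, 0L))

  sc2 <- method_consensus_score(list(m1 = match_p, m2 = match_p,
                                     m3 = match_p, dev = split_p), labs)
  expect_equal(sc2$disagreements[sc2$method == "dev"], 1L)
  expect_equal(sum(sc2$disagreements[sc2$method != "dev"]), 0L)

  # 2 vs 2 on S one: tie, species excluded from every method's score
  mix <- list(m1 = match_p, m2 = match_p, m3 = split_p, m4 = split_p)
  sc3 <- method_consensus_score(mix, labs)
  expect_equal(unique(sc3$n_species_scored), 1L)   # only T two scored
  expect_equal(sc3$disagreements, rep(0L, 4))      # T two is MATCH everywhere
})
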