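test_that("configuration invariants are enforced", {
  expect_error(sim_config(delta_intra = 0.05, delta_inter = 0.01))
  expect_error(sim_config(n_species = 1, mislabel_rate = 0.1))
  expect_error(sim_config(base_freqs = c(0.5, 0.5, 0.2, 0.2)))
  expect_error(sim_config(L = 400, short_rate = 0.1, short_len = 500))
  cfg <- sim_config(seed = 1)
  expect_equal(cfg$L, 667L)
  expect_equal(cfg$delta_inter / cfg$delta_intra, 10)
})

test_that("the same seed reproduces the library byte for byte", {
  cfg <- sim_config(n_species = 6, mean_samples = 4, L = 300,
                    unidentified_rate = 0.2, mislabel_rate = 0.05,
                    short_rate = 0.1, short_len = 200, seed = 99)
  a <- simulate_library(cfg)
  b <- simulate_library(cfg)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(a$alignment, f1)
  write_alignment(b$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(a$truth$injected_errors, b$truth$injected_errors)
})

test_that("zero intraspecific divergence collapses to one haplotype per species", {
  cfg <- sim_config(n_species = 10, sampling = "fixed", mean_samples = 5,
                    L = 400, delta_intra = 0, delta_inter = 0.05,
                    mislabel_rate = 0, unidentified_rate = 0, short_rate = 0,
                    seed = 5)
  sim <- simulate_library(cfg)
  out <- collapse_haplotypes(sim$alignment)
  expect_equal(length(out$alignment), 10L)
  expect_true(all(out$map$multiplicity == 5L))
})

test_that("injected structure matches the written labels", {
  cfg <- sim_config(n_species = 8, sampling = "fixed", mean_samples = 6,
                    L = 400, mislabel_rate = 0.1, unidentified_rate = 0.2,
                    short_rate = 0.1, short_len = 300, seed = 17)
  sim <- simulate_library(cfg)
  lab <- sim$alignment$labels
  err <- sim$truth$injected_errors
  # errors carry a wrong but well-formed species label
  expect_true(all(err$written_species != err$true_species))
  expect_equal(unname(lab$species[match(err$id, lab$id)]), err$written_species)
  # labels differ from truth exactly on the injected errors (among identified)
  ident <- lab$id[lab$identified]
  mismatch <- ident[lab$species[match(ident, lab$id)] !=
                    sim$truth$true_species[ident]]
  expect_setequal(mismatch, err$id)
  # degraded labels are genus-only and unidentified
  expect_true(all(!lab$identified[match(sim$truth$unidentified_ids, lab$id)]))
  # truncated records are under-length but still aligned
  expect_true(all(ungapped_lengths(sim$alignment)[sim$truth$short_ids] == 300L))
  expect_equal(unique(nchar(sim$alignment$seqs)), 400L)
})

test_that("pair divergence concentrates near twice the leaf branch length", {
  # two independent branches from the ancestor: expected pair divergence
  # ~ 2 * delta_intra; averaged over seeds the K2P mean should sit close
  means <- vapply(1:40, function(seed) {
    cfg <- sim_config(n_species = 10, sampling = "fixed", mean_samples = 10,
                      L = 667, delta_intra = 0.005, delta_inter = 0.05,
                      mislabel_rate = 0, unidentified_rate = 0, short_rate = 0,
                      seed = seed)
    sim <- simulate_library(cfg)
    dm <- suppressWarnings(distance_matrix(sim$alignment, "K2P"))
    su <- species_summaries(dm, sim$alignment$labels)
    mean(su$mean_intra, na.rm = TRUE)
  }, 1)
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.010), 3 * se + 0.0005)
})

test_that("observed divergence never exceeds the substitution budget on average", {
  # multiple hits only hide events, so mean p-distance <= 2 * delta_intra
  ps <- vapply(1:10, function(seed) {
    cfg <- sim_config(n_species = 6, sampling = "fixed", mean_samples = 6,
                      L = 500, delta_intra = 0.01, delta_inter = 0.12,
                      mislabel_rate = 0, unidentified_rate = 0, short_rate = 0,
                      seed = seed + 400)
    sim <- simulate_library(cfg)
    dm <- distance_matrix(sim$alignment, "p")
    su <- species_summaries(dm, sim$alignment$labels)
    mean(su$mean_intra, na.rm = TRUE)
  }, 1)
  expect_lt(mean(ps), 2 * 0.01)
})

test_that("the planted barcode gap survives simulation for nearly all species", {
  n_sp <- 0; n_gap <- 0
  for (seed in 1:20) {
    sim <- quick_sim(seed + 500)
    dm <- distance_matrix(sim$alignment, "K2P")
    su <- species_summaries(dm, sim$alignment$labels)
    multi <- su[su$n >= 2, ]
    n_sp <- n_sp + nrow(multi)
    n_gap <- n_gap + sum(multi$max_intra < multi$min_inter)
  }
  expect_gte(n_gap / n_sp, 0.95)
})

test_that("truth scorecard computes ARI, misid scores and congruence rates", {
  sim <- quick_sim(91, mislabel = 0.05)
  truth <- sim$truth
  perfect <- truth$true_partition
  singletons <- new_partition(setNames(seq_along(truth$true_species),
                                       names(truth$true_species)))
  rep <- truth_report(truth, partitions = list(perfect = perfect,
                                               atoms = singletons))
  expect_equal(unname(rep$ari["perfect"]), 1)
  expect_lt(rep$ari["atoms"], 1)

  flags <- data.frame(id = truth$injected_errors$id)
  rep2 <- truth_report(truth, flags = flags)
  expect_equal(rep2$misid_precision, 1)
  expect_equal(rep2$misid_recall, 1)
})
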