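test_that("sampled trees are binary, positive-length and seed-deterministic", {
  cfg <- sim_config(n_taxa = 3, n_queries = 0, n_groups = 1, seed = 7)
  tr <- sample_tree(cfg)
  expect_equal(length(tr$tip.label), 3)
  # the unique unrooted 3-leaf topology: one internal node after unrooting
  expect_equal(ape::unroot(tr)$Nnode, 1)

  expect_identical(ape::write.tree(sample_tree(cfg)),
                   ape::write.tree(sample_tree(cfg)))
  expect_error(sample_tree(structure(list(n_taxa = 2, seed = 1),
                                     class = "sim_config")), "n_taxa")
  expect_error(sim_config(n_taxa = 8, n_queries = 8), "n_queries")

  tr32 <- sample_tree(sim_config(n_taxa = 32, seed = 1))
  expect_true(all(tr32$edge.length > 0))
  for (key in bipartitions(tr32)) {
    side <- strsplit(key, ",", fixed = TRUE)[[1]]
    expect_equal(length(side) + length(setdiff(tr32$tip.label, side)), 32)
  }
})

test_that("zero rates give identical leaves and a gap-free true alignment", {
  cfg <- sim_config(n_taxa = 6, n_queries = 0, n_groups = 2,
                    depth_scale = 0, indel_rate = c(its1 = 0, r58s = 0,
                                                    its2 = 0),
                    seed = 5)
  sim <- evolve_its(sample_tree(cfg), cfg)
  expect_equal(length(unique(unname(sim$records))), 1)
  expect_false(any(grepl("-", sim$true_alignment, fixed = TRUE)))
  expect_equal(msa_ncol(sim$true_alignment), sum(cfg$region_lengths))
})

test_that("degapped true-alignment rows equal pre-artifact residues", {
  for (seed in c(2, 9, 31)) {
    cfg <- sim_config(n_taxa = 10, n_queries = 2, n_groups = 2, seed = seed)
    sim <- simulate_its(cfg)
    expect_identical(degap(sim$true_alignment), sim$pre_artifact_records)
    expect_equal(sort(names(sim$records)), sort(sim$artifact_table$id))
    expect_equal(anyDuplicated(sim$artifact_table$id), 0)
  }
})

test_that("simulation is byte-identical under one seed", {
  cfg <- sim_config(n_taxa = 8, n_queries = 2, n_groups = 2,
                    artifact_fractions = c(reverse_complement = 0.2,
                                           truncate = 0.1, short = 0.1),
                    seed = 13)
  a <- simulate_its(cfg)
  b <- simulate_its(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("5.8S block stays more conserved than the spacers", {
  ok <- 0
  n_rep <- 30
  for (seed in seq_len(n_rep)) {
    cfg <- sim_config(n_taxa = 8, n_queries = 0, n_groups = 2, seed = seed)
    sim <- simulate_its(cfg)
    idy <- region_identity(sim)
    if (idy[["5.8S"]] > idy[["ITS1"]] && idy[["5.8S"]] > idy[["ITS2"]]) {
      ok <- ok + 1
    }
  }
  expect_gte(ok, ceiling(0.95 * n_rep))
})

test_that("doubling the depth scale lowers whole-ITS similarity", {
  for (seed in c(1, 4)) {
    sims <- lapply(c(0.05, 0.10), function(ds) {
      cfg <- sim_config(n_taxa = 5, n_queries = 0, n_groups = 1,
                        depth_scale = ds, seed = seed)
      simulate_its(cfg)
    })
    mean_sim <- vapply(sims, function(s) {
      S <- similarity_matrix(s$records)
      mean(S[upper.tri(S)])
    }, numeric(1))
    expect_gt(mean_sim[1], mean_sim[2])
  }
})

test_that("artifact injection flags exactly the altered records", {
  cfg0 <- sim_config(n_taxa = 8, n_queries = 0, n_groups = 2, seed = 3)
  clean <- simulate_its(cfg0)
  expect_false(any(unlist(clean$artifact_table[, -1])))
  expect_identical(clean$records, clean$pre_artifact_records)

  # reverse-complement everything: involution restores the originals
  cfg_rc <- sim_config(n_taxa = 8, n_queries = 0, n_groups = 2,
                       artifact_fractions = c(reverse_complement = 1,
                                              truncate = 0, short = 0),
                       seed = 3)
  rc <- simulate_its(cfg_rc)
  expect_true(all(rc$artifact_table$reverse_complemented))
  expect_identical(revcomp(rc$records), rc$pre_artifact_records)

  # seeded sampling without replacement gives an exact count
  cfg_tr <- sim_config(n_taxa = 40, n_queries = 0, n_groups = 2,
                       artifact_fractions = c(reverse_complement = 0,
                                              truncate = 0.25, short = 0),
                       seed = 17)
  tr <- simulate_its(cfg_tr)
  expect_equal(sum(tr$artifact_table$truncated), 10)
  truncated <- tr$artifact_table$id[tr$artifact_table$truncated]
  for (id in truncated) {
    expect_false("ITS2" %in% region_rows(tr$region_maps, id)$region)
  }
})

test_that("simulation files round-trip through their text formats", {
  cfg <- sim_config(n_taxa = 6, n_queries = 1, n_groups = 2, seed = 11)
  sim <- simulate_its(cfg)
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  expect_identical(read_fasta(file.path(dir, "records.fasta")), sim$records)
  expect_identical(read_fasta(file.path(dir, "true_alignment.fasta")),
                   sim$true_alignment)
  expect_identical(read_regions(file.path(dir, "regions.tsv")),
                   sim$region_maps)
  tr <- ape::read.tree(file.path(dir, "true_tree.nwk"))
  expect_equal(rf_distance(tr, sim$tree)$count, 0)
})
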