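test_that("global similarity handles identity and total mismatch", {
  expect_equal(global_similarity("ACGTACGT", "ACGTACGT"), 1.0)
  expect_equal(global_similarity("AAAA", "TTTT"), 0.0)
  expect_error(global_similarity("", "ACGT"), "empty")
})

test_that("pairwise DP matches exhaustive alignment enumeration", {
  sc <- align_scoring(match = 1, mismatch = -1, gap_open = 2, gap_extend = 1)
  # fixture frozen from the brute-force enumerator: ACGT vs ACT has a unique
  # optimum AC-T with 3 matches over 4 columns
  oracle <- brute_best_alignment("ACGT", "ACT", 1, -1, 2, 1)
  expect_equal(oracle$similarities, 0.75)
  al <- pairwise_align("ACGT", "ACT", sc)
  expect_equal(al$score, oracle$score)
  expect_equal(global_similarity("ACGT", "ACT", sc), 0.75)

  set.seed(42)
  for (i in 1:12) {
    a <- random_dna(sample(3:6, 1))
    b <- random_dna(sample(3:6, 1))
    oracle <- brute_best_alignment(a, b)
    al <- pairwise_align(a, b)
    expect_equal(al$score, oracle$score, tolerance = 1e-9)
    expect_true(any(abs(global_similarity(a, b) -
                          oracle$similarities) < 1e-9))
  }
})

test_that("similarity agrees with an independent aligner on default scoring", {
  skip_if_not_installed("Biostrings")
  set.seed(7)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = TRUE)
  for (i in 1:10) {
    a <- random_dna(40); b <- random_dna(40)
    ours <- pairwise_align(a, b)
    ref <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                         gapOpening = 10, gapExtension = 0.5,
                                         type = "global")
    expect_equal(ours$score, Biostrings::score(ref), tolerance = 1e-9)
  }
})

test_that("global similarity is symmetric and reflexive", {
  set.seed(11)
  for (i in 1:200) {
    a <- random_dna(sample(10:30, 1))
    b <- random_dna(sample(10:30, 1))
    expect_equal(global_similarity(a, b), global_similarity(b, a))
  }
  for (len in c(5, 17, 60)) {
    a <- random_dna(len)
    expect_equal(global_similarity(a, a), 1.0)
  }
})

test_that("ambiguity codes only match as identical literals", {
  # N aligned to N is an identical pair; N aligned to A is not
  expect_equal(global_similarity("ACGNT", "ACGNT"), 1.0)
  expect_lt(global_similarity("ACGNT", "ACGAT"), 1.0)
})

test_that("orientation vote flips reverse-complemented records", {
  set.seed(3)
  refs <- setNames(replicate(3, random_dna(120)), c("r1", "r2", "r3"))
  rec <- c(q1 = refs[["r1"]], q2 = revcomp(refs[["r2"]]))
  out <- orient(rec, refs)
  expect_identical(out$records[["q1"]], refs[["r1"]])
  expect_identical(out$records[["q2"]], refs[["r2"]])
  expect_identical(out$flipped, "q2")
  # involution: orienting the corrected set changes nothing
  again <- orient(out$records, refs)
  expect_identical(again$records, out$records)
  expect_length(again$flipped, 0)
})

test_that("orientation is unresolved on a forced zero tie", {
  set.seed(4)
  refs <- setNames(replicate(2, random_dna(100)), c("r1", "r2"))
  rec <- c(q = "ACACACACACACACACACAC")   # shares no 8-mers with random pool
  out <- orient(rec, refs, k = 8)
  expect_identical(out$unresolved, "q")
  expect_identical(out$records[["q"]], rec[["q"]])
  expect_error(orient(rec, character(0)), "non-empty")
})

test_that("orientation never changes multiset content", {
  set.seed(5)
  refs <- setNames(replicate(3, random_dna(150)), paste0("r", 1:3))
  recs <- c(refs[1], x = revcomp(refs[[2]]), y = random_dna(90))
  out <- orient(recs, refs)
  for (id in names(recs)) {
    expect_true(out$records[[id]] == recs[[id]] ||
                  out$records[[id]] == revcomp(recs[[id]]))
  }
})

test_that("record filters apply length and ITS2 rules", {
  recs <- setNames(c(random_dna(250), random_dna(199), random_dna(200)),
                   c("a", "b", "c"))
  all_kept <- filter_records(recs, min_length = 0, require_its2 = FALSE)
  expect_setequal(all_kept$kept, names(recs))
  expect_equal(nrow(all_kept$excluded), 0)

  rep <- filter_records(recs, min_length = 200)
  expect_setequal(rep$kept, c("a", "c"))   # exactly min_length is kept
  expect_equal(rep$excluded$id, "b")
  expect_equal(rep$excluded$reason, "too_short")
  expect_setequal(c(rep$kept, rep$excluded$id), names(recs))
})

test_that("ITS2-lacking records from the simulator are excluded", {
  cfg <- sim_config(n_taxa = 10, n_queries = 0, n_groups = 2,
                    artifact_fractions = c(reverse_complement = 0,
                                           truncate = 0.3, short = 0),
                    seed = 21)
  sim <- simulate_its(cfg)
  truncated <- sim$artifact_table$id[sim$artifact_table$truncated]
  expect_length(truncated, 3)
  rep <- filter_records(sim$records, sim$region_maps, min_length = 0,
                        require_its2 = TRUE)
  expect_setequal(rep$excluded$id, truncated)
  expect_true(all(rep$excluded$reason == "missing_its2"))
})
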