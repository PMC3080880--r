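test_that("column classification matches hand enumeration", {
  # 4 rows x 4 columns; the columns are (A,A,A,A) constant, (A,A,A,G)
  # singleton, (A,A,G,G) informative, (A,-,-,G) two residues of two states
  # but not two each -> uninformative
  msa <- c(r1 = "AAAA", r2 = "AAA-", r3 = "AAG-", r4 = "AGGG")
  cc <- classify_columns(msa)
  expect_equal(cc$n_constant, 1)
  expect_equal(cc$n_pars_uninformative, 2)
  expect_equal(cc$n_pars_informative, 1)
  expect_equal(cc$n_other, 0)
  expect_equal(cc$n_total, 4)
})

test_that("identical rows are all constant; two rows are never informative", {
  msa <- setNames(rep("ACGTACGT", 5), paste0("s", 1:5))
  cc <- classify_columns(msa)
  expect_equal(cc$n_constant, cc$n_total)
  expect_equal(cc$pct_informative, 0)

  set.seed(12)
  two <- setNames(c(random_dna(50), random_dna(50)), c("a", "b"))
  expect_equal(classify_columns(two)$n_pars_informative, 0)
})

test_that("classification partitions and matches a brute recount", {
  set.seed(33)
  for (i in 1:50) {
    msa <- random_msa(sample(3:8, 1), sample(10:40, 1),
                      alphabet = c("A", "C", "G", "T", "N"))
    cc <- classify_columns(msa)
    expect_equal(cc$n_constant + cc$n_pars_uninformative +
                   cc$n_pars_informative + cc$n_other, cc$n_total)
    oracle <- brute_classify(msa)
    expect_equal(cc$n_constant, unname(oracle["constant"]))
    expect_equal(cc$n_pars_uninformative, unname(oracle["uninf"]))
    expect_equal(cc$n_pars_informative, unname(oracle["inf"]))
    expect_equal(cc$n_other, unname(oracle["other"]))
  }
})

test_that("informative percentages round half away from zero", {
  # the printed convention: 895/1296 -> 69, 879/1094 -> 80, 1039/1553 -> 67,
  # 1029/1544 -> 67
  pct <- function(k, n) {
    msa <- setNames(c(
      paste(c(rep("A", n - k), rep("A", k)), collapse = ""),
      paste(c(rep("A", n - k), rep("C", k)), collapse = ""),
      paste(c(rep("A", n - k), rep("A", k)), collapse = ""),
      paste(c(rep("A", n - k), rep("C", k)), collapse = "")),
      paste0("s", 1:4))
    classify_columns(msa)$pct_informative
  }
  expect_equal(pct(895, 1296), 69)
  expect_equal(pct(879, 1094), 80)
  expect_equal(pct(1039, 1553), 67)
  expect_equal(pct(1029, 1544), 67)
})

test_that("monophyly follows the unrooted bipartition convention", {
  tr <- ape::read.tree(text = "(((a,b),c),(d,(e,f)));")
  expect_true(monophyly(tr, c("a", "b"))$monophyletic)
  # complement of a monophyletic group is monophyletic too
  expect_true(monophyly(tr, c("c", "d", "e", "f"))$monophyletic)
  expect_true(monophyly(tr, "a")$monophyletic)      # singleton: leaf edge
  expect_false(monophyly(tr, c("a", "d"))$monophyletic)
  expect_error(monophyly(tr, c("a", "zzz")), "subset")

  # 6-leaf caterpillar, opposite ends: verified by full enumeration
  cat6 <- ape::read.tree(text = "(a,(b,(c,(d,(e,f)))));")
  expect_false(monophyly(cat6, c("a", "f"))$monophyletic)
  found <- any(vapply(bipartitions(cat6), function(k) {
    side <- strsplit(k, ",")[[1]]
    setequal(side, c("a", "f")) ||
      setequal(side, setdiff(cat6$tip.label, c("a", "f")))
  }, logical(1)))
  expect_false(found)
})

test_that("monophyly reports the defining edge's support", {
  sim <- simulate_its(sim_config(n_taxa = 8, n_queries = 0, n_groups = 2,
                                 seed = 5))
  res <- bootstrap_support(sim$true_alignment, 50, seed = 3)
  ntips <- res$tree$tip.label
  key <- bipartitions(res$tree)[1]
  grp <- strsplit(key, ",")[[1]]
  m <- monophyly(res$tree, grp)
  expect_true(m$monophyletic)
  expect_equal(m$support, res$table$support[res$table$bipartition == key])
})

test_that("RF distance matches enumeration and the reference implementation", {
  t1 <- ape::read.tree(text = "((a,b),(c,(d,e)));")
  expect_equal(rf_distance(t1, t1)$count, 0)

  # maximally conflicting 5-leaf binary trees: RF = 2(5-3) = 4
  t2 <- ape::read.tree(text = "((a,c),(b,(d,e)));")
  t3 <- ape::read.tree(text = "((a,d),(e,(b,c)));")
  expect_equal(length(union(bipartitions(t1), bipartitions(t3))), 4)
  expect_equal(rf_distance(t1, t3)$count, 4)
  expect_equal(rf_distance(t1, t3)$normalized, 1)

  set.seed(44)
  for (i in 1:10) {
    a <- ape::rtree(7); b <- ape::rtree(7)
    ours <- rf_distance(a, b)
    expect_equal(ours$count, rf_distance(b, a)$count)
    expect_equal(ours$count, as.integer(phangorn::RF.dist(a, b)))
  }
  expect_error(rf_distance(t1, ape::rtree(4)), "leaf set")
})

test_that("long-branch flagging uses a strict multiple of the median", {
  equal <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_length(long_branches(equal, factor = 1.5), 0)
  one_long <- ape::read.tree(text = "((a:1,b:10):1,(c:1,d:1):1);")
  expect_identical(long_branches(one_long, factor = 5), "b")
  # boundary: ratio exactly equal to the factor is excluded
  expect_length(long_branches(one_long, factor = 10), 0)
})

test_that("alignment accuracy is exact on matching alignments and row-order invariant", {
  truth <- c(a = "AC-GT", b = "ACAGT", c = "AC-GT")
  expect_equal(alignment_accuracy(truth, truth),
               list(sp_score = 1, column_score = 1))
  shuffled <- truth[c(2, 3, 1)]
  expect_equal(alignment_accuracy(shuffled, truth),
               list(sp_score = 1, column_score = 1))
  expect_error(alignment_accuracy(c(a = "ACGT", b = "ACGT", c = "ACGT"),
                                  truth), "degapped")
})

test_that("a single spurious gap shift is scored by pair enumeration", {
  truth <- c(a = "ACGTAC", b = "ACGTAC", c = "ACGTAC")
  est <- c(a = "ACGTAC-", b = "ACGTAC-", c = "-CGTACA")
  # degap identity: row c is a rotation; build est so degapped rows match
  est[["c"]] <- "A-CGTAC"
  # oracle by explicit pair counting: truth pairs are 6 columns x 3 pairs =
  # 18; row c's residues 2..6 sit one column right of rows a/b's residues
  # 2..6 in est, so pairs with c survive only where columns still coincide
  mt <- do.call(rbind, strsplit(unname(truth), ""))
  me <- do.call(rbind, strsplit(unname(est), ""))
  colof <- function(m, r) which(m[r, ] != "-")
  hits <- 0; total <- 0
  for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
    ct1 <- colof(mt, p[1]); ct2 <- colof(mt, p[2])
    ce1 <- colof(me, p[1]); ce2 <- colof(me, p[2])
    for (k in seq_len(ncol(mt))) {
      i1 <- match(k, ct1); i2 <- match(k, ct2)
      if (!is.na(i1) && !is.na(i2)) {
        total <- total + 1
        if (ce1[i1] == ce2[i2]) hits <- hits + 1
      }
    }
  }
  acc <- alignment_accuracy(est, truth)
  expect_equal(acc$sp_score, hits / total)
  expect_lt(acc$column_score, 1)
  expect_equal(acc$column_score, 1 / 6)
})
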