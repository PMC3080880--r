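test_that("k-mer distances are zero for identical, one for disjoint", {
  recs <- c(a = strrep("ACGT", 10), b = strrep("ACGT", 10),
            c = strrep("T", 40))
  D <- kmer_distance_matrix(recs, k = 4)
  expect_equal(D[["a", "b"]], 0)
  expect_equal(D[["a", "c"]], 1)
  expect_equal(diag(D), setNames(rep(0, 3), names(recs)))
})

test_that("k-mer distances are symmetric and in [0,1]", {
  set.seed(23)
  recs <- setNames(replicate(12, random_dna(sample(30:80, 1))),
                   paste0("s", 1:12))
  D <- kmer_distance_matrix(recs)
  expect_equal(D, t(D))
  expect_true(all(D >= 0 & D <= 1))
  short <- c(recs, tiny = "ACG")
  expect_warning(D2 <- kmer_distance_matrix(short), "shorter than")
  expect_true(all(D2["tiny", colnames(D2) != "tiny"] == 1))
})

test_that("identical sequences align gap-free under any guide", {
  recs <- setNames(rep(strrep("ACGTT", 8), 4), paste0("s", 1:4))
  guide <- ape::read.tree(text = "((s1,s3),(s2,s4));")
  msa <- progressive_align(recs, guide)
  expect_identical(unname(msa), unname(recs))
})

test_that("two-sequence progressive alignment reduces to the pairwise DP", {
  set.seed(31)
  for (i in 1:8) {
    a <- random_dna(25); b <- random_dna(30)
    guide <- ape::read.tree(text = "(x:1,y:1);")
    msa <- progressive_align(c(x = a, y = b), guide)
    pw <- pairwise_align(a, b)
    expect_identical(unname(msa), c(pw$a, pw$b))
  }
})

test_that("small three-sequence alignments match an independent merge oracle", {
  # oracle: a pure-R Gotoh on one-hot/frequency profiles, written separately
  # from the C++ path, folded over the same fixed guide
  r_gotoh <- function(P1, P2, S, go, ge) {
    n1 <- ncol(P1); n2 <- ncol(P2)
    sim <- t(P1) %*% S %*% P2
    M <- X <- Y <- matrix(-Inf, n1 + 1, n2 + 1)
    tM <- tX <- tY <- matrix(NA_integer_, n1 + 1, n2 + 1)
    M[1, 1] <- 0
    for (i in seq_len(n1)) { X[i + 1, 1] <- -(go + i * ge)
                             tX[i + 1, 1] <- if (i == 1) 1L else 2L }
    for (j in seq_len(n2)) { Y[1, j + 1] <- -(go + j * ge)
                             tY[1, j + 1] <- if (j == 1) 1L else 3L }
    for (i in seq_len(n1)) {
      for (j in seq_len(n2)) {
        cand <- c(M[i, j], X[i, j], Y[i, j])
        w <- which.max(cand)   # ties: M > X > Y as which.max takes first
        M[i + 1, j + 1] <- cand[w] + sim[i, j]; tM[i + 1, j + 1] <- w
        cand <- c(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                  Y[i, j + 1] - go - ge)
        w <- which.max(cand)
        X[i + 1, j + 1] <- cand[w]; tX[i + 1, j + 1] <- w
        cand <- c(M[i + 1, j] - go - ge, X[i + 1, j] - go - ge,
                  Y[i + 1, j] - ge)
        w <- which.max(cand)
        Y[i + 1, j + 1] <- cand[w]; tY[i + 1, j + 1] <- w
      }
    }
    cand <- c(M[n1 + 1, n2 + 1], X[n1 + 1, n2 + 1], Y[n1 + 1, n2 + 1])
    state <- which.max(cand)
    i <- n1; j <- n2; path <- integer(0)
    while (i > 0 || j > 0) {
      if (state == 1) { path <- c(1L, path); state <- tM[i + 1, j + 1]
                        i <- i - 1; j <- j - 1 }
      else if (state == 2) { path <- c(2L, path); state <- tX[i + 1, j + 1]
                             i <- i - 1 }
      else { path <- c(3L, path); state <- tY[i + 1, j + 1]; j <- j - 1 }
    }
    path
  }
  apply_path <- function(m1, m2, path) {
    out <- matrix("-", nrow(m1) + nrow(m2), length(path))
    i <- 0; j <- 0
    for (s in seq_along(path)) {
      if (path[s] != 3) { i <- i + 1; out[seq_len(nrow(m1)), s] <- m1[, i] }
      if (path[s] != 2) { j <- j + 1
                          out[nrow(m1) + seq_len(nrow(m2)), s] <- m2[, j] }
    }
    rownames(out) <- c(rownames(m1), rownames(m2))
    out
  }
  oracle_align3 <- function(seqs, sc) {
    ab <- c("A", "C", "G", "T")
    S <- matrix(sc$mismatch, 4, 4, dimnames = list(ab, ab))
    diag(S) <- sc$match
    prof <- function(m) {
      P <- matrix(0, 4, ncol(m), dimnames = list(ab, NULL))
      for (a in seq_len(4)) P[a, ] <- colSums(m == ab[a]) / nrow(m)
      P
    }
    mats <- lapply(seqs, function(s) {
      m <- matrix(strsplit(s, "")[[1]], nrow = 1)
      m
    })
    for (i in seq_along(mats)) rownames(mats[[i]]) <- names(seqs)[i]
    # guide ((1,2),3)
    p12 <- r_gotoh(prof(mats[[1]]), prof(mats[[2]]), S, sc$gap_open,
                   sc$gap_extend)
    m12 <- apply_path(mats[[1]], mats[[2]], p12)
    p123 <- r_gotoh(prof(m12), prof(mats[[3]]), S, sc$gap_open,
                    sc$gap_extend)
    m <- apply_path(m12, mats[[3]], p123)
    setNames(apply(m, 1, paste, collapse = ""), rownames(m))
  }

  sc <- align_scoring()
  guide <- ape::read.tree(text = "((s1:1,s2:1):1,s3:1);")
  fix <- c(s1 = "ACGT", s2 = "AGT", s3 = "ACT")
  expect_identical(progressive_align(fix, guide, sc)[names(fix)],
                   oracle_align3(fix, sc)[names(fix)])
  set.seed(41)
  for (i in 1:6) {
    seqs <- setNames(c(random_dna(12), random_dna(10), random_dna(14)),
                     c("s1", "s2", "s3"))
    expect_identical(progressive_align(seqs, guide, sc)[names(seqs)],
                     oracle_align3(seqs, sc)[names(seqs)])
  }
})

test_that("every emitted alignment degaps to its input", {
  set.seed(9)
  recs <- setNames(replicate(6, random_dna(sample(40:60, 1))),
                   paste0("s", 1:6))
  guide <- nj_tree(kmer_distance_matrix(recs))
  msa <- progressive_align(recs, guide)
  expect_identical(degap(msa), recs)
  expect_error(progressive_align(recs[-1], guide), "match")
})
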