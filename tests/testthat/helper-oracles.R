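# Independent brute-force oracles used to freeze expected values.
# These deliberately share no code with the package implementation.

# enumerate every global alignment of two short strings (monotone paths)
brute_alignments <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(x, y) {
    if (!length(x) && !length(y)) return(list(list(x = character(0),
                                                   y = character(0))))
    out <- list()
    if (length(x) && length(y)) {
      for (r in rec(x[-1], y[-1])) {
        out <- c(out, list(list(x = c(x[1], r$x), y = c(y[1], r$y))))
      }
    }
    if (length(x)) {
      for (r in rec(x[-1], y)) {
        out <- c(out, list(list(x = c(x[1], r$x), y = c("-", r$y))))
      }
    }
    if (length(y)) {
      for (r in rec(x, y[-1])) {
        out <- c(out, list(list(x = c("-", r$x), y = c(y[1], r$y))))
      }
    }
    out
  }
  rec(ca, cb)
}

# score one gapped pair: column scores minus (open + len * extend) per
# maximal gap run in either row; end gaps count
brute_pair_score <- function(x, y, match, mismatch, open, extend) {
  resid <- x != "-" & y != "-"
  s <- sum(ifelse(x[resid] == y[resid], match, mismatch))
  gap_runs <- function(v) {
    r <- rle(v == "-")
    r$lengths[r$values]
  }
  runs <- c(gap_runs(x), gap_runs(y))
  s - sum(open + runs * extend)
}

# best score over all alignments + the set of similarities attained by the
# optimal ones (similarity = identical residue pairs / alignment length)
brute_best_alignment <- function(a, b, match = 5, mismatch = -4,
                                 open = 10, extend = 0.5) {
  alns <- brute_alignments(a, b)
  scores <- vapply(alns, function(al)
    brute_pair_score(al$x, al$y, match, mismatch, open, extend), numeric(1))
  best <- max(scores)
  opt <- alns[abs(scores - best) < 1e-9]
  sims <- vapply(opt, function(al)
    sum(al$x == al$y & al$x != "-") / length(al$x), numeric(1))
  list(score = best, similarities = unique(round(sims, 12)))
}

# Jukes-Cantor likelihood by explicit summation over all internal-node
# state assignments (any small tree)
brute_loglik_jc <- function(msa, tree) {
  codes <- matrix(match(do.call(rbind, strsplit(msa, "")),
                        c("A", "C", "G", "T")),
                  nrow = length(msa))
  rownames(codes) <- names(msa)
  codes <- codes[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  pmat <- function(t) {
    e <- exp(-4 * t / 3)
    m <- matrix(0.25 - 0.25 * e, 4, 4); diag(m) <- 0.25 + 0.75 * e
    m
  }
  Ps <- lapply(tree$edge.length, pmat)
  grid <- as.matrix(expand.grid(rep(list(1:4), nint)))
  total <- 0
  for (col in seq_len(ncol(codes))) {
    obs <- codes[, col]
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      st <- grid[g, ]
      state_of <- function(node) if (node <= ntip) obs[node] else
        st[node - ntip]
      p <- 0.25
      ok <- TRUE
      for (e in seq_len(nrow(tree$edge))) {
        sp <- state_of(tree$edge[e, 1])
        sc <- state_of(tree$edge[e, 2])
        if (is.na(sc)) next      # missing leaf marginalises to 1
        p <- p * Ps[[e]][sp, sc]
      }
      if (ok) lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

# least-squares fit of a 4-taxon distance matrix to each of the three
# unrooted topologies; returns the winning split as a sorted pair
brute_nj4 <- function(D) {
  taxa <- rownames(D)
  stopifnot(length(taxa) == 4)
  pairs <- t(combn(4, 2))
  d <- D[pairs]
  splits <- list(c(1, 2), c(1, 3), c(1, 4))   # partner of taxon 1
  rss <- vapply(splits, function(sp) {
    # branches: 4 terminal + 1 internal; path indicator per pair
    A <- matrix(0, 6, 5)
    for (r in seq_len(6)) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      A[r, i] <- 1; A[r, j] <- 1
      same <- (all(c(i, j) %in% sp)) || (!any(c(i, j) %in% sp))
      if (!same) A[r, 5] <- 1
    }
    fit <- lm.fit(A, d)
    sum(fit$residuals^2)
  }, numeric(1))
  sp <- splits[[which.min(rss)]]
  sort(taxa[sp])
}

# independent per-column recount of parsimony classes
brute_classify <- function(msa) {
  rows <- strsplit(unname(msa), "")
  ncolumns <- length(rows[[1]])
  counts <- c(constant = 0, uninf = 0, inf = 0, other = 0)
  for (j in seq_len(ncolumns)) {
    col <- vapply(rows, `[[`, character(1), j)
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) < 2) {
      counts["other"] <- counts["other"] + 1
    } else {
      k <- c(sum(col == "A"), sum(col == "C"), sum(col == "G"),
             sum(col == "T"))
      k <- k[k > 0]
      if (length(k) == 1) counts["constant"] <- counts["constant"] + 1
      else if (sum(k >= 2) >= 2) counts["inf"] <- counts["inf"] + 1
      else counts["uninf"] <- counts["uninf"] + 1
    }
  }
  counts
}

# random alignment-shaped character data for property tests
random_msa <- function(n, width, gap_frac = 0.2,
                       alphabet = c("A", "C", "G", "T")) {
  rows <- replicate(n, {
    ch <- sample(alphabet, width, replace = TRUE)
    gaps <- runif(width) < gap_frac
    # never produce an all-gap row
    if (all(gaps)) gaps[sample.int(width, 1)] <- FALSE
    ch[gaps] <- "-"
    paste(ch, collapse = "")
  })
  setNames(rows, sprintf("s%03d", seq_len(n)))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
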