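#' Alignment scoring scheme
#'
#' Identity-matrix scoring with affine gap penalties, defaulting to the
#' EMBOSS values for DNA (match 5, mismatch -4, gap open 10, gap extend 0.5).
#' A gap run of length L costs `gap_open + L * gap_extend`; end gaps are
#' penalised (true end-to-end alignment). Ambiguity codes score as a match
#' only against the identical literal character.
#'
#' @param match,mismatch scores for identical / differing residues.
#' @param gap_open,gap_extend positive gap penalties.
#' @return a list of class `align_scoring`.
#' @export
align_scoring <- function(match = 5, mismatch = -4,
                          gap_open = 10, gap_extend = 0.5) {
  if (gap_open < 0 || gap_extend < 0) {
    stop("gap penalties must be non-negative", call. = FALSE)
  }
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

# substitution score matrix over an explicit alphabet
score_matrix <- function(alphabet, scoring) {
  S <- matrix(scoring$mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(S) <- scoring$match
  S
}

# per-column residue frequency profile of a character matrix (rows =
# sequences); gaps contribute nothing ("gap as absence")
profile_of <- function(mat, alphabet) {
  n <- nrow(mat)
  P <- matrix(0, length(alphabet), ncol(mat), dimnames = list(alphabet, NULL))
  for (a in seq_along(alphabet)) {
    P[a, ] <- colSums(mat == alphabet[a]) / n
  }
  P
}

# Gotoh alignment of two sub-alignments given as character matrices.
# Returns list(mat = merged character matrix, score).
merge_alignments <- function(m1, m2, alphabet, S, scoring) {
  P1 <- profile_of(m1, alphabet)
  P2 <- profile_of(m2, alphabet)
  sim <- crossprod(P1, S %*% P2)
  res <- .gotoh_align(sim, scoring$gap_open, scoring$gap_extend)
  path <- res$path
  n1 <- nrow(m1); n2 <- nrow(m2)
  out <- matrix("-", n1 + n2, length(path))
  i <- 0L; j <- 0L
  for (s in seq_along(path)) {
    mv <- path[s]
    if (mv == 1L) {
      i <- i + 1L; j <- j + 1L
      out[seq_len(n1), s] <- m1[, i]
      out[n1 + seq_len(n2), s] <- m2[, j]
    } else if (mv == 2L) {
      i <- i + 1L
      out[seq_len(n1), s] <- m1[, i]
    } else {
      j <- j + 1L
      out[n1 + seq_len(n2), s] <- m2[, j]
    }
  }
  rownames(out) <- c(rownames(m1), rownames(m2))
  list(mat = out, score = res$score)
}

#' Optimal global pairwise alignment
#'
#' End-to-end Needleman–Wunsch/Gotoh alignment with affine gap penalties and
#' deterministic tie-breaking (diagonal over up over left), the same dynamic
#' programme used for profile merging during progressive alignment.
#'
#' @param a,b unaligned DNA strings.
#' @param scoring an [align_scoring()] scheme.
#' @return list with elements `a`, `b` (the two gapped strings) and `score`.
#' @export
pairwise_align <- function(a, b, scoring = align_scoring()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  m1 <- matrix(strsplit(a, "", fixed = TRUE)[[1L]], nrow = 1L)
  m2 <- matrix(strsplit(b, "", fixed = TRUE)[[1L]], nrow = 1L)
  alphabet <- sort(unique(c(m1[1L, ], m2[1L, ])))
  S <- score_matrix(alphabet, scoring)
  res <- merge_alignments(m1, m2, alphabet, S, scoring)
  list(a = paste(res$mat[1L, ], collapse = ""),
       b = paste(res$mat[2L, ], collapse = ""),
       score = res$score)
}

#' Progressive multiple alignment along a guide tree
#'
#' Aligns sequences pairwise and then profile–profile following the guide
#' tree topology bottom-up ("once a gap, always a gap"). Profiles are
#' per-column residue frequency vectors; gaps are treated as absence during
#' profile scoring; gap penalties are the scheme's constants.
#'
#' @param records named character vector of unaligned sequences.
#' @param guide an `ape::phylo` guide tree whose tip labels equal
#'   `names(records)`.
#' @param scoring an [align_scoring()] scheme.
#' @return a named character vector alignment (rows in `records` order).
#' @export
progressive_align <- function(records, guide, scoring = align_scoring()) {
  check_ids(records)
  if (!setequal(guide$tip.label, names(records))) {
    stop("guide tree leaves must match record ids", call. = FALSE)
  }
  if (length(records) == 1L) return(records)
  alphabet <- sort(unique(unlist(strsplit(unname(records), "", fixed = TRUE))))
  alphabet <- setdiff(alphabet, "-")
  S <- score_matrix(alphabet, scoring)

  tr <- ape::reorder.phylo(guide, "postorder")
  ntip <- length(tr$tip.label)
  nodes <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) {
    ch <- strsplit(records[[tr$tip.label[i]]], "", fixed = TRUE)[[1L]]
    m <- matrix(ch, nrow = 1L)
    rownames(m) <- tr$tip.label[i]
    nodes[[i]] <- m
  }
  # postorder edges: children appear before parents
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]
    child <- tr$edge[e, 2L]
    if (is.null(nodes[[parent]])) {
      nodes[[parent]] <- nodes[[child]]
    } else {
      nodes[[parent]] <- merge_alignments(nodes[[parent]], nodes[[child]],
                                          alphabet, S, scoring)$mat
    }
    nodes[[child]] <- NA  # free
  }
  root <- ntip + 1L
  out <- collapse_rows(nodes[[root]])
  out <- out[names(records)]
  as_msa(out)
  out
}

#' Pairwise k-mer distance matrix
#'
#' Distance between two sequences is `1 - shared / min(total)`, where
#' `shared` is the multiset intersection size of their k-mer counts and
#' `total` is each sequence's k-mer count. Used to seed guide trees.
#'
#' @param records named character vector of unaligned sequences.
#' @param k word size.
#' @return symmetric numeric matrix with zero diagonal, values in \[0, 1\].
#' @export
kmer_distance_matrix <- function(records, k = 6L) {
  check_ids(records)
  if (length(records) < 3L) stop("need at least 3 records", call. = FALSE)
  tabs <- lapply(records, function(s) {
    n <- nchar(s)
    if (n < k) return(NULL)
    table(substring(s, 1:(n - k + 1L), k:n))
  })
  short <- vapply(tabs, is.null, logical(1))
  if (any(short)) {
    warning(sprintf("%d sequence(s) shorter than k = %d; distance set to 1",
                    sum(short), k))
  }
  n <- length(records)
  D <- matrix(0, n, n, dimnames = list(names(records), names(records)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (short[i] || short[j]) {
        d <- 1
      } else {
        common <- intersect(names(tabs[[i]]), names(tabs[[j]]))
        shared <- if (length(common)) {
          sum(pmin(tabs[[i]][common], tabs[[j]][common]))
        } else 0
        d <- 1 - shared / min(sum(tabs[[i]]), sum(tabs[[j]]))
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}
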