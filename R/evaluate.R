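#' Classify alignment columns for parsimony
#'
#' Per column, over non-gap unambiguous residues only (gaps and ambiguity
#' codes are missing data): *constant* = exactly one state, present in at
#' least two sequences; *parsimony-informative* = at least two states each
#' present in at least two sequences; *parsimony-uninformative* = variable
#' but not informative; *other* = fewer than two scorable residues.
#'
#' @param msa named character vector alignment.
#' @return list of class `column_classes`: `n_total`, `n_constant`,
#'   `n_pars_uninformative`, `n_pars_informative`, `n_other`, and
#'   `pct_informative` (percentage of informative columns, rounded half away
#'   from zero to the nearest integer, as conventionally printed).
#' @export
classify_columns <- function(msa) {
  as_msa(msa)
  m <- seq_matrix(msa)
  n_total <- ncol(m)
  cls <- integer(4)  # constant, uninformative, informative, other
  for (j in seq_len(n_total)) {
    col <- m[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) < 2L) {
      cls[4] <- cls[4] + 1L
    } else {
      tab <- table(col)
      if (length(tab) == 1L) {
        cls[1] <- cls[1] + 1L
      } else if (sum(tab >= 2L) >= 2L) {
        cls[3] <- cls[3] + 1L
      } else {
        cls[2] <- cls[2] + 1L
      }
    }
  }
  structure(list(n_total = n_total,
                 n_constant = cls[1],
                 n_pars_uninformative = cls[2],
                 n_pars_informative = cls[3],
                 n_other = cls[4],
                 pct_informative =
                   as.integer(round_half_up(100 * cls[3] / n_total))),
            class = "column_classes")
}

#' Test a group for monophyly
#'
#' True iff some edge's bipartition has one side exactly equal to the group
#' (unrooted convention, so the complement of a monophyletic group is also
#' monophyletic). Returns that edge's support when the tree carries support
#' labels.
#'
#' @param tree an `ape::phylo`, optionally with support node labels.
#' @param group character vector of leaf ids, a proper non-empty subset of
#'   the leaves.
#' @return list with `monophyletic` (logical) and `support` (numeric or NA).
#' @export
monophyly <- function(tree, group) {
  tips <- tree$tip.label
  if (!length(group) || !all(group %in% tips) || length(group) >= length(tips)) {
    stop("group must be a proper non-empty subset of the leaves",
         call. = FALSE)
  }
  if (length(group) == 1L || length(group) == length(tips) - 1L) {
    return(list(monophyletic = TRUE, support = NA_real_))  # trivial edge
  }
  key <- bipart_key(group, tips)
  ntip <- length(tips)
  clades <- node_clades(tree)
  labels <- tree$node.label
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    cl <- clades[[node]]
    if (length(cl) <= 1L || length(cl) >= ntip - 1L) next
    if (bipart_key(cl, tips) == key) {
      s <- NA_real_
      if (!is.null(labels) && nzchar(labels[node - ntip])) {
        s <- suppressWarnings(as.numeric(labels[node - ntip]))
      }
      return(list(monophyletic = TRUE, support = s))
    }
  }
  list(monophyletic = FALSE, support = NA_real_)
}

#' Robinson–Foulds distance
#'
#' Symmetric-difference count of internal bipartitions, plus the value
#' normalised by `2 (n - 3)`, the maximum for two binary trees.
#'
#' @param t1,t2 `ape::phylo` trees on the same leaf set.
#' @return list with `count` and `normalized`.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees must share one leaf set", call. = FALSE)
  }
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  count <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  n <- length(t1$tip.label)
  denom <- 2 * (n - 3)
  list(count = count,
       normalized = if (denom > 0) count / denom else 0)
}

#' Leaves on extremely long terminal branches
#'
#' Flags leaves whose terminal branch length is strictly greater than
#' `factor` times the median terminal branch length.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param factor multiple of the median (default 5).
#' @return character vector of leaf ids.
#' @export
long_branches <- function(tree, factor = 5) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  ntip <- length(tree$tip.label)
  term <- tree$edge[, 2L] <= ntip
  len <- tree$edge.length[term]
  tip <- tree$tip.label[tree$edge[term, 2L]]
  tip[len > factor * median(len)]
}

#' Alignment accuracy against a known true alignment
#'
#' `sp_score` is the fraction of the truth's homologous residue pairs that
#' the estimated alignment reproduces; `column_score` is the fraction of
#' truth columns reproduced exactly (same residues and same gap pattern).
#'
#' @param estimated,truth alignments over the same ids whose degapped rows
#'   are identical.
#' @return list with `sp_score` and `column_score`, both in \[0, 1\].
#' @export
alignment_accuracy <- function(estimated, truth) {
  as_msa(estimated); as_msa(truth)
  if (!setequal(names(estimated), names(truth))) {
    stop("alignments must share ids", call. = FALSE)
  }
  estimated <- estimated[names(truth)]
  if (!identical(degap(estimated), degap(truth))) {
    stop("degapped rows differ between estimated and truth", call. = FALSE)
  }
  mt <- seq_matrix(truth)
  me <- seq_matrix(estimated)
  n <- nrow(mt)
  # column index of each residue of each row, in each alignment
  res_cols <- function(m) apply(m != "-", 1L, which, simplify = FALSE)
  ct <- res_cols(mt); ce <- res_cols(me)
  # residue ordinal at each truth column (0 = gap)
  ord_t <- matrix(0L, n, ncol(mt))
  for (i in seq_len(n)) ord_t[i, ct[[i]]] <- seq_along(ct[[i]])

  pairs_total <- 0L
  pairs_hit <- 0L
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      both <- ord_t[a, ] > 0L & ord_t[b, ] > 0L
      ia <- ord_t[a, both]; ib <- ord_t[b, both]
      pairs_total <- pairs_total + length(ia)
      pairs_hit <- pairs_hit + sum(ce[[a]][ia] == ce[[b]][ib])
    }
  }
  # exact column reproduction: compare per-column residue-ordinal signatures
  ord_e <- matrix(0L, n, ncol(me))
  for (i in seq_len(n)) ord_e[i, ce[[i]]] <- seq_along(ce[[i]])
  key_t <- apply(ord_t, 2L, paste, collapse = ",")
  key_e <- apply(ord_e, 2L, paste, collapse = ",")
  list(sp_score = if (pairs_total > 0) pairs_hit / pairs_total else 1,
       column_score = mean(key_t %in% key_e))
}

#' Tree and alignment quality metrics for one strategy
#'
#' Bundles the evaluation the pipeline reports per strategy: reference-group
#' monophyly, fraction of supported branches, long-branch leaves, and (when
#' a simulated truth is available) Robinson–Foulds distance to the true tree
#' and accuracy against the true alignment.
#'
#' @param tree tree with bootstrap support labels.
#' @param msa the strategy's alignment.
#' @param groups named character vector of reference labels (ids -> group).
#' @param threshold support threshold for `supported_fraction`.
#' @param truth_tree,truth_alignment optional simulated truth.
#' @param long_branch_factor multiple of the median terminal branch length.
#' @return list of class `tree_metrics`.
#' @export
tree_metrics <- function(tree, msa, groups = NULL, threshold = 0.94,
                         truth_tree = NULL, truth_alignment = NULL,
                         long_branch_factor = 5) {
  mono <- NULL
  if (!is.null(groups)) {
    groups <- groups[names(groups) %in% tree$tip.label]
    mono <- lapply(split(names(groups), unname(groups)), function(ids) {
      if (length(ids) >= length(tree$tip.label)) return(NULL)
      monophyly(tree, ids)
    })
  }
  rf <- NULL
  if (!is.null(truth_tree)) {
    tt <- truth_tree
    extra <- setdiff(tt$tip.label, tree$tip.label)
    if (length(extra)) tt <- ape::drop.tip(tt, extra)
    rf <- rf_distance(tree, tt)
  }
  acc <- NULL
  if (!is.null(truth_alignment) &&
      setequal(names(truth_alignment), names(msa)) &&
      identical(degap(msa[names(truth_alignment)]), degap(truth_alignment))) {
    acc <- alignment_accuracy(msa, truth_alignment)
  }
  structure(list(monophyly = mono,
                 supported_fraction = supported_fraction(tree, threshold),
                 long_branch_ids = long_branches(tree, long_branch_factor),
                 rf = rf, accuracy = acc),
            class = "tree_metrics")
}
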