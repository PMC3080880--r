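# tips under each node: list indexed by node number (tips map to themselves)
node_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  out <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) out[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]
    child <- tr$edge[e, 2L]
    out[[parent]] <- c(out[[parent]], out[[child]])
  }
  out
}

# canonical key of the bipartition separating `side` from the rest: the side
# not containing the overall smallest leaf id, sorted and comma-joined
bipart_key <- function(side, all_tips) {
  if (min(all_tips) %in% side) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = ",")
}

#' Internal bipartitions of a tree
#'
#' One canonical key per internal edge (trivial single-leaf splits are
#' dropped; duplicate splits arising from rooting are merged).
#'
#' @param tree an `ape::phylo`.
#' @return character vector of canonical bipartition keys.
#' @export
bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  clades <- node_clades(tree)
  keys <- character(0)
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    cl <- clades[[node]]
    if (length(cl) <= 1L || length(cl) >= ntip - 1L) next
    keys <- c(keys, bipart_key(cl, tree$tip.label))
  }
  unique(keys)
}

#' Bootstrap bipartition support
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate (Jukes–Cantor distances + neighbor-joining) and assigns each
#' internal edge of the point-estimate tree the frequency of its bipartition
#' among the replicates. This bootstrap frequency fills the tree's support
#' slot; every downstream decision rule (the 0.94 significance threshold,
#' clade assignment) is estimator-agnostic.
#'
#' @param msa named character vector alignment (>= 4 rows for any internal
#'   edge to exist).
#' @param n_replicates number of bootstrap replicates.
#' @param seed integer seed.
#' @param d_max saturation cap for Jukes–Cantor distances.
#' @return list of class `support_result`: `tree` (point-estimate tree with
#'   support as internal node labels), `table` (data.frame bipartition /
#'   support), `n_replicates`.
#' @export
bootstrap_support <- function(msa, n_replicates = 100L, seed = 1L,
                              d_max = 5) {
  as_msa(msa)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  point <- nj_tree(jc_distance(msa, d_max))
  ntip <- length(point$tip.label)
  if (ntip < 4L) {
    warning("fewer than 4 taxa: no internal edges to support")
    return(structure(list(tree = point,
                          table = data.frame(bipartition = character(0),
                                             support = numeric(0)),
                          n_replicates = n_replicates),
                     class = "support_result"))
  }
  codes <- encode_msa(msa)
  ids <- names(msa)
  counts <- new.env(parent = emptyenv())
  set.seed(seed)
  for (b in seq_len(n_replicates)) {
    idx <- sample.int(ncol(codes), replace = TRUE)
    pd <- .pairwise_pdist(codes[, idx, drop = FALSE])
    d <- matrix(d_max, nrow(pd$p), ncol(pd$p))
    ok <- !is.na(pd$p) & pd$p < 0.75
    d[ok] <- -0.75 * log(1 - 4 * pd$p[ok] / 3)
    diag(d) <- 0
    dimnames(d) <- list(ids, ids)
    for (key in bipartitions(nj_tree(d))) {
      counts[[key]] <- (get0(key, envir = counts, ifnotfound = 0)) + 1L
    }
  }
  keys <- ls(counts)
  table <- data.frame(
    bipartition = keys,
    support = vapply(keys, function(k) counts[[k]] / n_replicates,
                     numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  clades <- node_clades(point)
  labels <- character(point$Nnode)
  for (node in (ntip + 1L):(ntip + point$Nnode)) {
    cl <- clades[[node]]
    if (length(cl) <= 1L || length(cl) >= ntip - 1L) next
    key <- bipart_key(cl, point$tip.label)
    f <- get0(key, envir = counts, ifnotfound = 0) / n_replicates
    labels[node - ntip] <- sprintf("%.6g", f)
  }
  point$node.label <- labels
  structure(list(tree = point, table = table, n_replicates = n_replicates),
            class = "support_result")
}

#' Majority-rule consensus tree
#'
#' Contains exactly the bipartitions whose frequency across the input trees
#' exceeds `threshold` (strict); with the default 0.5 these are pairwise
#' compatible by the majority-rule theorem. Polytomies are allowed; internal
#' node labels carry the bipartition frequencies.
#'
#' @param trees a list of `ape::phylo` trees on the same leaf set (or an
#'   `ape::multiPhylo`).
#' @param threshold inclusion threshold (frequency must be strictly higher).
#' @return an `ape::phylo` consensus tree (no branch lengths).
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 1L) stop("need at least one tree", call. = FALSE)
  tips <- sort(trees[[1L]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), tips)) {
      stop("all trees must share one leaf set", call. = FALSE)
    }
  }
  n <- length(trees)
  freq <- table(unlist(lapply(trees, bipartitions))) / n
  keep <- names(freq)[freq > threshold]
  m <- tips[1L]   # keys are clades relative to the smallest leaf
  clades <- lapply(keep, function(k) strsplit(k, ",", fixed = TRUE)[[1L]])
  supp <- as.numeric(freq[keep])
  ord <- order(vapply(clades, length, integer(1)), decreasing = TRUE)
  clades <- clades[ord]; supp <- supp[ord]

  # parent of each clade: the smallest strict superset (root if none)
  k <- length(clades)
  parent <- rep(0L, k)
  for (i in seq_len(k)) {
    for (j in rev(seq_len(k))) {   # candidates sorted big -> small
      if (j == i) next
      if (length(clades[[j]]) > length(clades[[i]]) &&
          all(clades[[i]] %in% clades[[j]])) {
        parent[i] <- j
        break
      }
    }
  }
  leaf_home <- setNames(rep(0L, length(tips)), tips)
  for (tip in setdiff(tips, m)) {
    holders <- which(vapply(clades, function(cl) tip %in% cl, logical(1)))
    if (length(holders)) {
      leaf_home[tip] <- holders[which.min(vapply(clades[holders], length,
                                                 integer(1)))]
    }
  }
  build <- function(i) {
    sub <- which(parent == i)
    here <- if (i == 0L) setdiff(tips[leaf_home == 0L], m) else
      clades[[i]][leaf_home[clades[[i]]] == i]
    parts <- c(sort(here), vapply(sub, build, character(1)))
    lab <- if (i == 0L) "" else sprintf("%.6g", supp[i])
    sprintf("(%s)%s", paste(parts, collapse = ","), lab)
  }
  nwk <- sprintf("(%s,%s);", m,
                 paste(c(sort(setdiff(tips[leaf_home == 0L], m)),
                         vapply(which(parent == 0L), build, character(1))),
                       collapse = ","))
  ape::read.tree(text = nwk)
}

#' Fraction of supported internal edges
#'
#' @param tree a tree whose internal node labels are numeric support values
#'   (e.g. from [bootstrap_support()]).
#' @param threshold significance threshold (support must be strictly
#'   higher); 0.94 follows the convention that posterior probabilities
#'   above 0.94 mark significantly supported branches.
#' @return proportion of internal edges with support > threshold (NaN if
#'   there are none).
#' @export
supported_fraction <- function(tree, threshold = 0.94) {
  s <- suppressWarnings(as.numeric(tree$node.label))
  s <- s[!is.na(s)]
  if (!length(s)) return(NaN)
  mean(s > threshold)
}
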