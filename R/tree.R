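#' Neighbor-joining tree with deterministic tie-breaking
#'
#' Standard neighbor-joining. When two pairs tie on the Q criterion, the pair
#' whose (lexicographically sorted) cluster labels are smallest is joined —
#' a cluster's label is the smallest leaf id it contains — so degenerate
#' matrices resolve to one documented topology. Negative branch lengths are
#' clamped to zero.
#'
#' @param D symmetric distance matrix with taxon ids as dimnames.
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("D must be a square matrix", call. = FALSE)
  }
  if (is.null(rownames(D))) stop("D must carry taxon ids", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) {
    stop("D must be symmetric", call. = FALSE)
  }
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)

  labels <- rownames(D)            # tie-break label: min leaf id in cluster
  frags <- rownames(D)             # newick fragment per active cluster
  fmt <- function(x) sprintf("%.10g", max(0, x))

  while (n > 3L) {
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key_a <- pmin(labels[cand[, 1L]], labels[cand[, 2L]])
    key_b <- pmax(labels[cand[, 1L]], labels[cand[, 2L]])
    pick <- order(key_a, key_b)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]

    vi <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    frag <- sprintf("(%s:%s,%s:%s)", frags[i], fmt(vi), frags[j], fmt(vj))
    lab <- min(labels[i], labels[j])

    keep <- setdiff(seq_len(n), c(i, j))
    newd <- 0.5 * (D[i, keep] + D[j, keep] - D[i, j])
    D <- D[keep, keep, drop = FALSE]
    D <- rbind(cbind(D, newd), c(newd, 0))
    labels <- c(labels[keep], lab)
    frags <- c(frags[keep], frag)
    n <- n - 1L
  }

  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frags[1], fmt(va), frags[2], fmt(vb), frags[3], fmt(vc))
  ape::read.tree(text = nwk)
}

# integer-code an alignment: A,C,G,T -> 1..4, everything else (gaps,
# ambiguity codes) -> NA ("missing")
encode_msa <- function(msa) {
  m <- seq_matrix(msa)
  codes <- matrix(match(m, c("A", "C", "G", "T")), nrow(m), ncol(m))
  rownames(codes) <- rownames(m)
  codes
}

#' Jukes–Cantor distance matrix from an alignment
#'
#' Proportions of differing sites are computed with pairwise deletion (gaps
#' and ambiguity codes are missing), then `d = -3/4 log(1 - 4p/3)`.
#' Saturated pairs (`p >= 0.75`) and pairs with no comparable sites are
#' capped at `d_max`.
#'
#' @param msa named character vector alignment.
#' @param d_max cap for saturated distances (substitutions/site).
#' @return symmetric distance matrix with sequence ids as dimnames.
#' @export
jc_distance <- function(msa, d_max = 5) {
  as_msa(msa)
  codes <- encode_msa(msa)
  pd <- .pairwise_pdist(codes)
  p <- pd$p
  d <- matrix(d_max, nrow(p), ncol(p))
  ok <- !is.na(p) & p < 0.75
  d[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  diag(d) <- 0
  dimnames(d) <- list(names(msa), names(msa))
  d
}

# JC transition probability matrix for branch length t
jc_pmatrix <- function(t) {
  e <- exp(-4 * t / 3)
  same <- 0.25 + 0.75 * e
  diff <- 0.25 - 0.25 * e
  P <- matrix(diff, 4, 4)
  diag(P) <- same
  P
}

#' Log-likelihood of an alignment on a tree (Jukes–Cantor)
#'
#' Felsenstein pruning under the Jukes–Cantor model with uniform base
#' frequencies; columns are independent; gaps and ambiguity codes are
#' missing data, so an all-gap column contributes exactly 0.
#'
#' @param msa named character vector alignment.
#' @param tree `ape::phylo` with branch lengths; leaf set must equal the
#'   alignment rows. Zero-length branches are allowed.
#' @return the log-likelihood (a scalar; may be `-Inf` for impossible
#'   zero-length-branch configurations).
#' @export
score_alignment_tree <- function(msa, tree) {
  as_msa(msa)
  if (!setequal(tree$tip.label, names(msa))) {
    stop("tree leaves must match alignment rows", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree must have branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths", call. = FALSE)
  }

  codes <- encode_msa(msa)[tree$tip.label, , drop = FALSE]
  key <- apply(codes, 2L, paste, collapse = "\r")
  upat <- !duplicated(key)
  pat <- codes[, upat, drop = FALSE]
  w <- as.vector(table(key)[key[upat]])
  npat <- ncol(pat)

  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  L <- vector("list", nnode)
  logscale <- matrix(0, nnode, npat)
  for (i in seq_len(ntip)) {
    li <- matrix(0, 4, npat)
    s <- pat[i, ]
    miss <- is.na(s)
    li[, miss] <- 1
    if (any(!miss)) li[cbind(s[!miss], which(!miss))] <- 1
    L[[i]] <- li
  }
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]
    child <- tr$edge[e, 2L]
    P <- jc_pmatrix(tr$edge.length[e])
    contrib <- P %*% L[[child]]
    if (is.null(L[[parent]])) {
      L[[parent]] <- contrib
    } else {
      L[[parent]] <- L[[parent]] * contrib
    }
    logscale[parent, ] <- logscale[parent, ] + logscale[child, ]
    # rescale to avoid underflow
    mx <- apply(L[[parent]], 2L, max)
    pos <- mx > 0
    if (any(pos)) {
      L[[parent]][, pos] <- sweep(L[[parent]][, pos, drop = FALSE], 2L,
                                  mx[pos], "/")
      logscale[parent, pos] <- logscale[parent, pos] + log(mx[pos])
    }
  }
  root <- ntip + 1L
  lik <- colSums(0.25 * L[[root]])
  sum(w * (log(lik) + logscale[root, ]))
}
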