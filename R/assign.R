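#' Assign environmental query sequences to labeled reference clades
#'
#' For each query leaf, walks from the leaf toward the root of the
#' midpoint-rooted tree and inspects each enclosing clade: the first clade
#' with support strictly above `threshold` that contains at least one
#' labeled reference assigns its label if all its references agree; clades
#' with mixed labels are passed over (the walk continues outward); queries
#' for which no such clade exists stay `"unassigned"` with a reason.
#'
#' @param support a `support_result` from [bootstrap_support()] (its
#'   bipartition table provides clade support), or an `ape::phylo` whose
#'   internal node labels are support values.
#' @param labels named character vector mapping reference leaf ids to group
#'   names; leaves absent from it are queries.
#' @param threshold support threshold (strict; default 0.94, the
#'   significance convention for posterior probabilities).
#' @param queries ids to place; defaults to all unlabeled leaves.
#' @return data.frame with one row per query: `query`, `group` (or
#'   `"unassigned"`), `support`, `clade_size`, `references` (comma-joined
#'   co-resident reference ids), `reason` (for unassigned queries).
#' @export
assign_queries <- function(support, labels, threshold = 0.94,
                           queries = NULL) {
  if (inherits(support, "support_result")) {
    tree <- support$tree
    smap <- setNames(support$table$support, support$table$bipartition)
  } else if (inherits(support, "phylo")) {
    tree <- support
    smap <- numeric(0)
    if (!is.null(tree$node.label)) {
      ntip <- length(tree$tip.label)
      clades <- node_clades(tree)
      for (node in (ntip + 1L):(ntip + tree$Nnode)) {
        cl <- clades[[node]]
        if (length(cl) <= 1L || length(cl) >= ntip - 1L) next
        v <- suppressWarnings(as.numeric(tree$node.label[node - ntip]))
        if (!is.na(v)) smap[bipart_key(cl, tree$tip.label)] <- v
      }
    }
  } else {
    stop("support must be a support_result or a phylo", call. = FALSE)
  }
  if (length(labels) == 0L) stop("need at least one labeled reference",
                                 call. = FALSE)
  tips <- tree$tip.label
  if (is.null(queries)) queries <- setdiff(tips, names(labels))
  if (!all(queries %in% tips)) stop("query not in tree", call. = FALSE)

  rooted <- phangorn::midpoint(tree)
  ntip <- length(rooted$tip.label)
  clades <- node_clades(rooted)
  parent_of <- integer(ntip + rooted$Nnode)
  parent_of[rooted$edge[, 2L]] <- rooted$edge[, 1L]

  rows <- lapply(queries, function(q) {
    node <- parent_of[match(q, rooted$tip.label)]
    saw_mixed <- FALSE
    while (node != 0L) {
      cl <- clades[[node]]
      refs <- intersect(cl, names(labels))
      s <- if (length(cl) > 1L && length(cl) < ntip - 1L) {
        unname(smap[bipart_key(cl, rooted$tip.label)])
      } else NA_real_
      if (length(refs) && !is.na(s) && s > threshold) {
        grp <- unique(unname(labels[refs]))
        if (length(grp) == 1L) {
          return(data.frame(query = q, group = grp, support = s,
                            clade_size = length(cl),
                            references = paste(sort(refs), collapse = ","),
                            reason = "", stringsAsFactors = FALSE))
        }
        saw_mixed <- TRUE
      }
      node <- parent_of[node]
    }
    data.frame(query = q, group = "unassigned", support = NA_real_,
               clade_size = NA_integer_, references = "",
               reason = if (saw_mixed) "mixed labels at all supported levels"
                        else "no supported clade",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
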