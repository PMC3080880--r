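#' Configuration for the synthetic ITS evolution simulator
#'
#' The generator emulates fungal ITS data across divergent lineages: a slowly
#' evolving ~160 nt 5.8S core flanked by fast-evolving, indel-rich ITS1 and
#' ITS2 spacers. Defaults are calibrated so that whole-ITS similarity between
#' groups falls below 70% (with within-group extremes in the 55-70% band),
#' the divergence regime reported for earth-tongue fungi and their relatives.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param birth_rate Yule birth rate for tree shape.
#' @param depth_scale expected root-to-tip substitutions/site at the slow
#'   (5.8S) rate; branch lengths are rescaled so tree height equals this.
#' @param region_lengths root lengths (nt) for `its1`, `r58s`, `its2`.
#' @param rate_multipliers per-region relative substitution rates; `r58s`
#'   must be 1 (normalisation convention).
#' @param indel_rate per-region expected indel events per site per unit
#'   branch length; 0 for 5.8S by default (length-conserved core).
#' @param indel_length_mean mean of the geometric indel length distribution.
#' @param n_queries number of leaves whose labels are masked as
#'   `"environmental"`.
#' @param n_groups number of reference groups ("genera") cut from the tree.
#' @param artifact_fractions fractions of records to reverse-complement,
#'   truncate (drop ITS2) or shorten below typical length.
#' @param short_length length (nt) to which "short" artifact records are cut.
#' @param chimera_fraction fraction of records whose ITS2 is swapped with
#'   another record's (truth flags emitted; no chimera detector exists here).
#' @param seed integer seed; the full simulation is reproducible from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 32L,
                       birth_rate = 1,
                       depth_scale = 0.04,
                       region_lengths = c(its1 = 220L, r58s = 160L,
                                          its2 = 240L),
                       rate_multipliers = c(its1 = 8, r58s = 1, its2 = 8),
                       indel_rate = c(its1 = 0.5, r58s = 0, its2 = 0.5),
                       indel_length_mean = 3,
                       n_queries = 8L,
                       n_groups = 4L,
                       artifact_fractions = c(reverse_complement = 0,
                                              truncate = 0, short = 0),
                       short_length = 150L,
                       chimera_fraction = 0,
                       seed = 1L) {
  regions <- c("its1", "r58s", "its2")
  region_lengths <- region_lengths[regions]
  rate_multipliers <- rate_multipliers[regions]
  indel_rate <- indel_rate[regions]
  if (anyNA(region_lengths) || anyNA(rate_multipliers) || anyNA(indel_rate)) {
    stop("region_lengths, rate_multipliers and indel_rate need entries ",
         "its1, r58s, its2", call. = FALSE)
  }
  if (any(region_lengths <= 0)) stop("region lengths must be > 0",
                                     call. = FALSE)
  if (any(rate_multipliers < 0) || any(indel_rate < 0) ||
      indel_length_mean < 1 || depth_scale < 0 || birth_rate <= 0) {
    stop("rates and lengths must be non-negative", call. = FALSE)
  }
  if (rate_multipliers[["r58s"]] != 1) {
    stop("rate_multipliers['r58s'] must equal 1 (normalisation convention)",
         call. = FALSE)
  }
  af <- artifact_fractions[c("reverse_complement", "truncate", "short")]
  af[is.na(af)] <- 0
  names(af) <- c("reverse_complement", "truncate", "short")
  if (any(af < 0) || any(af > 1) || chimera_fraction < 0 ||
      chimera_fraction > 1) {
    stop("artifact fractions must lie in [0, 1]", call. = FALSE)
  }
  if (n_queries < 0 || n_queries >= n_taxa) {
    stop("n_queries must be in [0, n_taxa)", call. = FALSE)
  }
  structure(list(n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
                 depth_scale = depth_scale,
                 region_lengths = region_lengths,
                 rate_multipliers = rate_multipliers,
                 indel_rate = indel_rate,
                 indel_length_mean = indel_length_mean,
                 n_queries = as.integer(n_queries),
                 n_groups = as.integer(n_groups),
                 artifact_fractions = af,
                 short_length = as.integer(short_length),
                 chimera_fraction = chimera_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample a Yule tree for simulation
#'
#' Pure-birth tree with `n_taxa` leaves labelled `t0001`, `t0002`, ...,
#' rescaled so the root-to-tip height equals `depth_scale` (expected
#' substitutions/site at the slow-region rate). Reproducible from the
#' config seed.
#'
#' @param cfg a [sim_config()].
#' @return a rooted binary `ape::phylo`.
#' @export
sample_tree <- function(cfg) {
  if (cfg$n_taxa < 3L) stop("n_taxa must be >= 3", call. = FALSE)
  set.seed(cfg$seed)
  tr <- ape::rphylo(cfg$n_taxa, birth = cfg$birth_rate, death = 0)
  tr$tip.label <- sprintf("t%04d", seq_len(cfg$n_taxa))
  height <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * cfg$depth_scale / height
  # guard strictly positive branch lengths
  tr$edge.length <- pmax(tr$edge.length, 1e-9)
  tr
}

DNA4 <- c("A", "C", "G", "T")

# evolve one region along one branch; x = list(chars, cols); registry is an
# environment holding the global column order and counter for this region
evolve_branch <- function(x, b, rate_m, indel_rate, len_mean, reg) {
  chars <- x$chars
  cols <- x$cols
  len <- length(chars)
  # substitutions (Jukes-Cantor)
  if (len > 0 && rate_m > 0) {
    p <- 0.75 * (1 - exp(-4 * rate_m * b / 3))
    hit <- which(runif(len) < p)
    if (length(hit)) {
      idx <- match(chars[hit], DNA4)
      step <- sample.int(3L, length(hit), replace = TRUE)
      chars[hit] <- DNA4[((idx - 1L + step) %% 4L) + 1L]
    }
  }
  # indels: Poisson number of events, geometric lengths, ins/del equiprobable
  if (indel_rate > 0 && len > 0) {
    n_ev <- rpois(1L, indel_rate * b * len)
    for (ev in seq_len(n_ev)) {
      len <- length(chars)
      g <- rgeom(1L, 1 / len_mean) + 1L
      if (runif(1L) < 0.5) {               # insertion
        pos <- sample.int(len + 1L, 1L) - 1L   # insert after residue pos
        new_ids <- reg$counter + seq_len(g)
        reg$counter <- reg$counter + g
        slot <- if (len == 0L) {
          length(reg$order)
        } else if (pos == 0L) {
          match(cols[1L], reg$order) - 1L
        } else {
          match(cols[pos], reg$order)
        }
        reg$order <- append(reg$order, new_ids, after = slot)
        chars <- append(chars, sample(DNA4, g, replace = TRUE), after = pos)
        cols <- append(cols, new_ids, after = pos)
      } else if (len > 0L) {               # deletion
        start <- sample.int(len, 1L)
        drop <- start:min(len, start + g - 1L)
        chars <- chars[-drop]
        cols <- cols[-drop]
      }
    }
  }
  list(chars = chars, cols = cols)
}

#' Evolve ITS-like sequences along a tree
#'
#' Residues evolve per region (ITS1, 5.8S, ITS2) under Jukes–Cantor with
#' per-region rate multipliers; indels (Poisson events, geometric lengths,
#' insertion/deletion equiprobable) are applied per region; the true
#' alignment is recorded by propagating insertion columns. Region maps are
#' 0-based half-open on the ungapped residues.
#'
#' @param tree rooted `ape::phylo` from [sample_tree()].
#' @param cfg a [sim_config()].
#' @return a list of class `its_sim` (see [simulate_its()]).
#' @export
evolve_its <- function(tree, cfg) {
  if (length(tree$tip.label) < 3L) stop("tree needs >= 3 leaves",
                                        call. = FALSE)
  set.seed(cfg$seed + 1L)
  regions <- c("its1", "r58s", "its2")
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  root <- ntip + 1L

  leaf_rows <- list()   # per region: matrix of gapped rows
  leaf_seqs <- list()   # per region: named ungapped strings
  for (r in regions) {
    L <- cfg$region_lengths[[r]]
    reg <- new.env(parent = emptyenv())
    reg$order <- seq_len(L)
    reg$counter <- L
    states <- vector("list", ntip + tr$Nnode)
    states[[root]] <- list(chars = sample(DNA4, L, replace = TRUE),
                           cols = seq_len(L))
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1L]
      child <- tr$edge[e, 2L]
      states[[child]] <- evolve_branch(states[[parent]], tr$edge.length[e],
                                       cfg$rate_multipliers[[r]],
                                       cfg$indel_rate[[r]],
                                       cfg$indel_length_mean, reg)
    }
    rows <- matrix("-", ntip, length(reg$order),
                   dimnames = list(tr$tip.label, NULL))
    seqs <- character(ntip)
    for (i in seq_len(ntip)) {
      st <- states[[i]]
      rows[i, match(st$cols, reg$order)] <- st$chars
      seqs[i] <- paste(st$chars, collapse = "")
    }
    leaf_rows[[r]] <- rows
    leaf_seqs[[r]] <- setNames(seqs, tr$tip.label)
  }

  ids <- tr$tip.label
  records <- setNames(paste0(leaf_seqs$its1, leaf_seqs$r58s, leaf_seqs$its2),
                      ids)
  true_alignment <- collapse_rows(cbind(leaf_rows$its1, leaf_rows$r58s,
                                        leaf_rows$its2))
  alignment_regions <- rep(c("ITS1", "5.8S", "ITS2"),
                           times = vapply(leaf_rows, ncol, integer(1)))
  l1 <- nchar(leaf_seqs$its1); l2 <- nchar(leaf_seqs$r58s)
  l3 <- nchar(leaf_seqs$its2)
  region_maps <- data.frame(
    id = rep(ids, each = 3L),
    region = rep(c("ITS1", "5.8S", "ITS2"), times = length(ids)),
    start = as.integer(rbind(0L, l1, l1 + l2)),
    end = as.integer(rbind(l1, l1 + l2, l1 + l2 + l3)),
    stringsAsFactors = FALSE
  )
  structure(list(config = cfg, tree = tree, records = records,
                 pre_artifact_records = records,
                 true_alignment = true_alignment,
                 alignment_regions = alignment_regions,
                 region_maps = region_maps,
                 labels = NULL, query_ids = character(0),
                 artifact_table = data.frame(
                   id = ids, reverse_complemented = FALSE, truncated = FALSE,
                   short = FALSE, chimera = FALSE,
                   stringsAsFactors = FALSE)),
            class = "its_sim")
}

# cut a rooted tree into n_groups clades by repeatedly splitting the clade
# with the most leaves (ties: the one containing the smallest leaf id)
tree_groups <- function(tree, n_groups) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  tips_under <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tips_under))
  }
  clades <- list(ntip + 1L)
  while (length(clades) < n_groups) {
    sizes <- vapply(clades, function(nd) length(tips_under(nd)), integer(1))
    internal <- vapply(clades, function(nd) nd > ntip, logical(1))
    if (!any(internal & sizes > 1L)) break
    cand <- which(internal & sizes == max(sizes[internal]))
    mins <- vapply(clades[cand], function(nd) min(tips_under(nd)),
                   character(1))
    pick <- cand[order(mins)[1L]]
    node <- clades[[pick]]
    clades <- c(clades[-pick], as.list(kids[[as.character(node)]]))
  }
  sets <- lapply(clades, tips_under)
  sets <- sets[order(vapply(sets, min, character(1)))]
  labels <- character(0)
  for (g in seq_along(sets)) {
    labels[sets[[g]]] <- sprintf("g%d", g)
  }
  labels
}

#' Inject database-style artifacts into simulated records
#'
#' Marks seeded fractions of records as reverse-complemented, ITS2-truncated
#' or shortened, mirroring the defects encountered when mining public ITS
#' records. Selection counts are `round(fraction * n)` without replacement.
#' The true alignment always refers to the pre-artifact residues.
#'
#' @param sim an `its_sim` from [evolve_its()] / [simulate_its()].
#' @param cfg a [sim_config()] supplying `artifact_fractions` and seed.
#' @return the modified `its_sim`, with `artifact_table` flags set.
#' @export
inject_artifacts <- function(sim, cfg = sim$config) {
  af <- cfg$artifact_fractions
  set.seed(cfg$seed + 3L)
  ids <- names(sim$records)
  n <- length(ids)
  pick <- function(frac) {
    k <- round_half_up(frac * n)
    if (k == 0) character(0) else sample(ids, k)
  }
  rc_ids <- pick(af[["reverse_complement"]])
  tr_ids <- pick(af[["truncate"]])
  sh_ids <- pick(af[["short"]])
  ch_ids <- pick(cfg$chimera_fraction)

  rm <- sim$region_maps
  # chimeras first: swap ITS2 with a rotated partner (flags only downstream)
  if (length(ch_ids) > 1L) {
    partner <- c(ch_ids[-1L], ch_ids[1L])
    its2_of <- function(id) {
      iv <- region_map(rm, id)[["ITS2"]]
      substr(sim$records[[id]], iv[1] + 1L, iv[2])
    }
    pieces <- vapply(partner, its2_of, character(1))
    for (i in seq_along(ch_ids)) {
      id <- ch_ids[i]
      iv <- region_map(rm, id)[["ITS2"]]
      head_part <- substr(sim$records[[id]], 1L, iv[1])
      sim$records[[id]] <- paste0(head_part, pieces[i])
      rm$end[rm$id == id & rm$region == "ITS2"] <-
        nchar(head_part) + nchar(pieces[i])
    }
  }
  # truncation: drop the ITS2 subregion
  for (id in tr_ids) {
    iv <- region_map(rm, id)[["ITS2"]]
    sim$records[[id]] <- substr(sim$records[[id]], 1L, iv[1])
    rm <- rm[!(rm$id == id & rm$region == "ITS2"), ]
  }
  # shortening: keep a prefix below typical length
  for (id in sh_ids) {
    keep <- min(cfg$short_length, nchar(sim$records[[id]]))
    sim$records[[id]] <- substr(sim$records[[id]], 1L, keep)
    sel <- rm$id == id
    rm$start[sel] <- pmin(rm$start[sel], keep)
    rm$end[sel] <- pmin(rm$end[sel], keep)
    rm <- rm[!(sel & rm$start == rm$end), ]
  }
  # reverse complement last (region maps keep forward-orientation coords)
  if (length(rc_ids)) {
    sim$records[rc_ids] <- revcomp(sim$records[rc_ids])
  }
  at <- sim$artifact_table
  at$reverse_complemented <- at$id %in% rc_ids
  at$truncated <- at$id %in% tr_ids
  at$short <- at$id %in% sh_ids
  at$chimera <- at$id %in% ch_ids
  sim$artifact_table <- at
  sim$region_maps <- rm
  sim
}

#' Simulate a full ITS dataset with known truth
#'
#' Composes [sample_tree()], [evolve_its()], group labelling, query masking
#' and [inject_artifacts()]. Reference groups are clades cut from the true
#' tree; `n_queries` leaves are masked as `"environmental"` such that every
#' group keeps at least two labelled references.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `its_sim` with elements `config`, `tree` (true
#'   tree), `records` (post-artifact), `pre_artifact_records`,
#'   `true_alignment`, `region_maps`, `labels` (true group of every leaf),
#'   `ref_labels` (labels with queries masked out), `query_ids`,
#'   `artifact_table`.
#' @export
simulate_its <- function(cfg = sim_config()) {
  tree <- sample_tree(cfg)
  sim <- evolve_its(tree, cfg)
  labels <- tree_groups(tree, cfg$n_groups)
  set.seed(cfg$seed + 2L)
  ids <- sample(names(sim$records))   # shuffled candidate order
  queries <- character(0)
  tally <- table(labels)
  for (id in ids) {
    if (length(queries) >= cfg$n_queries) break
    g <- labels[[id]]
    if (tally[[g]] > 2L) {
      queries <- c(queries, id)
      tally[[g]] <- tally[[g]] - 1L
    }
  }
  sim$labels <- labels
  sim$query_ids <- sort(queries)
  sim$ref_labels <- labels[setdiff(names(sim$records), sim$query_ids)]
  inject_artifacts(sim, cfg)
}

#' Write a simulated dataset to disk
#'
#' Emits `records.fasta` (unaligned), `true_alignment.fasta` (gapped),
#' `true_tree.nwk`, `regions.tsv` and `truth.json` (labels, queries,
#' artifact table).
#'
#' @param sim an `its_sim`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$records, file.path(dir, "records.fasta"))
  write_fasta(sim$true_alignment, file.path(dir, "true_alignment.fasta"))
  ape::write.tree(sim$tree, file.path(dir, "true_tree.nwk"))
  write_regions(sim$region_maps, file.path(dir, "regions.tsv"))
  truth <- list(labels = as.list(sim$labels),
                query_ids = sim$query_ids,
                artifact_table = sim$artifact_table,
                seed = sim$config$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
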