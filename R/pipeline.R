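STRATEGIES <- c("baseline_whole", "coest_whole", "coest_anchored",
                "coest_58s_reincluded")

#' Pipeline configuration
#'
#' Desk-scale defaults: 2 runs of 10 co-estimation iterations and 100
#' bootstrap replicates (the full-scale analog would be 6 runs of 20
#' iterations, see [coestimate()]).
#'
#' @param runs,iterations co-estimation runs and iterations per run.
#' @param bootstrap_replicates replicates for [bootstrap_support()].
#' @param support_threshold significance threshold on branch support.
#' @param scoring an [align_scoring()] scheme.
#' @param k word size for guide-tree distances.
#' @param d_max Jukes–Cantor saturation cap.
#' @param anchor_length length of the constant 5.8S anchor.
#' @param long_branch_factor multiple of the median terminal branch length
#'   beyond which a leaf counts as an extremely long branch.
#' @param min_length,require_its2 record filters (see [filter_records()]).
#' @param seed integer seed for the whole pipeline.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(runs = 2L, iterations = 10L,
                            bootstrap_replicates = 100L,
                            support_threshold = 0.94,
                            scoring = align_scoring(), k = 6L, d_max = 5,
                            anchor_length = 16L, long_branch_factor = 5,
                            min_length = 200L, require_its2 = TRUE,
                            seed = 1L) {
  structure(list(runs = as.integer(runs), iterations = as.integer(iterations),
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 support_threshold = support_threshold, scoring = scoring,
                 k = as.integer(k), d_max = d_max,
                 anchor_length = as.integer(anchor_length),
                 long_branch_factor = long_branch_factor,
                 min_length = as.integer(min_length),
                 require_its2 = require_its2, seed = as.integer(seed)),
            class = "pipeline_config")
}

strategy_report <- function(strategy, msa, sup, cfg, groups, truth_tree,
                            truth_alignment, seed) {
  metrics <- tree_metrics(sup$tree, msa, groups = groups,
                          threshold = cfg$support_threshold,
                          truth_tree = truth_tree,
                          truth_alignment = truth_alignment,
                          long_branch_factor = cfg$long_branch_factor)
  assignments <- NULL
  if (!is.null(groups) &&
      length(setdiff(sup$tree$tip.label, names(groups)))) {
    assignments <- assign_queries(sup, groups, cfg$support_threshold)
  }
  list(strategy = strategy, msa = msa, tree = sup$tree,
       support_table = sup$table, columns = classify_columns(msa),
       metrics = metrics, assignments = assignments, seed = seed,
       error = NULL)
}

failed_report <- function(strategy, e) {
  list(strategy = strategy, msa = NULL, tree = NULL, support_table = NULL,
       columns = NULL, metrics = NULL, assignments = NULL, seed = NA,
       error = conditionMessage(e))
}

#' Run the four alignment strategies end-to-end
#'
#' Executes, on one set of unaligned ITS records:
#' 1. `baseline_whole` — single-pass progressive alignment (one run, one
#'    iteration) of the whole ITS;
#' 2. `coest_whole` — the full co-estimation loop on whole sequences;
#' 3. `coest_anchored` — 5.8S replaced by the constant anchor, then
#'    co-estimation;
#' 4. `coest_58s_reincluded` — the excised 5.8S re-inserted into strategy
#'    3's best alignment, then tree and support on the combined alignment.
#'
#' Each strategy gets bootstrap support, column classification, tree metrics
#' (against the simulated truth when supplied) and query assignments. A
#' failing strategy is isolated and reported; the others still run.
#'
#' @param records named character vector of unaligned sequences (already
#'   oriented and filtered; see [orient()] and [filter_records()]).
#' @param regions region annotation data.frame (required for strategies 3-4).
#' @param groups named character vector of reference labels; leaves absent
#'   from it are treated as environmental queries.
#' @param cfg a [pipeline_config()].
#' @param truth_tree,truth_alignment optional simulated truth for accuracy
#'   metrics.
#' @return list of class `strategy_comparison`: `reports` (one per
#'   strategy), `comparison` (data.frame ranking the strategies), `anchored`
#'   (the `anchored_set` used), `seed`.
#' @export
run_strategies <- function(records, regions = NULL, groups = NULL,
                           cfg = pipeline_config(), truth_tree = NULL,
                           truth_alignment = NULL) {
  check_ids(records)
  reports <- list()
  seed <- cfg$seed

  run_one <- function(strategy, expr) {
    tryCatch(expr, error = function(e) failed_report(strategy, e))
  }

  reports$baseline_whole <- run_one("baseline_whole", {
    co <- coestimate(records, runs = 1L, iterations = 1L, seed = seed,
                     scoring = cfg$scoring, k = cfg$k, d_max = cfg$d_max)
    sup <- bootstrap_support(co$msa, cfg$bootstrap_replicates,
                             seed = seed + 11L, d_max = cfg$d_max)
    strategy_report("baseline_whole", co$msa, sup, cfg, groups, truth_tree,
                    truth_alignment, seed)
  })

  co2 <- NULL
  reports$coest_whole <- run_one("coest_whole", {
    co2 <- coestimate(records, runs = cfg$runs,
                       iterations = cfg$iterations, seed = seed,
                       scoring = cfg$scoring, k = cfg$k, d_max = cfg$d_max)
    sup <- bootstrap_support(co2$msa, cfg$bootstrap_replicates,
                             seed = seed + 12L, d_max = cfg$d_max)
    rep <- strategy_report("coest_whole", co2$msa, sup, cfg, groups,
                           truth_tree, truth_alignment, seed)
    rep$trace <- co2$trace
    rep
  })

  aset <- NULL
  co3 <- NULL
  reports$coest_anchored <- run_one("coest_anchored", {
    if (is.null(regions)) stop("anchored strategies need region annotations")
    aset <- make_anchored(records, regions, cfg$anchor_length)
    co3 <- coestimate(aset$anchored_records, runs = cfg$runs,
                       iterations = cfg$iterations, seed = seed,
                       scoring = cfg$scoring, k = cfg$k, d_max = cfg$d_max,
                       accept = function(msa)
                         anchor_intact(msa, aset$anchor))
    # canonical form: score-equivalent gap slides moved onto the modal block
    co3$msa <- normalize_anchor_block(co3$msa, aset$anchor)
    sup <- bootstrap_support(co3$msa, cfg$bootstrap_replicates,
                             seed = seed + 13L, d_max = cfg$d_max)
    rep <- strategy_report("coest_anchored", co3$msa, sup, cfg, groups,
                           truth_tree, NULL, seed)
    rep$trace <- co3$trace
    rep
  })

  reports$coest_58s_reincluded <- run_one("coest_58s_reincluded", {
    if (is.null(co3)) stop("anchored strategy failed; cannot re-include 5.8S")
    msa4 <- reinsert_58s(co3$msa, aset$excised[names(co3$msa)],
                         anchor = aset$anchor, scoring = cfg$scoring,
                         guide = co3$tree)
    block_width <- msa_ncol(msa4) - msa_ncol(co3$msa) + cfg$anchor_length
    stopifnot(block_width >= max(nchar(aset$excised)))
    sup <- bootstrap_support(msa4, cfg$bootstrap_replicates,
                             seed = seed + 14L, d_max = cfg$d_max)
    strategy_report("coest_58s_reincluded", msa4, sup, cfg, groups,
                    truth_tree, truth_alignment, seed)
  })

  structure(list(reports = reports,
                 comparison = comparison_table(reports),
                 anchored = aset, seed = seed),
            class = "strategy_comparison")
}

comparison_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    if (!is.null(r$error)) {
      return(data.frame(strategy = r$strategy, error = r$error,
                        ncol = NA, pct_informative = NA,
                        supported_fraction = NA, n_long_branches = NA,
                        rf = NA, rf_normalized = NA, sp_score = NA,
                        column_score = NA, n_assigned = NA))
    }
    m <- r$metrics
    data.frame(
      strategy = r$strategy, error = "",
      ncol = msa_ncol(r$msa),
      pct_informative = r$columns$pct_informative,
      supported_fraction = m$supported_fraction,
      n_long_branches = length(m$long_branch_ids),
      rf = if (is.null(m$rf)) NA else m$rf$count,
      rf_normalized = if (is.null(m$rf)) NA else m$rf$normalized,
      sp_score = if (is.null(m$accuracy)) NA else m$accuracy$sp_score,
      column_score = if (is.null(m$accuracy)) NA else
        m$accuracy$column_score,
      n_assigned = if (is.null(r$assignments)) NA else
        sum(r$assignments$group != "unassigned"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # rank by RF to truth when known, then by supported fraction
  ord <- order(out$rf_normalized, -out$supported_fraction,
               out$n_long_branches, na.last = TRUE)
  out[ord, ]
}

#' Simulate a dataset and run the four strategies on it
#'
#' Composes [simulate_its()] with orientation correction, record filters and
#' [run_strategies()], and scores query assignments against the simulated
#' truth.
#'
#' @param sim_cfg a [sim_config()].
#' @param cfg a [pipeline_config()].
#' @return list with `sim` (the `its_sim`, including `true_alignment` and
#'   its per-column `alignment_regions`), `result` (the
#'   `strategy_comparison`), and `assignment_scores` (data.frame per
#'   strategy: queries assigned, correctly assigned, accuracy among
#'   assigned).
#' @export
simulate_and_run <- function(sim_cfg = sim_config(),
                             cfg = pipeline_config(seed = sim_cfg$seed)) {
  sim <- simulate_its(sim_cfg)
  refs <- sim$records[names(sim$ref_labels)]
  ori <- orient(sim$records, refs)
  rep <- filter_records(ori$records, sim$region_maps,
                        min_length = cfg$min_length,
                        require_its2 = cfg$require_its2)
  records <- ori$records[rep$kept]
  groups <- sim$ref_labels[names(sim$ref_labels) %in% rep$kept]
  truth_aln <- sim$true_alignment[rep$kept]
  result <- run_strategies(records, sim$region_maps, groups, cfg,
                           truth_tree = sim$tree,
                           truth_alignment = truth_aln)
  scores <- lapply(result$reports, function(r) {
    if (is.null(r$assignments)) {
      return(data.frame(strategy = r$strategy, n_queries = NA_integer_,
                        n_assigned = NA_integer_, n_correct = NA_integer_,
                        accuracy = NA_real_))
    }
    a <- r$assignments
    assigned <- a[a$group != "unassigned", , drop = FALSE]
    correct <- sum(assigned$group == sim$labels[assigned$query])
    data.frame(strategy = r$strategy, n_queries = nrow(a),
               n_assigned = nrow(assigned), n_correct = correct,
               accuracy = if (nrow(assigned)) correct / nrow(assigned)
                          else NA_real_)
  })
  scores <- do.call(rbind, scores)
  rownames(scores) <- NULL
  list(sim = sim, result = result, assignment_scores = scores)
}

#' Write a strategy comparison to disk
#'
#' Per strategy: gapped FASTA alignment, Newick tree with support labels,
#' support table and assignments as TSV; plus `comparison.tsv`,
#' `comparison.json` and a short Markdown summary.
#'
#' @param result a `strategy_comparison` from [run_strategies()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in result$reports) {
    if (!is.null(r$error)) next
    base <- file.path(dir, r$strategy)
    write_fasta(r$msa, paste0(base, ".alignment.fasta"))
    ape::write.tree(r$tree, paste0(base, ".tree.nwk"))
    write.table(r$support_table, paste0(base, ".support.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(r$assignments)) {
      write.table(r$assignments, paste0(base, ".assignments.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  write.table(result$comparison, file.path(dir, "comparison.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$comparison, file.path(dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  md <- c("# Strategy comparison", "",
          sprintf("Seed: %d", result$seed), "",
          paste(capture.output(print(result$comparison)), collapse = "\n"))
  writeLines(md, file.path(dir, "summary.md"))
  invisible(dir)
}
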