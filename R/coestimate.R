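#' Iterative co-estimation of alignment and tree
#'
#' Desk-scale analog of simultaneous alignment/tree estimation: each run
#' starts from a k-mer-distance neighbor-joining guide tree (perturbed per
#' run by seeded multiplicative noise on the distances), then iterates
#' progressive alignment on the current tree, tree re-estimation
#' (Jukes–Cantor distances from the alignment + neighbor-joining) and
#' scoring by Jukes–Cantor log-likelihood on that tree. The best-scored
#' (alignment, tree) pair across all runs and iterations is kept.
#'
#' An iteration whose guide tree repeats an earlier guide within the same
#' run reuses the cached alignment (the procedure is deterministic given
#' the guide), so converged runs cost little.
#'
#' @param records named character vector of unaligned sequences (>= 4
#'   recommended).
#' @param runs number of independent runs.
#' @param iterations iterations per run.
#' @param seed integer seed controlling the per-run guide perturbations.
#' @param scoring an [align_scoring()] scheme.
#' @param k word size for the initial guide distances.
#' @param noise_sd relative amplitude of the per-run multiplicative noise on
#'   the initial distance matrix (runs differ only by this stochasticity).
#' @param d_max saturation cap for Jukes–Cantor distances.
#' @param accept optional predicate on the alignment; only iterates for
#'   which it returns `TRUE` compete for the best-scored pair (the anchored
#'   strategy uses it to keep only alignments whose constant anchor block
#'   survived intact). All iterations are still traced.
#' @return list of class `coestimation_trace`: `msa` and `tree` (the best
#'   pair), `score`, `best_run`, `best_iteration`, and `trace` (data.frame
#'   of run, iteration, score, accepted).
#' @export
coestimate <- function(records, runs = 6L, iterations = 20L, seed = 1L,
                       scoring = align_scoring(), k = 6L, noise_sd = 0.05,
                       d_max = 5, accept = NULL) {
  check_ids(records)
  check_dna(records)
  if (length(records) < 3L) stop("need at least 3 records", call. = FALSE)
  if (runs < 1L || iterations < 1L) {
    stop("runs and iterations must be >= 1", call. = FALSE)
  }
  D0 <- kmer_distance_matrix(records, k)
  set.seed(seed)
  best <- list(score = -Inf, msa = NULL, tree = NULL,
               run = NA_integer_, iteration = NA_integer_)
  trace <- vector("list", runs * iterations)
  row <- 0L
  for (run in seq_len(runs)) {
    D <- D0
    if (run > 1L) {   # run 1 uses the unperturbed guide
      noise <- matrix(runif(length(D), 1 - noise_sd, 1 + noise_sd), nrow(D))
      noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
      D <- D * noise
      diag(D) <- 0
    }
    guide <- nj_tree(D)
    seen <- new.env(parent = emptyenv())
    for (it in seq_len(iterations)) {
      # alignment depends on the guide only through its topology
      key <- paste(sort(bipartitions(guide)), collapse = ";")
      hit <- get0(key, envir = seen)
      if (is.null(hit)) {
        msa <- progressive_align(records, guide, scoring)
        tree <- nj_tree(jc_distance(msa, d_max))
        score <- score_alignment_tree(msa, tree)
        ok <- is.null(accept) || isTRUE(accept(msa))
        assign(key, list(msa = msa, tree = tree, score = score, ok = ok),
               envir = seen)
      } else {
        msa <- hit$msa; tree <- hit$tree; score <- hit$score; ok <- hit$ok
      }
      row <- row + 1L
      trace[[row]] <- data.frame(run = run, iteration = it, score = score,
                                 accepted = ok)
      if (ok && score > best$score) {
        best <- list(score = score, msa = msa, tree = tree,
                     run = run, iteration = it)
      }
      guide <- tree
    }
  }
  if (is.null(best$msa)) {
    stop("no iteration produced an acceptable alignment", call. = FALSE)
  }
  structure(list(msa = best$msa, tree = best$tree, score = best$score,
                 best_run = best$run, best_iteration = best$iteration,
                 trace = do.call(rbind, trace)),
            class = "coestimation_trace")
}

#' @export
print.coestimation_trace <- function(x, ...) {
  cat(sprintf(
    "co-estimation: %d sequences, %d x %d run/iterations\n",
    length(x$msa), max(x$trace$run), max(x$trace$iteration)))
  cat(sprintf("best score %.3f at run %d, iteration %d; %d columns\n",
              x$score, x$best_run, x$best_iteration, msa_ncol(x$msa)))
  invisible(x)
}
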