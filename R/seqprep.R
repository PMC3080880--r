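#' Needle-style global pairwise similarity
#'
#' Computes one optimal end-to-end alignment of the two sequences under
#' affine gap penalties ([pairwise_align()]) and returns the number of
#' identical aligned residue pairs divided by the alignment length, gaps
#' included. Ambiguity codes count as matching only when the two aligned
#' characters are the identical literal symbol. The two sequences are put in
#' a canonical order before the dynamic programme so that tie-breaking among
#' equally optimal alignments cannot make the similarity asymmetric:
#' `global_similarity(a, b) == global_similarity(b, a)` always.
#'
#' @param a,b unaligned DNA strings.
#' @param scoring an [align_scoring()] scheme.
#' @return similarity fraction in \[0, 1\].
#' @export
#' @examples
#' global_similarity("ACGTACGT", "ACGTACGT")  # 1
global_similarity <- function(a, b, scoring = align_scoring()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  al <- pairwise_align(a, b, scoring)
  ca <- strsplit(al$a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(al$b, "", fixed = TRUE)[[1L]]
  sum(ca == cb & ca != "-") / length(ca)
}

#' Pairwise similarity matrix
#'
#' @param records named character vector of unaligned sequences.
#' @inheritParams global_similarity
#' @return symmetric matrix of [global_similarity()] values, unit diagonal.
#' @export
similarity_matrix <- function(records, scoring = align_scoring()) {
  check_ids(records)
  n <- length(records)
  S <- matrix(1, n, n, dimnames = list(names(records), names(records)))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        S[i, j] <- S[j, i] <- global_similarity(records[[i]], records[[j]],
                                                scoring)
      }
    }
  }
  S
}

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Orientation correction against a reference pool
#'
#' For each record, counts k-mers shared with the pooled reference k-mer set
#' for the sequence and for its reverse complement, and keeps whichever
#' orientation shares more. Records whose two counts are equal (including
#' both zero) are flagged unresolved and left untouched.
#'
#' @param records named character vector of unaligned sequences.
#' @param references named character vector of trusted-orientation sequences.
#' @param k word size for the vote.
#' @return list with `records` (corrected), `flipped` (ids reverse
#'   complemented) and `unresolved` (ids with a tied vote).
#' @export
orient <- function(records, references, k = 8L) {
  check_ids(records)
  if (length(references) == 0L) {
    stop("reference pool must be non-empty", call. = FALSE)
  }
  pool <- unique(unlist(lapply(references, seq_kmers, k = k)))
  flipped <- character(0)
  unresolved <- character(0)
  for (id in names(records)) {
    fwd <- sum(seq_kmers(records[[id]], k) %in% pool)
    rc <- revcomp(records[[id]])
    rev <- sum(seq_kmers(rc, k) %in% pool)
    if (rev > fwd) {
      records[[id]] <- rc
      flipped <- c(flipped, id)
    } else if (rev == fwd) {
      unresolved <- c(unresolved, id)
    }
  }
  list(records = records, flipped = flipped, unresolved = unresolved)
}

#' Exclusion filters for mined ITS records
#'
#' Excludes records strictly shorter than `min_length` (reason `too_short`)
#' and, when `require_its2` is set, records whose region annotation lacks an
#' ITS2 interval (reason `missing_its2`). Order-preserving.
#'
#' @param records named character vector of unaligned sequences.
#' @param regions region annotation data.frame (see [read_regions()]); only
#'   consulted when `require_its2 = TRUE`.
#' @param min_length minimum length in nt (kept if `length >= min_length`).
#' @param require_its2 drop records without an annotated ITS2 subregion?
#' @return a `filter_report`: list with `kept` (ids) and `excluded`
#'   (data.frame of id, reason).
#' @export
filter_records <- function(records, regions = NULL, min_length = 200L,
                           require_its2 = FALSE) {
  check_ids(records)
  reasons <- character(0)
  ids <- character(0)
  for (id in names(records)) {
    if (nchar(records[[id]]) < min_length) {
      ids <- c(ids, id); reasons <- c(reasons, "too_short")
    } else if (require_its2) {
      rmap <- if (is.null(regions)) NULL else region_map(regions, id)
      if (is.null(rmap) || !("ITS2" %in% names(rmap))) {
        ids <- c(ids, id); reasons <- c(reasons, "missing_its2")
      }
    }
  }
  structure(list(kept = setdiff(names(records), ids),
                 excluded = data.frame(id = ids, reason = reasons,
                                       stringsAsFactors = FALSE)),
            class = "filter_report")
}
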