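DEFAULT_ANCHOR_LENGTH <- 16L

# The anchored procedure needs only constancy across taxa, but the motif
# must also be aperiodic: a periodic anchor (e.g. repeated ACGT) still
# matches itself well under small shifts, letting the aligner slide the
# block in some rows. This 16-mer has at most 3 matching characters under
# any nonzero self-shift; longer anchors repeat it.
ANCHOR_MOTIF <- "CTAGTCGATCTCAGGC"

make_anchor <- function(length = DEFAULT_ANCHOR_LENGTH) {
  paste(rep(strsplit(ANCHOR_MOTIF, "")[[1]], length.out = length),
        collapse = "")
}

#' Split a sequence into ITS1, 5.8S, ITS2 and fringes
#'
#' Slices the ungapped residues by the record's region annotation (0-based
#' half-open intervals). Residues outside the three regions are returned as
#' leading/trailing fringes (18S/28S remnants, discarded before alignment).
#'
#' @param residues ungapped DNA string.
#' @param rmap region map for this record: named list of `c(start, end)`
#'   with names among `ITS1`, `5.8S`, `ITS2` (see [read_regions()] /
#'   `region_map`).
#' @return list with `its1`, `r58s`, `its2`, `fringe_left`, `fringe_right`.
#' @export
split_regions <- function(residues, rmap) {
  if (is.null(rmap) || !all(c("ITS1", "5.8S", "ITS2") %in% names(rmap))) {
    stop("record lacks a complete region map", call. = FALSE)
  }
  iv1 <- rmap[["ITS1"]]; iv5 <- rmap[["5.8S"]]; iv2 <- rmap[["ITS2"]]
  n <- nchar(residues)
  if (iv1[1] > iv1[2] || iv1[2] != iv5[1] || iv5[1] > iv5[2] ||
      iv5[2] != iv2[1] || iv2[1] > iv2[2] || iv1[1] < 0 || iv2[2] > n) {
    stop("region intervals must be contiguous, ordered ITS1 < 5.8S < ITS2 ",
         "and within sequence bounds", call. = FALSE)
  }
  list(its1 = substr(residues, iv1[1] + 1L, iv1[2]),
       r58s = substr(residues, iv5[1] + 1L, iv5[2]),
       its2 = substr(residues, iv2[1] + 1L, iv2[2]),
       fringe_left = substr(residues, 1L, iv1[1]),
       fringe_right = if (iv2[2] < n) substr(residues, iv2[2] + 1L, n) else "")
}

#' Replace the 5.8S region by a constant anchor
#'
#' Builds the anchored data set of the anchored-alignment strategy: every
#' record becomes `ITS1 + anchor + ITS2` with one constant anchor string
#' (16 characters by default) standing in for the excised 5.8S, which is
#' stored per id for later re-insertion. Records lacking a usable ITS1,
#' 5.8S or ITS2 are excluded with a per-record reason rather than failing
#' globally. Fringe residues are dropped.
#'
#' @param records named character vector of ungapped sequences.
#' @param regions region annotation data.frame.
#' @param anchor_length length of the constant anchor.
#' @param anchor optional explicit anchor string (overrides `anchor_length`).
#' @return list of class `anchored_set` with `anchored_records`, `excised`
#'   (named vector of 5.8S substrings), `anchor`, `excluded` (data.frame of
#'   id, reason) and `provenance` (original region coordinates).
#' @export
make_anchored <- function(records, regions,
                          anchor_length = DEFAULT_ANCHOR_LENGTH,
                          anchor = NULL) {
  check_ids(records)
  if (is.null(anchor)) anchor <- make_anchor(anchor_length)
  anchored <- character(0)
  excised <- character(0)
  ex_id <- character(0); ex_reason <- character(0)
  prov <- list()
  for (id in names(records)) {
    rmap <- region_map(regions, id)
    missing <- setdiff(c("ITS1", "5.8S", "ITS2"), names(rmap))
    if (length(missing)) {
      ex_id <- c(ex_id, id)
      ex_reason <- c(ex_reason,
                     paste0("missing_",
                            tolower(gsub(".", "", missing[1L], fixed = TRUE))))
      next
    }
    parts <- split_regions(records[[id]], rmap)
    if (!nzchar(parts$its1)) {
      ex_id <- c(ex_id, id); ex_reason <- c(ex_reason, "missing_its1")
      next
    }
    if (!nzchar(parts$its2)) {
      ex_id <- c(ex_id, id); ex_reason <- c(ex_reason, "missing_its2")
      next
    }
    anchored[id] <- paste0(parts$its1, anchor, parts$its2)
    excised[id] <- parts$r58s
    prov[[id]] <- rmap
  }
  structure(list(anchored_records = anchored, excised = excised,
                 anchor = anchor,
                 excluded = data.frame(id = ex_id, reason = ex_reason,
                                       stringsAsFactors = FALSE),
                 provenance = prov),
            class = "anchored_set")
}

#' Reassemble a record from its anchored parts
#'
#' @param aset an `anchored_set`.
#' @param id record id.
#' @return the original ungapped `ITS1 + 5.8S + ITS2` residues.
#' @export
reassemble <- function(aset, id) {
  s <- aset$anchored_records[[id]]
  pos <- regexpr(aset$anchor, s, fixed = TRUE)
  if (pos < 0) stop("anchor not found in record", call. = FALSE)
  paste0(substr(s, 1L, pos - 1L), aset$excised[[id]],
         substr(s, pos + nchar(aset$anchor), nchar(s)))
}

# align a set of sequences with the package's progressive aligner, deriving
# a k-mer guide tree when none is supplied; handles n = 1, 2 directly
align_records <- function(records, scoring = align_scoring(), guide = NULL) {
  n <- length(records)
  if (n == 1L) return(records)
  if (n == 2L) {
    al <- pairwise_align(records[[1L]], records[[2L]], scoring)
    return(setNames(c(al$a, al$b), names(records)))
  }
  if (is.null(guide)) guide <- nj_tree(kmer_distance_matrix(records))
  progressive_align(records, guide, scoring)
}

# locate the contiguous anchor block: columns at which every row carries the
# anchor exactly (constant and gap-free); error if the aligner corrupted it
find_anchor_block <- function(msa, anchor) {
  alen <- nchar(anchor)
  first <- msa[[1L]]
  starts <- integer(0)
  p <- 1L
  repeat {
    hit <- regexpr(anchor, substr(first, p, nchar(first)), fixed = TRUE)
    if (hit < 0) break
    starts <- c(starts, p + hit - 1L)
    p <- p + hit
  }
  for (s in starts) {
    if (all(substr(msa, s, s + alen - 1L) == anchor)) return(s)
  }
  stop("anchor block is not identical and contiguous across all rows; ",
       "the aligner corrupted the anchor", call. = FALSE)
}

# Canonicalize score-equivalent gap slides around the anchor. Because the
# anchor's boundary characters can equal the first/last characters of the
# flanks, equally optimal alignments exist that slide single anchor residues
# across adjacent gap runs; the tie-break sometimes picks a variant in which
# the anchor block is not contiguous in some row. Moving a residue across
# gaps only (never across another residue) does not change any aligned pair,
# so the alignment is rewritten with every row's anchor at the modal block.
# Genuine corruption (anchor residues interleaved with flank residues at the
# block) still errors.
normalize_anchor_block <- function(msa, anchor) {
  as_msa(msa)
  alen <- nchar(anchor)
  mat <- seq_matrix(msa)
  n <- nrow(mat)
  res_cols <- apply(mat != "-", 1L, which, simplify = FALSE)
  starts <- integer(n)       # anchor start as residue ordinal, per row
  for (i in seq_len(n)) {
    o <- regexpr(anchor, paste(mat[i, res_cols[[i]]], collapse = ""),
                 fixed = TRUE)
    if (o < 0) {
      stop("anchor not found in row ", rownames(mat)[i], call. = FALSE)
    }
    starts[i] <- o
  }
  anchor_cols <- lapply(seq_len(n), function(i)
    res_cols[[i]][starts[i]:(starts[i] + alen - 1L)])
  # modal start column among rows whose block is already contiguous
  contig <- vapply(anchor_cols, function(cc)
    cc[alen] - cc[1L] == alen - 1L, logical(1))
  if (!any(contig)) {
    stop("anchor block is not identical and contiguous across all rows; ",
         "the aligner corrupted the anchor", call. = FALSE)
  }
  first <- vapply(anchor_cols, `[`, integer(1), 1L)
  S <- as.integer(names(sort(table(first[contig]), decreasing = TRUE))[1L])
  target <- S:(S + alen - 1L)
  for (i in seq_len(n)) {
    if (contig[i] && first[i] == S) next
    its1 <- res_cols[[i]][seq_len(starts[i] - 1L)]
    its2 <- res_cols[[i]][-seq_len(starts[i] + alen - 1L)]
    if ((length(its1) && max(its1) >= S) ||
        (length(its2) && min(its2) <= S + alen - 1L)) {
      stop("anchor block is not identical and contiguous across all rows; ",
           "the aligner corrupted the anchor", call. = FALSE)
    }
    mat[i, anchor_cols[[i]]] <- "-"
    mat[i, target] <- strsplit(anchor, "")[[1L]]
  }
  keep <- colSums(mat != "-") > 0L
  out <- collapse_rows(mat[, keep, drop = FALSE])
  out[names(msa)]
}

#' Does an alignment preserve the constant anchor block?
#'
#' `TRUE` iff the anchor forms one identical, contiguous, gap-free column
#' block in every row, up to canonicalization of score-equivalent gap slides
#' (single anchor residues moved across adjacent gap runs, which changes no
#' aligned pair). The anchored co-estimation strategy uses this as its
#' acceptance rule: an alignment that genuinely broke the anchor has failed
#' the anchor's purpose of keeping ITS1 and ITS2 registered.
#'
#' @param msa alignment of anchored records.
#' @param anchor the constant anchor string.
#' @return logical scalar.
#' @export
anchor_intact <- function(msa, anchor = make_anchor()) {
  !inherits(tryCatch(normalize_anchor_block(msa, anchor),
                     error = function(e) e), "error")
}

#' Re-insert excised 5.8S regions into an anchored alignment
#'
#' The excised 5.8S substrings are aligned among themselves (they are
#' conserved, so a single progressive pass suffices), then the constant
#' anchor columns are replaced by the aligned 5.8S block at the same
#' position. The result degaps to the original full-length residues.
#'
#' @param anchored_msa alignment of anchored records; the anchor must form a
#'   contiguous identical block in every row (verified, after canonicalizing
#'   score-equivalent gap slides at the block edges).
#' @param excised named vector of 5.8S substrings from [make_anchored()].
#' @param anchor the constant anchor string used.
#' @param scoring an [align_scoring()] scheme for the 5.8S block.
#' @param guide optional guide tree for aligning the 5.8S block.
#' @return the combined alignment (named character vector).
#' @export
reinsert_58s <- function(anchored_msa, excised,
                         anchor = make_anchor(), scoring = align_scoring(),
                         guide = NULL) {
  as_msa(anchored_msa)
  if (!setequal(names(anchored_msa), names(excised))) {
    stop("excised 5.8S set must match alignment rows", call. = FALSE)
  }
  anchored_msa <- normalize_anchor_block(anchored_msa, anchor)
  pos <- find_anchor_block(anchored_msa, anchor)
  block <- align_records(excised[names(anchored_msa)], scoring, guide)
  alen <- nchar(anchor)
  width <- msa_ncol(anchored_msa)
  out <- paste0(substr(anchored_msa, 1L, pos - 1L),
                block,
                substr(anchored_msa, pos + alen, width))
  out <- setNames(out, names(anchored_msa))
  as_msa(out)
  out
}
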