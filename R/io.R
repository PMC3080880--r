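#' Read and write FASTA sequence sets
#'
#' Sequences are handled throughout the package as named character vectors of
#' uppercase IUPAC DNA strings; alignments additionally use `-` as the gap
#' character and have equal-length rows.
#'
#' @param path file path.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  x <- toupper(vapply(as.character(dna), paste, character(1), collapse = ""))
  names(x) <- names(dna)
  check_ids(x)
  x
}

#' @param x named character vector of sequences (gapped or ungapped).
#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  check_ids(x)
  lines <- character(2L * length(x))
  lines[c(TRUE, FALSE)] <- paste0(">", names(x))
  lines[c(FALSE, TRUE)] <- unname(x)
  writeLines(lines, path)
  invisible(path)
}

#' Validate a multiple sequence alignment
#'
#' An MSA is a named character vector of equal-length gapped strings over
#' IUPAC DNA codes plus `-`. Rows that are entirely gaps are rejected.
#'
#' @param x named character vector.
#' @return `x`, invisibly, after validation.
#' @export
as_msa <- function(x) {
  check_ids(x)
  if (length(unique(nchar(x))) != 1L) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  if (any(gsub("-", "", x, fixed = TRUE) == "")) {
    stop("alignment contains an all-gap row", call. = FALSE)
  }
  invisible(x)
}

#' Number of columns of an alignment
#' @param msa named character vector alignment.
#' @export
msa_ncol <- function(msa) nchar(msa[[1L]])

#' Remove gap characters from alignment rows
#' @param x character vector of gapped strings.
#' @export
degap <- function(x) {
  out <- gsub("-", "", x, fixed = TRUE)
  names(out) <- names(x)
  out
}

#' Read and write ITS region annotations
#'
#' Region tables have columns `id`, `region` (one of `ITS1`, `5.8S`, `ITS2`),
#' `start`, `end`; coordinates are 0-based half-open on the ungapped
#' residues of the named sequence.
#'
#' @param path file path of a tab-separated table.
#' @return a data.frame with the four columns above.
#' @export
read_regions <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "integer",
                                  "integer"))
  validate_regions(df)
  df
}

#' @param regions region data.frame as above.
#' @rdname read_regions
#' @export
write_regions <- function(regions, path) {
  validate_regions(regions)
  write.table(regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_regions <- function(df) {
  need <- c("id", "region", "start", "end")
  if (!all(need %in% names(df))) {
    stop("regions table must have columns id, region, start, end",
         call. = FALSE)
  }
  ok <- df$region %in% c("ITS1", "5.8S", "ITS2")
  if (!all(ok)) stop("unknown region name in regions table", call. = FALSE)
  if (any(df$end < df$start) || any(df$start < 0)) {
    stop("invalid region interval", call. = FALSE)
  }
  invisible(df)
}

# per-id list of region intervals: list(ITS1 = c(start, end), ...)
region_map <- function(regions, id) {
  rows <- regions[regions$id == id, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  m <- lapply(seq_len(nrow(rows)), function(i) c(rows$start[i], rows$end[i]))
  names(m) <- rows$region
  m
}

#' Read and write group label tables
#'
#' Two tab-separated columns, `id` and `group`. The reserved group value
#' `"environmental"` marks unlabeled query sequences.
#'
#' @param path file path.
#' @return named character vector of group labels (names are ids).
#' @export
read_groups <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character"))
  setNames(df$group, df$id)
}

#' @param groups named character vector of labels.
#' @rdname read_groups
#' @export
write_groups <- function(groups, path) {
  write.table(data.frame(id = names(groups), group = unname(groups)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
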