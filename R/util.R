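#' @noRd
IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-")

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented to their counterparts; gap
#' characters are preserved.
#'
#' @param x character vector of uppercase IUPAC DNA strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  out <- vapply(x, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    comp <- COMPLEMENT[ch]
    if (anyNA(comp)) stop("non-IUPAC character in sequence", call. = FALSE)
    paste(rev(comp), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  names(out) <- names(x)
  out
}

# round half away from zero, as printed percentages conventionally are
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# split equal-length strings into a character matrix (rows = sequences)
seq_matrix <- function(x) {
  stopifnot(length(x) >= 1L)
  n <- nchar(x)
  if (length(unique(n)) != 1L) stop("strings differ in length", call. = FALSE)
  m <- matrix("", nrow = length(x), ncol = n[1])
  sp <- strsplit(x, "", fixed = TRUE)
  for (i in seq_along(sp)) m[i, ] <- sp[[i]]
  rownames(m) <- names(x)
  m
}

collapse_rows <- function(m) {
  setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_DNA, collapse = "")), x)
  if (any(bad)) {
    stop(sprintf("%s contains non-IUPAC characters: %s", what,
                 paste(head(names(x)[bad], 3L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

check_ids <- function(x) {
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "") ||
      anyDuplicated(names(x))) {
    stop("sequences must carry unique non-empty names", call. = FALSE)
  }
  invisible(x)
}
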