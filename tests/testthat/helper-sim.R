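# canonical bipartition key as used by the package: the side not containing
# the smallest leaf id, sorted, comma-joined
bipart_key_for <- function(side, all_tips) {
  if (min(all_tips) %in% side) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = ",")
}

# region rows of the annotation table for one id (test-side convenience)
region_rows <- function(regions, id) {
  regions[regions$id == id, , drop = FALSE]
}

# mean pairwise column identity per region block of a simulation's true
# alignment: fraction of comparable (both-residue) positions that agree,
# averaged over all leaf pairs
region_identity <- function(sim) {
  m <- do.call(rbind, strsplit(unname(sim$true_alignment), ""))
  out <- c()
  for (region in c("ITS1", "5.8S", "ITS2")) {
    cols <- sim$alignment_regions == region
    sub <- m[, cols, drop = FALSE]
    n <- nrow(sub)
    same <- 0; comp <- 0
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        both <- sub[a, ] != "-" & sub[b, ] != "-"
        comp <- comp + sum(both)
        same <- same + sum(sub[a, both] == sub[b, both])
      }
    }
    out[region] <- same / comp
  }
  out
}
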