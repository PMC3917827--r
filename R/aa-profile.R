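# Amino-acid profiles of protein-coding (mitochondrial) alignments:
# per-sequence translation under the vertebrate mitochondrial code, the list
# of segregating (non-synonymous) codon positions, and the count of positions
# whose amino-acid sets are disjoint between two groups.

#' Amino-acid profile of a coding alignment
#'
#' Translates every sequence under the vertebrate mitochondrial genetic code
#' from the given reading frame, lists the codon positions at which more than
#' one amino acid segregates, and (given a two-group partition) counts the
#' positions that are diagnostic, i.e. where the amino-acid sets of the two
#' groups are disjoint. Codons containing gaps or Ns translate to \code{X}
#' and are ignored at that position; internal stop codons raise a warning
#' with their position.
#'
#' @param aln a \linkS4class{LocusAlignment}; the full (unmasked) sequences
#'   are translated so the reading frame is preserved.
#' @param partition a \linkS4class{PopPartition} with exactly two
#'   populations/groups.
#' @param frame reading-frame offset: 1, 2 or 3 (first codon starts at this
#'   column). Trailing incomplete codons are dropped.
#' @return list of class \code{"aaProfile"} with \code{segregating} (a
#'   data.frame: codon position, amino acids present, per-group amino-acid
#'   sets), \code{nSegregating} and \code{nDiagnostic}.
#' @export
aaProfile <- function(aln, partition, frame = 1) {
  check_aln(aln)
  stopifnot(frame %in% 1:3)
  idx <- resolve_two_pops(aln, partition)
  mat <- alignment_matrix_raw(aln@seqs)
  L <- ncol(mat)
  usable <- L - (frame - 1)
  ncodon <- usable %/% 3L
  if (ncodon < 1L) stop("no complete codon in the chosen frame")
  code <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
  aas <- matrix(NA_character_, nrow(mat), ncodon)
  for (cd in seq_len(ncodon)) {
    cols <- (frame - 1) + (cd - 1L) * 3L + 1:3
    tri <- apply(mat[, cols, drop = FALSE], 1L, paste0, collapse = "")
    aa <- unname(code[tri])
    aa[is.na(aa)] <- "X"   # gap- or N-containing codon
    aas[, cd] <- aa
  }
  stops <- which(aas == "*", arr.ind = TRUE)
  stops <- stops[stops[, 2L] < ncodon, , drop = FALSE]
  if (nrow(stops))
    warning("internal stop codon(s) at codon position(s): ",
            paste(sort(unique(stops[, 2L])), collapse = ", "))
  seg <- integer(0)
  rows <- list()
  for (cd in seq_len(ncodon)) {
    aa <- aas[, cd]
    ok <- aa != "X"
    if (length(unique(aa[ok])) >= 2L) {
      seg <- c(seg, cd)
      set1 <- sort(unique(aa[idx$i1][aa[idx$i1] != "X"]))
      set2 <- sort(unique(aa[idx$i2][aa[idx$i2] != "X"]))
      rows[[length(rows) + 1L]] <- data.frame(
        codon = cd,
        amino_acids = paste(sort(unique(aa[ok])), collapse = "/"),
        group1 = paste(set1, collapse = "/"),
        group2 = paste(set2, collapse = "/"),
        diagnostic = length(set1) > 0 && length(set2) > 0 &&
          !length(intersect(set1, set2)),
        stringsAsFactors = FALSE)
    }
  }
  segdf <- if (length(rows)) do.call(rbind, rows) else
    data.frame(codon = integer(0), amino_acids = character(0),
               group1 = character(0), group2 = character(0),
               diagnostic = logical(0))
  structure(list(segregating = segdf,
                 nSegregating = nrow(segdf),
                 nDiagnostic = sum(segdf$diagnostic)),
            class = "aaProfile")
}

#' @export
print.aaProfile <- function(x, ...) {
  cat("Amino-acid profile:", x$nSegregating,
      "segregating codon position(s),", x$nDiagnostic,
      "diagnostic between groups\n")
  if (x$nSegregating) print(x$segregating, row.names = FALSE)
  invisible(x)
}
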