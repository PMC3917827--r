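# FASTA / sample-sheet IO for the sequence statistics.

#' Read a locus alignment from FASTA
#'
#' Sequences are uppercased; lengths must agree and ids must be unique.
#' The analyzed-site mask is built according to \code{sitePolicy} (default
#' complete deletion: any column containing '-' or 'N' is excluded).
#'
#' @param path FASTA file.
#' @param name locus name (default: file name without extension).
#' @param sitePolicy \code{"complete"} or \code{"pairwise"}.
#' @return a \linkS4class{LocusAlignment}.
#' @export
readLocusAlignment <- function(path, name = NULL,
                               sitePolicy = c("complete", "pairwise")) {
  sitePolicy <- match.arg(sitePolicy)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in ", path)
  if (is.null(name))
    name <- sub("\\.(fa|fasta|fna)$", "", basename(path), ignore.case = TRUE)
  LocusAlignment(Biostrings::DNAStringSet(toupper(as.character(seqs))),
                 name = name, sitePolicy = sitePolicy)
}

#' Write a locus alignment to FASTA (60-column wrap)
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeLocusAlignment <- function(aln, path) {
  stopifnot(is(aln, "LocusAlignment"))
  Biostrings::writeXStringSet(aln@seqs, path, width = 60L)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated file with header \code{individual}, \code{population},
#' \code{group}, \code{sex}.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readSampleSheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("individual", "population", "group", "sex")
  if (!all(needed %in% names(sheet)))
    stop("sample sheet needs columns: ", paste(needed, collapse = ", "))
  if (anyDuplicated(sheet$individual)) stop("duplicate individuals in sheet")
  sheet
}

#' Build a PopPartition for an alignment from a sample sheet
#'
#' Sequence ids are expected to be \code{<individual>} or
#' \code{<individual>_<allele>} (phased allele copies). Each sequence is
#' mapped to its individual's population, and populations to groups.
#'
#' @param aln a \linkS4class{LocusAlignment} (or character vector of ids).
#' @param sheet sample sheet data.frame.
#' @param level \code{"population"} (default) or \code{"group"}: which sheet
#'   column becomes the partition's population level. Using \code{"group"}
#'   gives the two-subspecies partition directly.
#' @return a \linkS4class{PopPartition}.
#' @export
partitionFromSheet <- function(aln, sheet, level = c("population", "group")) {
  level <- match.arg(level)
  ids <- if (is.character(aln)) aln else names(alignedSequences(aln))
  ind <- sub("_[0-9]+$", "", ids)
  hit <- match(ind, sheet$individual)
  if (anyNA(hit))
    stop("sequences without a sample-sheet entry: ",
         paste(ids[is.na(hit)], collapse = ", "))
  if (level == "population") {
    PopPartition(stats::setNames(sheet$population[hit], ids),
                 popGroup = stats::setNames(
                   sheet$group[match(unique(sheet$population),
                                     sheet$population)],
                   unique(sheet$population)))
  } else {
    PopPartition(stats::setNames(sheet$group[hit], ids))
  }
}
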