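# Accessors and show methods for the S4 classes.

#' Construct a LocusAlignment
#'
#' @param seqs a named \link[Biostrings]{DNAStringSet} (or named character
#'   vector of equal-length DNA strings).
#' @param name locus name.
#' @param sitePolicy \code{"complete"} (drop every column containing '-' or
#'   'N' from the analysis; default) or \code{"pairwise"}.
#' @return a \linkS4class{LocusAlignment}.
#' @examples
#' aln <- LocusAlignment(c(a = "ACGT", b = "ACGA"), name = "toy")
#' segregatingSites(aln)
#' @export
LocusAlignment <- function(seqs, name = "locus",
                           sitePolicy = c("complete", "pairwise")) {
  sitePolicy <- match.arg(sitePolicy)
  if (is.character(seqs)) {
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  } else if (!is(seqs, "DNAStringSet")) {
    stop("'seqs' must be a DNAStringSet or character vector")
  }
  if (length(seqs) == 0L) stop("empty alignment")
  mat <- alignment_matrix_raw(seqs)
  mask <- if (sitePolicy == "complete") {
    apply(mat, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  } else {
    # pairwise deletion keeps every column with at least one called base
    apply(mat, 2L, function(col) any(col %in% c("A", "C", "G", "T")))
  }
  new("LocusAlignment", name = as.character(name), seqs = seqs,
      analyzedSites = as.logical(mask), sitePolicy = sitePolicy)
}

# character matrix (sequences x columns) from a DNAStringSet
alignment_matrix_raw <- function(seqs) {
  w <- unique(Biostrings::width(seqs))
  if (length(w) != 1L) stop("ragged alignment: sequences differ in length")
  mat <- matrix(unlist(strsplit(toupper(as.character(seqs)), "")),
                nrow = length(seqs), byrow = TRUE)
  rownames(mat) <- names(seqs)
  mat
}

# analyzed-sites character matrix for a LocusAlignment
alignment_matrix <- function(aln) {
  alignment_matrix_raw(aln@seqs)[, aln@analyzedSites, drop = FALSE]
}

#' Construct a PopPartition
#'
#' @param seqPop named character vector mapping sequence id to population.
#' @param popGroup optional named character vector mapping population to
#'   group (the AMOVA top level).
#' @return a \linkS4class{PopPartition}.
#' @examples
#' part <- PopPartition(c(s1 = "p1", s2 = "p1", s3 = "p2", s4 = "p2"),
#'                      popGroup = c(p1 = "north", p2 = "south"))
#' populations(part)
#' @export
PopPartition <- function(seqPop, popGroup = character()) {
  sp <- stats::setNames(as.character(seqPop), names(seqPop))
  pg <- if (length(popGroup)) {
    stats::setNames(as.character(popGroup), names(popGroup))
  } else character()
  new("PopPartition", seqPop = sp, popGroup = pg)
}

#' @rdname accessors
#' @export
setMethod("locusName", "LocusAlignment", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("analyzedSites", "LocusAlignment", function(x) x@analyzedSites)

#' @rdname accessors
#' @export
setMethod("alignedSequences", "LocusAlignment", function(x) x@seqs)

#' @rdname accessors
#' @export
setMethod("populations", "PopPartition", function(x) x@seqPop)

#' @rdname accessors
#' @export
setMethod("groups", "PopPartition", function(x) x@popGroup)

#' @rdname accessors
#' @export
setMethod("pValue", "DiTestResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setMethod("pValue", "KstResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setMethod("pValue", "AmovaResult", function(x) x@pValues)

#' @rdname accessors
#' @export
setMethod("nullSample", "DiTestResult", function(x) x@nullSample)

setMethod("show", "LocusAlignment", function(object) {
  cat("LocusAlignment '", object@name, "': ", length(object@seqs),
      " sequences x ", Biostrings::width(object@seqs)[1L], " bp (",
      sum(object@analyzedSites), " analyzed sites, ", object@sitePolicy,
      " deletion)\n", sep = "")
})

setMethod("show", "PopPartition", function(object) {
  cat("PopPartition: ", length(object@seqPop), " sequences in ",
      length(unique(object@seqPop)), " populations", sep = "")
  if (length(object@popGroup))
    cat(" within", length(unique(object@popGroup)), "groups")
  cat("\n")
})

setMethod("show", "SimulatedLocus", function(object) {
  cat("SimulatedLocus: ", length(object@alignment), " haplotypes (",
      paste(table(object@demeLabels), collapse = " + "), "), ",
      object@mutationCount, " mutations, TMRCA ",
      signif(object@treeDepth, 4), "\n", sep = "")
})

setMethod("show", "DiTestResult", function(object) {
  cat("Di permutation test, axis ", object@axis, ": Di = ",
      signif(object@diObserved, 5), ", p = ", signif(object@pValue, 4),
      " (", object@nPermutations, " permutations, ", object@tail,
      ")\n", sep = "")
})

setMethod("show", "LocusStats", function(object) {
  cat("LocusStats '", object@name, "': n = ", object@n, ", L = ", object@L,
      ", S = ", object@S, ", Hd = ", signif(object@Hd, 4),
      ", theta/site = ", signif(object@thetaWSite, 4),
      " (SE ", signif(object@thetaWSE, 3), "), pi/site = ",
      signif(object@piSite, 4), ", Tajima's D = ",
      ifelse(is.na(object@tajimasD), "undefined",
             signif(object@tajimasD, 4)), "\n", sep = "")
})

setMethod("show", "KstResult", function(object) {
  cat("Kst = ", signif(object@kst, 4), " (Ks = ", signif(object@ks, 4),
      ", Kt = ", signif(object@kt, 4), "), p = ", signif(object@pValue, 4),
      " [", object@nPermutations, " permutations]\n", sep = "")
})

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA variance components:\n")
  comp <- cbind(component = object@components,
                percent = object@percentages)
  print(round(comp, 5))
  cat("F_CT = ", signif(object@fStatistics[["FCT"]], 4),
      " (p = ", signif(object@pValues[["FCT"]], 4), "), F_SC = ",
      signif(object@fStatistics[["FSC"]], 4),
      " (p = ", signif(object@pValues[["FSC"]], 4), "), F_ST = ",
      signif(object@fStatistics[["FST"]], 4),
      " (p = ", signif(object@pValues[["FST"]], 4), ")\n", sep = "")
})

#' Tabulate per-locus statistics
#'
#' Turn one or more \linkS4class{LocusStats} objects into a single
#' data.frame, one row per locus, with the diversity columns used by the
#' pipeline reports.
#'
#' @param x a \code{LocusStats} or list of them.
#' @return data.frame with columns \code{locus}, \code{n}, \code{sites},
#'   \code{S}, \code{Hd}, \code{theta_site}, \code{theta_se}, \code{pi_site},
#'   \code{tajimas_d}.
#' @export
locusStatsTable <- function(x) {
  if (is(x, "LocusStats")) x <- list(x)
  do.call(rbind, lapply(x, function(s) {
    data.frame(locus = s@name, n = s@n, sites = s@L, S = s@S, Hd = s@Hd,
               theta_site = s@thetaWSite, theta_se = s@thetaWSE,
               pi_site = s@piSite, tajimas_d = s@tajimasD,
               stringsAsFactors = FALSE)
  }))
}
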