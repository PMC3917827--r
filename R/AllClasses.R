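#' LocusAlignment: an aligned set of equal-length DNA sequences
#'
#' Container for one locus: the aligned sequences plus the mask of analyzed
#' sites. Under the default \code{"complete"} site policy every column that
#' contains a gap (\code{-}) or ambiguous base (\code{N}) is excluded from all
#' statistics, mirroring DnaSP's complete-deletion behaviour; \code{"pairwise"}
#' keeps all columns and lets pairwise comparisons skip missing data per pair.
#'
#' @slot name locus name.
#' @slot seqs a \link[Biostrings]{DNAStringSet}, all of equal width, with
#'   unique names (sequence/allele identifiers).
#' @slot analyzedSites logical vector, one element per alignment column;
#'   \code{TRUE} marks columns entering the statistics.
#' @slot sitePolicy \code{"complete"} or \code{"pairwise"}.
#' @exportClass LocusAlignment
setClass("LocusAlignment",
  slots = c(
    name = "character",
    seqs = "DNAStringSet",
    analyzedSites = "logical",
    sitePolicy = "character"
  )
)

setValidity("LocusAlignment", function(object) {
  w <- Biostrings::width(object@seqs)
  msg <- character()
  if (length(object@seqs) < 1L) msg <- c(msg, "alignment must contain sequences")
  if (length(unique(w)) > 1L)
    msg <- c(msg, "ragged alignment: sequences differ in length")
  ids <- names(object@seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "all sequences must be named")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    msg <- c(msg, paste0("duplicate sequence ids: ",
                         paste(dup, collapse = ", ")))
  }
  if (length(w) && length(object@analyzedSites) != w[1L])
    msg <- c(msg, "analyzedSites length must equal alignment width")
  if (!object@sitePolicy %in% c("complete", "pairwise"))
    msg <- c(msg, "sitePolicy must be 'complete' or 'pairwise'")
  if (length(msg)) msg else TRUE
})

#' PopPartition: sequence-to-population (and population-to-group) mapping
#'
#' Two-level hierarchical partition used by the divergence statistics:
#' sequences (phased alleles) belong to populations, and populations may be
#' nested within higher-level groups (e.g. subspecies) for AMOVA.
#'
#' @slot seqPop named character; names are sequence ids, values populations.
#' @slot popGroup named character (possibly empty); names are populations,
#'   values groups.
#' @exportClass PopPartition
setClass("PopPartition",
  slots = c(seqPop = "character", popGroup = "character")
)

setValidity("PopPartition", function(object) {
  msg <- character()
  if (is.null(names(object@seqPop)) || anyNA(names(object@seqPop)))
    msg <- c(msg, "seqPop must be a named character vector")
  if (anyDuplicated(names(object@seqPop)))
    msg <- c(msg, "duplicate sequence ids in partition")
  if (length(object@popGroup)) {
    pops <- unique(object@seqPop)
    missing <- setdiff(pops, names(object@popGroup))
    if (length(missing))
      msg <- c(msg, paste0("populations without a group: ",
                           paste(missing, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' SimulatedLocus: output of the isolation-with-migration simulator
#'
#' @slot alignment \link[Biostrings]{DNAStringSet} of simulated haplotypes.
#' @slot demeLabels character, one of \code{"deme1"}/\code{"deme2"} per
#'   sequence (sampling deme).
#' @slot mutationCount number of mutations placed on the genealogy; equals the
#'   number of segregating sites under the infinite-sites mapping.
#' @slot treeDepth time to the most recent common ancestor, coalescent units.
#' @exportClass SimulatedLocus
setClass("SimulatedLocus",
  slots = c(
    alignment = "DNAStringSet",
    demeLabels = "character",
    mutationCount = "integer",
    treeDepth = "numeric"
  )
)

#' DiTestResult: per-axis niche-divergence permutation test
#'
#' @slot axis principal-component axis tested.
#' @slot diObserved observed difference of group means on that axis
#'   (first group minus second).
#' @slot nullSample permutation null sample of Di.
#' @slot pValue permutation p-value under the declared tail policy.
#' @slot nPermutations number of label permutations.
#' @slot tail \code{"two.sided"} (on |Di|) or \code{"greater"} (literal
#'   one-sided count).
#' @slot plusOne logical; whether the (count+1)/(n+1) correction was used.
#' @slot seed seed used to draw the permutations (NA if none given).
#' @exportClass DiTestResult
setClass("DiTestResult",
  slots = c(
    axis = "integer",
    diObserved = "numeric",
    nullSample = "numeric",
    pValue = "numeric",
    nPermutations = "integer",
    tail = "character",
    plusOne = "logical",
    seed = "numeric"
  )
)

setValidity("DiTestResult", function(object) {
  msg <- character()
  if (length(object@nullSample) != object@nPermutations)
    msg <- c(msg, "null sample length must equal nPermutations")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' LocusStats: per-locus diversity summary
#'
#' @slot name locus (or locus/group) label.
#' @slot n number of alleles (sequences).
#' @slot L number of analyzed sites.
#' @slot S number of segregating sites.
#' @slot Hd haplotype diversity with the n/(n-1) correction.
#' @slot thetaWSite Watterson's theta per site.
#' @slot thetaWSE standard error of thetaWSite from
#'   Var(S) = a1*theta + a2*theta^2 (locus scale), divided by (a1*L)^2.
#' @slot piSite nucleotide diversity per site.
#' @slot tajimasD Tajima's D; \code{NA} when S = 0 (undefined).
#' @exportClass LocusStats
setClass("LocusStats",
  slots = c(
    name = "character", n = "integer", L = "integer", S = "integer",
    Hd = "numeric", thetaWSite = "numeric", thetaWSE = "numeric",
    piSite = "numeric", tajimasD = "numeric"
  )
)

#' KstResult: Hudson's Kst permutation test
#'
#' @slot ks weighted mean within-population pairwise difference count.
#' @slot kt mean pairwise difference count over the pooled sample.
#' @slot kst 1 - Ks/Kt (NA when Kt = 0).
#' @slot perPopulation named mean within-population pairwise differences.
#' @slot pValue permutation p-value, (count+1)/(n+1).
#' @slot nPermutations number of permutations of sequence labels.
#' @slot weighting \code{"size"} (n_j/n) or \code{"nj1"} ((n_j-1)-based).
#' @slot seed seed used (NA if none).
#' @exportClass KstResult
setClass("KstResult",
  slots = c(
    ks = "numeric", kt = "numeric", kst = "numeric",
    perPopulation = "numeric", pValue = "numeric",
    nPermutations = "integer", weighting = "character", seed = "numeric"
  )
)

#' AmovaResult: two-level analysis of molecular variance
#'
#' Variance components are estimated from expected mean squares with
#' unequal-sample-size coefficients; negative components are reported as
#' estimated (with a warning at fit time), not clamped.
#'
#' @slot components named numeric: \code{amongGroups}, \code{amongPopsWithin},
#'   \code{withinPops}.
#' @slot percentages components as percent of their sum.
#' @slot fStatistics named numeric: \code{FCT}, \code{FSC}, \code{FST}.
#' @slot pValues permutation p-values for the three F-statistics.
#' @slot ssd sums of squared deviations per stratum, plus total.
#' @slot df degrees of freedom per stratum.
#' @slot nPermutations permutations used per statistic.
#' @slot seed seed used (NA if none).
#' @exportClass AmovaResult
setClass("AmovaResult",
  slots = c(
    components = "numeric", percentages = "numeric",
    fStatistics = "numeric", pValues = "numeric",
    ssd = "numeric", df = "numeric",
    nPermutations = "integer", seed = "numeric"
  )
)
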