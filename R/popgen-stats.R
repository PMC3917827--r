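# Sequence diversity statistics: S, Hd, Watterson's theta (with SE),
# nucleotide diversity, Tajima's D. All operate on the analyzed-site mask of
# a LocusAlignment and use frequency-spectrum (per-column base count)
# computations rather than O(n^2 L) pairwise loops.

check_aln <- function(aln, minSeq = 2L) {
  stopifnot(is(aln, "LocusAlignment"))
  if (length(aln@seqs) < minSeq)
    stop("need at least ", minSeq, " sequences")
  invisible(aln)
}

# per-column counts of A, C, G, T over analyzed sites (4 x L matrix)
base_counts <- function(aln) {
  cm <- Biostrings::consensusMatrix(aln@seqs)[c("A", "C", "G", "T"), ,
                                              drop = FALSE]
  cm[, aln@analyzedSites, drop = FALSE]
}

#' Number of segregating sites
#'
#' Count of analyzed columns at which at least two distinct bases occur.
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @return integer S.
#' @export
segregatingSites <- function(aln) {
  check_aln(aln)
  cm <- base_counts(aln)
  sum(colSums(cm > 0) >= 2L)
}

#' Number of analyzed sites
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @return integer L.
#' @export
analyzedLength <- function(aln) sum(aln@analyzedSites)

#' Haplotype diversity
#'
#' Hd = n (1 - sum p_i^2) / (n - 1) over the distinct analyzed-site
#' haplotypes with sample frequencies p_i: the (bias-corrected) probability
#' that two randomly drawn alleles are different haplotypes.
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @return numeric in [0, 1].
#' @export
haplotypeDiversity <- function(aln) {
  check_aln(aln)
  mat <- alignment_matrix(aln)
  hap <- apply(mat, 1L, paste0, collapse = "")
  n <- length(hap)
  p <- as.numeric(table(hap)) / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Watterson's theta per site, with standard error
#'
#' theta_hat = S / (a1 * L) with a1 = sum_{i=1}^{n-1} 1/i. The standard
#' error comes from the neutral sampling variance of S,
#' Var(S) = a1 * theta_L + a2 * theta_L^2 (theta_L the locus-scale estimate,
#' a2 = sum 1/i^2), divided through by (a1 * L)^2.
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @return list with \code{theta} (per site), \code{se}, \code{S}, \code{L},
#'   \code{n}.
#' @export
wattersonTheta <- function(aln) {
  check_aln(aln)
  L <- analyzedLength(aln)
  if (L == 0L) stop("no analyzed sites (L = 0)")
  n <- length(aln@seqs)
  S <- segregatingSites(aln)
  a1 <- harmonic_a1(n)
  a2 <- harmonic_a2(n)
  thetaL <- S / a1
  se <- sqrt(a1 * thetaL + a2 * thetaL^2) / (a1 * L)
  list(theta = thetaL / L, se = se, S = S, L = L, n = n)
}

#' Nucleotide diversity per site
#'
#' Mean number of pairwise differences over all C(n,2) sequence pairs at
#' analyzed sites, divided by the number of analyzed sites. Computed from the
#' per-column base counts: pairwise differences at a column with counts n_b
#' equal C(n,2) - sum_b C(n_b,2).
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @return numeric pi per site.
#' @export
nucleotideDiversity <- function(aln) {
  check_aln(aln)
  L <- analyzedLength(aln)
  if (L == 0L) return(0)
  cm <- base_counts(aln)
  nv <- colSums(cm)                      # called bases per column
  pairs <- nv * (nv - 1) / 2             # = C(n,2) everywhere under
  same <- colSums(cm * (cm - 1) / 2)     #   complete deletion
  ok <- pairs > 0
  sum((pairs[ok] - same[ok]) / pairs[ok]) / L
}

#' Tajima's D
#'
#' D = (pi_locus - S/a1) / sqrt(e1 * S + e2 * S * (S - 1)) with Tajima's
#' (1989) constants: b1 = (n+1)/(3(n-1)), b2 = 2(n^2+n+3)/(9n(n-1)),
#' c1 = b1 - 1/a1, c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1,
#' e2 = c2/(a1^2 + a2). Undefined (returns \code{NA}) when S = 0.
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @return numeric D, or \code{NA_real_} when S = 0.
#' @export
tajimasD <- function(aln) {
  check_aln(aln, minSeq = 3L)
  n <- length(aln@seqs)
  S <- segregatingSites(aln)
  if (S == 0L) return(NA_real_)
  L <- analyzedLength(aln)
  piL <- nucleotideDiversity(aln) * L
  a1 <- harmonic_a1(n)
  a2 <- harmonic_a2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (piL - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Per-locus diversity summary
#'
#' Bundles n, L, S, Hd, Watterson's theta (with SE), pi and Tajima's D for
#' one alignment (optionally restricted to a subset of sequences, e.g. one
#' subspecies).
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @param ids optional sequence ids to restrict to.
#' @param name label for the summary (default the locus name).
#' @return a \linkS4class{LocusStats}.
#' @export
locusStats <- function(aln, ids = NULL, name = NULL) {
  check_aln(aln)
  if (!is.null(ids)) {
    miss <- setdiff(ids, names(aln@seqs))
    if (length(miss)) stop("unknown sequence ids: ",
                           paste(miss, collapse = ", "))
    aln <- LocusAlignment(aln@seqs[ids], name = aln@name,
                          sitePolicy = aln@sitePolicy)
  }
  if (is.null(name)) name <- aln@name
  th <- wattersonTheta(aln)
  D <- if (length(aln@seqs) >= 3L) tajimasD(aln) else NA_real_
  new("LocusStats", name = as.character(name),
      n = as.integer(th$n), L = as.integer(th$L), S = as.integer(th$S),
      Hd = haplotypeDiversity(aln), thetaWSite = th$theta,
      thetaWSE = th$se, piSite = nucleotideDiversity(aln), tajimasD = D)
}
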