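# Between-population divergence: pairwise difference matrices, Hudson's Kst
# with a sequence-label permutation test, fixed differences, Dxy, and the
# two-level AMOVA with its three permutation schemes.

#' Pairwise difference matrix
#'
#' Number of analyzed sites at which each pair of sequences differs
#' (both bases called).
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @return symmetric integer matrix with sequence ids as dimnames.
#' @export
pairwiseDifferences <- function(aln) {
  check_aln(aln)
  mat <- alignment_matrix(aln)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  called <- mat %in% c("A", "C", "G", "T")
  dim(called) <- dim(mat)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- called[i, ] & called[j, ]
      d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok])
    }
  }
  d
}

match_partition <- function(aln, partition) {
  ids <- names(aln@seqs)
  pops <- partition@seqPop[ids]
  if (anyNA(pops))
    stop("sequences not covered by the partition: ",
         paste(ids[is.na(pops)], collapse = ", "))
  pops
}

# mean within-population pairwise differences, per population, from a
# distance matrix and a population label vector
within_pop_means <- function(d, pops) {
  vapply(unique(pops), function(p) {
    idx <- which(pops == p)
    if (length(idx) < 2L) return(NA_real_)
    sub <- d[idx, idx]
    sum(sub[upper.tri(sub)]) / (length(idx) * (length(idx) - 1) / 2)
  }, numeric(1L))
}

kst_from_d <- function(d, pops, weighting) {
  nj <- table(pops)[unique(pops)]
  Kj <- within_pop_means(d, pops)
  w <- if (weighting == "size") as.numeric(nj) / sum(nj)
       else (as.numeric(nj) - 1) / sum(as.numeric(nj) - 1)
  ks <- sum(w * Kj)
  kt <- sum(d[upper.tri(d)]) / (nrow(d) * (nrow(d) - 1) / 2)
  list(ks = ks, kt = kt,
       kst = if (kt > 0) 1 - ks / kt else NA_real_, Kj = Kj)
}

#' Hudson's Kst test of population differentiation
#'
#' Kst = 1 - Ks/Kt, where Ks is the weighted mean within-population pairwise
#' difference count (weights n_j/n by default, (n_j-1)-based via
#' \code{weighting = "nj1"}) and Kt the mean over the pooled sample.
#' Significance is assessed by permuting sequence-to-population assignments;
#' the reported p-value is (count + 1)/(nPermutations + 1), counting permuted
#' Kst values at least as large as the observed one.
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @param partition a \linkS4class{PopPartition} covering the sequences
#'   (its population level is used; pass a group-level partition for a
#'   two-subspecies test).
#' @param nPermutations number of label permutations (default 999).
#' @param seed optional integer seed.
#' @param weighting \code{"size"} (default) or \code{"nj1"}.
#' @return a \linkS4class{KstResult}.
#' @export
kstTest <- function(aln, partition, nPermutations = 999, seed = NULL,
                    weighting = c("size", "nj1")) {
  weighting <- match.arg(weighting)
  nPermutations <- stop_if_not_scalar_count(nPermutations, "nPermutations")
  pops <- match_partition(aln, partition)
  if (length(unique(pops)) < 2L) stop("need at least 2 populations")
  if (any(table(pops) < 2L)) stop("each population needs >= 2 sequences")
  d <- pairwiseDifferences(aln)
  obs <- kst_from_d(d, pops, weighting)
  perm <- with_seed(seed, vapply(seq_len(nPermutations), function(i) {
    kst_from_d(d, sample(pops), weighting)$kst
  }, numeric(1L)))
  count <- sum(perm >= obs$kst, na.rm = TRUE)
  new("KstResult", ks = obs$ks, kt = obs$kt,
      kst = obs$kst, perPopulation = obs$Kj,
      pValue = (count + 1) / (nPermutations + 1),
      nPermutations = as.integer(nPermutations), weighting = weighting,
      seed = if (is.null(seed)) NA_real_ else seed)
}

resolve_two_pops <- function(aln, partition) {
  pops <- match_partition(aln, partition)
  u <- unique(pops)
  if (length(u) != 2L) stop("exactly two populations required")
  i1 <- which(pops == u[1L]); i2 <- which(pops == u[2L])
  if (!length(i1) || !length(i2)) stop("a population is empty")
  list(i1 = i1, i2 = i2, labels = u)
}

#' Fixed differences between two populations
#'
#' Number of analyzed sites at which the sets of bases observed in the two
#' populations are disjoint (no shared allele).
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @param partition a \linkS4class{PopPartition} with exactly two
#'   populations.
#' @return integer count.
#' @export
fixedDifferences <- function(aln, partition) {
  idx <- resolve_two_pops(aln, partition)
  mat <- alignment_matrix(aln)
  bases <- c("A", "C", "G", "T")
  count_mat <- function(rows) {
    m <- mat[rows, , drop = FALSE]
    vapply(bases, function(b) colSums(m == b), numeric(ncol(mat)))
  }
  c1 <- count_mat(idx$i1) > 0
  c2 <- count_mat(idx$i2) > 0
  sum(rowSums(c1 & c2) == 0 & rowSums(c1) > 0 & rowSums(c2) > 0)
}

#' Percent sequence divergence between two populations (Dxy)
#'
#' Average pairwise difference count between one sequence from each
#' population, divided by the number of analyzed sites, times 100. With
#' \code{net = TRUE} the mean within-population diversity
#' (pi_1 + pi_2)/2 is subtracted first (net divergence, Da).
#'
#' @inheritParams fixedDifferences
#' @param net subtract mean within-population diversity (default FALSE).
#' @return percent divergence.
#' @export
percentDivergence <- function(aln, partition, net = FALSE) {
  idx <- resolve_two_pops(aln, partition)
  d <- pairwiseDifferences(aln)
  L <- analyzedLength(aln)
  dxy <- mean(d[idx$i1, idx$i2, drop = FALSE]) / L
  if (net) {
    wm <- within_pop_means(d, ifelse(seq_len(nrow(d)) %in% idx$i1,
                                     "p1", "p2"))
    wm[is.na(wm)] <- 0
    dxy <- dxy - mean(wm) / L
  }
  100 * dxy
}

# P x P matrix of pairwise-distance sums between populations:
# pp[p, q] = sum_{i in p, j in q} d2[i, j] (full, both orientations; the
# within-population pair sum is diag(pp)/2).
pop_pair_sums <- function(d2, popf) {
  rowsum(t(rowsum(d2, popf)), popf)
}

# AMOVA pieces from the population-pair sums: pp (ordered as n_p),
# n_p population sizes, grp_of_pop group label per population. The
# sequence-level data enter only through pp, which makes the permutation
# schemes cheap to evaluate.
amova_from_pp <- function(pp, n_p, grp_of_pop) {
  N <- sum(n_p)
  P <- length(n_p)
  gu <- unique(grp_of_pop)
  G <- length(gu)
  ssd_wp <- sum(diag(pp) / (2 * n_p))
  n_g <- vapply(gu, function(g) sum(n_p[grp_of_pop == g]), numeric(1L))
  ssd_g <- sum(vapply(seq_along(gu), function(k) {
    idx <- which(grp_of_pop == gu[k])
    sum(pp[idx, idx]) / (2 * n_g[k])
  }, numeric(1L)))
  ssd_tot <- sum(pp) / (2 * N)
  ssd_ap <- ssd_g - ssd_wp
  ssd_ag <- ssd_tot - ssd_g
  df <- c(amongGroups = G - 1, amongPopsWithin = P - G, withinPops = N - P)
  # unequal-size coefficients for the expected mean squares
  sum_np2_by_g <- vapply(gu, function(g) {
    sum(n_p[grp_of_pop == g]^2) / sum(n_p[grp_of_pop == g])
  }, numeric(1L))
  n1 <- (N - sum(sum_np2_by_g)) / (P - G)
  n2 <- (sum(sum_np2_by_g) - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(n_g^2) / N) / (G - 1)
  sigma_c <- ssd_wp / df[["withinPops"]]
  if (df[["amongPopsWithin"]] > 0) {
    sigma_b <- (ssd_ap / df[["amongPopsWithin"]] - sigma_c) / n1
  } else {
    sigma_b <- 0   # one population per group: no middle stratum
  }
  sigma_a <- (ssd_ag / df[["amongGroups"]] - sigma_c - n2 * sigma_b) / n3
  comp <- c(amongGroups = sigma_a, amongPopsWithin = sigma_b,
            withinPops = sigma_c)
  tot <- sum(comp)
  f <- c(FCT = sigma_a / tot,
         FSC = if (df[["amongPopsWithin"]] > 0)
           sigma_b / (sigma_b + sigma_c) else NA_real_,
         FST = (sigma_a + sigma_b) / tot)
  list(components = comp, f = f,
       ssd = c(amongGroups = ssd_ag, amongPopsWithin = ssd_ap,
               withinPops = ssd_wp, total = ssd_tot),
       df = df)
}

#' Two-level analysis of molecular variance (AMOVA)
#'
#' Partitions pairwise sequence distances (counts of differences at analyzed
#' sites, used as squared distances) into among-group, among-population-
#' within-group and within-population variance components using expected
#' mean squares with unequal-sample-size coefficients, and reports the
#' fixation indices F_CT, F_SC and F_ST. Significance comes from three
#' permutation schemes: whole populations permuted among groups (F_CT),
#' sequences permuted among populations within their group (F_SC), and
#' sequences permuted among all populations (F_ST); p-values are
#' (count + 1)/(nPermutations + 1). Negative variance components are
#' reported as estimated, with a warning.
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @param partition a \linkS4class{PopPartition} whose populations are
#'   nested in at least two groups.
#' @param nPermutations permutations per statistic (default 999; the
#'   full-fidelity setting used for final reports is 1e5).
#' @param seed optional integer seed.
#' @param schemes which permutation schemes to run (default all three);
#'   statistics whose scheme is skipped get an NA p-value. Useful when only
#'   one index is of interest: the F_CT scheme has a much smaller label
#'   space (population-level), so resolving small p-values benefits from
#'   more permutations than the sequence-level schemes need.
#' @return an \linkS4class{AmovaResult}.
#' @export
amova <- function(aln, partition, nPermutations = 999, seed = NULL,
                  schemes = c("FCT", "FSC", "FST")) {
  nPermutations <- stop_if_not_scalar_count(nPermutations, "nPermutations")
  schemes <- match.arg(schemes, several.ok = TRUE)
  pops <- match_partition(aln, partition)
  if (!length(partition@popGroup))
    stop("partition has no group level; AMOVA needs populations nested in groups")
  grps <- partition@popGroup[pops]
  if (anyNA(grps)) stop("populations without group assignment")
  if (length(unique(grps)) < 2L)
    stop("a single group: F_CT undefined")
  if (any(table(pops) < 2L)) stop("each population needs >= 2 sequences")
  d2 <- pairwiseDifferences(aln)
  if (all(d2 == 0))
    stop("all sequences identical: molecular variance is zero, AMOVA undefined")
  popu <- unique(pops)
  popf <- factor(pops, levels = popu)
  n_p <- as.numeric(table(popf))
  grp_of_pop <- grps[match(popu, pops)]
  pp <- pop_pair_sums(d2, popf)[popu, popu, drop = FALSE]
  obs <- amova_from_pp(pp, n_p, grp_of_pop)
  if (any(obs$components < 0))
    warning("negative variance component(s) estimated; reported unclamped")
  beats <- function(f_perm, f_obs) {
    !is.na(f_perm) && !is.na(f_obs) && f_perm >= f_obs
  }
  perms <- with_seed(seed, {
    cnt <- c(FCT = NA_integer_, FSC = NA_integer_, FST = NA_integer_)
    cnt[schemes] <- 0L
    for (i in seq_len(nPermutations)) {
      if ("FCT" %in% schemes) {
        # permute whole populations among groups; pp and n_p are unchanged
        f1 <- amova_from_pp(pp, n_p, sample(grp_of_pop))$f[["FCT"]]
        if (beats(f1, obs$f[["FCT"]])) cnt[["FCT"]] <- cnt[["FCT"]] + 1L
      }
      if ("FSC" %in% schemes) {
        # permute sequences among populations within their group
        p2 <- pops
        for (g in unique(grps)) {
          idx <- which(grps == g)
          p2[idx] <- p2[idx][sample.int(length(idx))]
        }
        pp2 <- pop_pair_sums(d2, factor(p2, levels = popu))[popu, popu,
                                                            drop = FALSE]
        f2 <- amova_from_pp(pp2, n_p, grp_of_pop)$f[["FSC"]]
        if (beats(f2, obs$f[["FSC"]])) cnt[["FSC"]] <- cnt[["FSC"]] + 1L
      }
      if ("FST" %in% schemes) {
        # permute sequences among all populations (pop->group map fixed)
        p3 <- pops[sample.int(length(pops))]
        pp3 <- pop_pair_sums(d2, factor(p3, levels = popu))[popu, popu,
                                                            drop = FALSE]
        f3 <- amova_from_pp(pp3, n_p, grp_of_pop)$f[["FST"]]
        if (beats(f3, obs$f[["FST"]])) cnt[["FST"]] <- cnt[["FST"]] + 1L
      }
    }
    cnt
  })
  pvals <- (perms + 1) / (nPermutations + 1)
  if (is.na(obs$f[["FSC"]])) pvals[["FSC"]] <- NA_real_
  pct <- 100 * obs$components / sum(obs$components)
  new("AmovaResult", components = obs$components, percentages = pct,
      fStatistics = obs$f, pValues = pvals, ssd = obs$ssd, df = obs$df,
      nPermutations = as.integer(nPermutations),
      seed = if (is.null(seed)) NA_real_ else seed)
}
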