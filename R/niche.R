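# Climatic-niche divergence: correlation-matrix PCA, the per-axis Di
# difference-of-means statistic with a label-permutation null, and a Wilks'
# lambda MANOVA confirmation on the leading axes.

#' Read an occurrence-site climate table
#'
#' CSV with columns \code{site_id}, \code{group} and one numeric column per
#' climate variable. Rows with missing values are rejected at load (dropped
#' with a warning).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readClimateTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site_id", "group") %in% names(tab)))
    stop("climate table needs 'site_id' and 'group' columns")
  ok <- stats::complete.cases(tab)
  if (!all(ok)) {
    warning(sum(!ok), " rows with missing values dropped")
    tab <- tab[ok, , drop = FALSE]
  }
  vars <- setdiff(names(tab), c("site_id", "group"))
  if (!length(vars)) stop("no climate variable columns found")
  if (!all(vapply(tab[vars], is.numeric, logical(1L))))
    stop("all climate variable columns must be numeric")
  tab
}

#' Principal components of standardized climate variables
#'
#' PCA on the correlation matrix: each variable is centered and scaled to
#' unit variance before the rotation, so variables measured in degrees and
#' millimetres contribute equally. Eigenvector signs are fixed by flipping
#' each loading vector so that its largest-magnitude element is positive,
#' making results reproducible across platforms (the sign of any axis is
#' otherwise arbitrary).
#'
#' @param table climate table as returned by \code{\link{readClimateTable}}
#'   or \code{\link{generateClimateOccurrences}}.
#' @param nAxes number of axes to retain (default all).
#' @return list of class \code{"climatePCA"} with elements \code{loadings}
#'   (variables x axes), \code{scores} (sites x axes), \code{varianceFraction},
#'   \code{siteId}, \code{group}, \code{center}, \code{scale}.
#' @examples
#' tab <- generateClimateOccurrences(c(10, 10), seed = 1)
#' pca <- climatePCA(tab, nAxes = 3)
#' pca$varianceFraction
#' @export
climatePCA <- function(table, nAxes = NULL) {
  vars <- setdiff(names(table), c("site_id", "group"))
  x <- as.matrix(table[vars])
  if (nrow(x) < 2L) stop("need at least 2 sites")
  if (ncol(x) < 2L) stop("need at least 2 variables")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant climate variable(s): ",
         paste(vars[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-12)
  if (is.null(nAxes)) nAxes <- rank
  if (nAxes > rank)
    stop("nAxes (", nAxes, ") exceeds the rank of the data (", rank, ")")
  keep <- seq_len(nAxes)
  rot <- pc$rotation[, keep, drop = FALSE]
  # deterministic sign: largest-|loading| element of each axis positive
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1L))
  rot <- sweep(rot, 2L, flip, `*`)
  scores <- sweep(pc$x[, keep, drop = FALSE], 2L, flip, `*`)
  structure(list(
    loadings = rot,
    scores = scores,
    varianceFraction = (pc$sdev^2 / sum(pc$sdev^2))[keep],
    siteId = table$site_id,
    group = table$group,
    center = pc$center,
    scale = pc$scale
  ), class = "climatePCA")
}

#' @export
print.climatePCA <- function(x, ...) {
  cat("Climate PCA:", nrow(x$scores), "sites,", nrow(x$loadings),
      "variables,", ncol(x$scores), "axes retained\n")
  cat("variance fractions:",
      paste(sprintf("%.3f", x$varianceFraction), collapse = " "), "\n")
  invisible(x)
}

resolve_scores <- function(scores, groups, axis) {
  if (inherits(scores, "climatePCA")) {
    if (is.null(groups)) groups <- scores$group
    scores <- scores$scores
  }
  scores <- as.matrix(scores)
  if (axis < 1L || axis > ncol(scores))
    stop("axis out of range")
  list(s = scores[, axis], groups = groups)
}

#' Observed per-axis difference of group means (Di)
#'
#' Di = mean score of the first group level minus mean score of the second,
#' on one principal-component axis. The order of levels (and hence the sign)
#' is fixed by the caller via \code{levels} or the factor's level order.
#'
#' @param scores site-by-axis score matrix, or a \code{climatePCA} object.
#' @param groups group labels per site (ignored if \code{scores} is a
#'   \code{climatePCA} and carries them); exactly two levels must be present.
#' @param axis axis index (default 1).
#' @param levels optional length-2 character fixing the (A, B) order.
#' @return numeric Di.
#' @export
diObserved <- function(scores, groups = NULL, axis = 1, levels = NULL) {
  r <- resolve_scores(scores, groups, axis)
  g <- as.character(r$groups)
  lev <- if (is.null(levels)) unique(g) else levels
  if (length(lev) != 2L || !all(g %in% lev))
    stop("exactly two group labels required")
  nA <- sum(g == lev[1L]); nB <- sum(g == lev[2L])
  if (nA == 0L || nB == 0L) stop("a group has zero members")
  mean(r$s[g == lev[1L]]) - mean(r$s[g == lev[2L]])
}

#' Permutation test for niche divergence on one PC axis
#'
#' Builds the null distribution of Di by reshuffling group labels without
#' replacement (preserving group sizes) and compares the observed Di to it.
#' The default tail policy is two-sided on |Di|: p = #(|Di_null| >= |Di_obs|)
#' / nPermutations. The literal one-sided count (#(Di_null >= Di_obs)) is
#' available via \code{tail = "greater"}, and the (count+1)/(n+1) small-sample
#' correction via \code{plusOne = TRUE}.
#'
#' @inheritParams diObserved
#' @param nPermutations number of label permutations (>= 99); ignored when
#'   \code{exhaustive = TRUE}.
#' @param seed optional integer seed (recorded in the result).
#' @param tail \code{"two.sided"} (default) or \code{"greater"}.
#' @param plusOne use the (count+1)/(n+1) estimator (default FALSE: the
#'   plain count/n ratio).
#' @param exhaustive enumerate all label allocations (choose(n, nA)) instead
#'   of sampling; feasible only for small site counts.
#' @return a \linkS4class{DiTestResult}.
#' @examples
#' tab <- generateClimateOccurrences(c(14, 14), shift = c(3, 0, 0), seed = 2)
#' pca <- climatePCA(tab, nAxes = 3)
#' diPermutationTest(pca, axis = 1, nPermutations = 999, seed = 7)
#' @export
diPermutationTest <- function(scores, groups = NULL, axis = 1,
                              nPermutations = 9999, seed = NULL,
                              tail = c("two.sided", "greater"),
                              plusOne = FALSE, levels = NULL,
                              exhaustive = FALSE) {
  tail <- match.arg(tail)
  r <- resolve_scores(scores, groups, axis)
  g <- as.character(r$groups)
  lev <- if (is.null(levels)) unique(g) else levels
  if (length(lev) != 2L || !all(g %in% lev))
    stop("exactly two group labels required")
  s <- r$s
  n <- length(s)
  nA <- sum(g == lev[1L]); nB <- n - nA
  if (nA == 0L || nB == 0L) stop("a group has zero members")
  obs <- mean(s[g == lev[1L]]) - mean(s[g == lev[2L]])
  total <- sum(s)
  di_from_idx <- function(idx) {
    sa <- sum(s[idx])
    sa / nA - (total - sa) / nB
  }
  if (exhaustive) {
    allo <- utils::combn(n, nA)
    null <- apply(allo, 2L, di_from_idx)
    nPermutations <- ncol(allo)
  } else {
    nPermutations <- stop_if_not_scalar_count(nPermutations,
                                              "nPermutations", min = 99L)
    null <- with_seed(seed, vapply(seq_len(nPermutations), function(i) {
      di_from_idx(sample.int(n, nA))
    }, numeric(1L)))
  }
  count <- if (tail == "two.sided") sum(abs(null) >= abs(obs))
           else sum(null >= obs)
  p <- if (plusOne) (count + 1) / (nPermutations + 1)
       else count / nPermutations
  new("DiTestResult", axis = as.integer(axis), diObserved = obs,
      nullSample = as.numeric(null), pValue = p,
      nPermutations = as.integer(nPermutations), tail = tail,
      plusOne = plusOne, seed = if (is.null(seed)) NA_real_ else seed)
}

#' Wilks' lambda MANOVA on the leading PC axes
#'
#' Tests whether group mean vectors coincide across the retained axes.
#' Lambda = det(E) / det(E + H), with E the pooled within-group and H the
#' between-group cross-product matrices; the p-value uses Rao's F
#' approximation (exact for two groups).
#'
#' @param scores site-by-axis matrix or \code{climatePCA} object.
#' @param groups group labels (two or more levels).
#' @param nAxes number of leading axes to use (default: all columns).
#' @return list of class \code{"wilksManova"} with \code{wilksLambda},
#'   \code{approxF}, \code{df1}, \code{df2}, \code{pValue}.
#' @export
wilksManova <- function(scores, groups = NULL, nAxes = NULL) {
  if (inherits(scores, "climatePCA")) {
    if (is.null(groups)) groups <- scores$group
    scores <- scores$scores
  }
  x <- as.matrix(scores)
  if (!is.null(nAxes)) x <- x[, seq_len(nAxes), drop = FALSE]
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least two groups")
  p <- ncol(x)
  N <- nrow(x)
  if (any(table(g) <= p))
    stop("each group must have more members than axes used")
  grand <- colMeans(x)
  E <- matrix(0, p, p); H <- matrix(0, p, p)
  for (lv in levels(g)) {
    xi <- x[g == lv, , drop = FALSE]
    mi <- colMeans(xi)
    ci <- sweep(xi, 2L, mi)
    E <- E + crossprod(ci)
    H <- H + nrow(xi) * tcrossprod(mi - grand)
  }
  dE <- det(E)
  if (dE <= 0) stop("singular within-group matrix; use fewer axes")
  lambda <- dE / det(E + H)
  nh <- nlevels(g) - 1L
  ne <- N - nlevels(g)
  t <- if (p^2 + nh^2 - 5 > 0) sqrt((p^2 * nh^2 - 4) / (p^2 + nh^2 - 5)) else 1
  w <- ne + nh - (p + nh + 1) / 2
  df1 <- p * nh
  df2 <- w * t - (p * nh - 2) / 2
  lt <- lambda^(1 / t)
  Fstat <- (1 - lt) / lt * df2 / df1
  pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  structure(list(wilksLambda = lambda, approxF = Fstat,
                 df1 = df1, df2 = df2, pValue = pval),
            class = "wilksManova")
}

#' @export
print.wilksManova <- function(x, ...) {
  cat(sprintf("Wilks' lambda = %.4g, approx F(%g, %.4g) = %.4g, p = %.4g\n",
              x$wilksLambda, x$df1, x$df2, x$approxF, x$pValue))
  invisible(x)
}
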