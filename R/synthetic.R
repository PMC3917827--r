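# Synthetic climate and morphology generators. These emulate the structure
# the downstream analyses assume: collinear climate variables arising from a
# few latent factors with a group mean shift, and log-scale traits with sexual
# dimorphism and a (possibly quadratic) dependence on one climate axis.

#' Generate a synthetic occurrence-site climate table
#'
#' Sites are drawn from a latent-factor model: each of \code{nVars} climate
#' variables is a fixed linear combination (\code{loadings}) of
#' \code{nLatent} independent standard-normal latent factors plus independent
#' Gaussian noise. Group 2's latent means are offset by \code{shift}, so the
#' between-group signal lives in a known low-dimensional subspace — the
#' situation a principal-component niche-divergence test is designed for.
#'
#' @param nPerGroup integer vector of length 2, sites per group (each >= 2).
#' @param nVars number of climate variables (default 19, the bioclim set
#'   size).
#' @param nLatent number of latent factors (default 3).
#' @param loadings \code{nVars x nLatent} matrix of full column rank; by
#'   default drawn once from the seeded RNG with column scales 3, 2, 1, ...
#' @param shift numeric of length \code{nLatent}: latent-mean offset of group
#'   2 relative to group 1 (default all zero, the exchangeable null).
#' @param noiseSd positive noise standard deviation (default 1).
#' @param groupNames length-2 character vector of group labels.
#' @param seed optional integer seed.
#' @return data.frame with columns \code{site_id}, \code{group} and
#'   \code{bio1 ... bio<nVars>}.
#' @examples
#' tab <- generateClimateOccurrences(c(10, 10), shift = c(3, 0, 0), seed = 1)
#' head(tab[, 1:5])
#' @export
generateClimateOccurrences <- function(nPerGroup = c(28, 8), nVars = 19,
                                       nLatent = 3, loadings = NULL,
                                       shift = rep(0, nLatent), noiseSd = 1,
                                       groupNames = c("group1", "group2"),
                                       seed = NULL) {
  stopifnot(length(nPerGroup) == 2L, all(nPerGroup >= 2),
            nVars >= 2, nLatent >= 1, length(shift) == nLatent,
            is.numeric(noiseSd), noiseSd > 0, length(groupNames) == 2L)
  with_seed(seed, {
    if (is.null(loadings)) {
      loadings <- matrix(stats::rnorm(nVars * nLatent), nVars, nLatent)
      loadings <- sweep(loadings, 2L, rev(seq_len(nLatent)), `*`)
    }
    loadings <- as.matrix(loadings)
    if (!identical(dim(loadings), c(as.integer(nVars), as.integer(nLatent))))
      stop("'loadings' must be an nVars x nLatent matrix")
    if (qr(loadings)$rank < nLatent)
      stop("'loadings' must have full column rank")
    n <- sum(nPerGroup)
    latent <- matrix(stats::rnorm(n * nLatent), n, nLatent)
    isB <- rep(c(FALSE, TRUE), nPerGroup)
    latent[isB, ] <- sweep(latent[isB, , drop = FALSE], 2L, shift, `+`)
    x <- latent %*% t(loadings) +
      matrix(stats::rnorm(n * nVars, sd = noiseSd), n, nVars)
    colnames(x) <- paste0("bio", seq_len(nVars))
    data.frame(site_id = sprintf("site%03d", seq_len(n)),
               group = rep(groupNames, nPerGroup),
               x, stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic individual-morphology table
#'
#' Individuals are drawn per site with sex assigned by \code{sexRatio}; each
#' log10-scale trait is intercept + sexEffect * [male] + linear * x +
#' quad * x^2 + Gaussian noise, where x is the site's climate-axis value, and
#' is then back-transformed to natural units (g, mm).
#'
#' @param sites data.frame with columns \code{site_id}, \code{group},
#'   \code{climate} (site score on the climate axis driving morphology).
#' @param nPerSite individuals per site (>= 3, matching the minimum site
#'   sample size used in site-level analyses).
#' @param intercepts,sexEffect,linear,quad,residualSd named numeric vectors
#'   with elements \code{mass}, \code{wing}, \code{tarsus}; all on the log10
#'   scale. Defaults give a bird of roughly 31 g, 80 mm wing, 27 mm tarsus
#'   with mild male-biased dimorphism and a negative quadratic mass/wing
#'   response to the climate axis.
#' @param sexRatio probability an individual is male (default 52/81, the
#'   study-scale male fraction).
#' @param seed optional integer seed.
#' @return data.frame with columns \code{individual_id}, \code{site_id},
#'   \code{group}, \code{sex}, \code{mass}, \code{wing}, \code{tarsus}.
#' @export
generateMorphology <- function(sites, nPerSite = 7,
                               intercepts = c(mass = 1.49, wing = 1.90,
                                              tarsus = 1.43),
                               sexEffect = c(mass = 0.03, wing = 0.025,
                                             tarsus = 0.012),
                               linear = c(mass = 0, wing = 0, tarsus = 0),
                               quad = c(mass = -0.01, wing = -0.006,
                                        tarsus = 0),
                               residualSd = c(mass = 0.025, wing = 0.012,
                                              tarsus = 0.015),
                               sexRatio = 52 / 81, seed = NULL) {
  if (!is.data.frame(sites) || nrow(sites) == 0L)
    stop("'sites' must be a non-empty data.frame")
  if (!all(c("site_id", "group", "climate") %in% names(sites)))
    stop("'sites' needs columns site_id, group, climate")
  if (nPerSite < 3) stop("'nPerSite' must be >= 3")
  traits <- c("mass", "wing", "tarsus")
  for (v in list(intercepts, sexEffect, linear, quad, residualSd))
    stopifnot(all(traits %in% names(v)))
  if (any(residualSd[traits] <= 0)) stop("residualSd must be positive")
  with_seed(seed, {
    n <- nrow(sites) * nPerSite
    site <- rep(sites$site_id, each = nPerSite)
    grp <- rep(sites$group, each = nPerSite)
    x <- rep(sites$climate, each = nPerSite)
    male <- stats::rbinom(n, 1L, sexRatio)
    out <- data.frame(individual_id = sprintf("bird%03d", seq_len(n)),
                      site_id = site, group = grp,
                      sex = ifelse(male == 1L, "male", "female"),
                      stringsAsFactors = FALSE)
    for (tr in traits) {
      logval <- intercepts[[tr]] + sexEffect[[tr]] * male +
        linear[[tr]] * x + quad[[tr]] * x^2 +
        stats::rnorm(n, sd = residualSd[[tr]])
      out[[tr]] <- 10^logval
    }
    out
  })
}
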