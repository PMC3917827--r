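# Morphology: trait transforms, structural-size index, factorial ANOVA and
# the four-model climate-regression suite ranked by AICc with Akaike weights.

#' Read an individual-morphology table
#'
#' CSV with columns \code{individual_id}, \code{site_id}, \code{group},
#' \code{sex} (female/male) and the traits \code{mass} (g), \code{wing} (mm),
#' \code{tarsus} (mm).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readMorphologyTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("individual_id", "site_id", "group", "sex",
              "mass", "wing", "tarsus")
  if (!all(needed %in% names(tab)))
    stop("morphology table needs columns: ", paste(needed, collapse = ", "))
  if (!all(tab$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male' and non-missing")
  for (tr in c("mass", "wing", "tarsus")) {
    bad <- which(!is.finite(tab[[tr]]) | tab[[tr]] <= 0)
    if (length(bad))
      stop("non-positive or missing ", tr, " for record(s): ",
           paste(tab$individual_id[bad], collapse = ", "))
  }
  tab
}

#' Log10-transform the trait columns
#'
#' Replaces \code{mass}, \code{wing} and \code{tarsus} by their base-10
#' logarithms (the scale on which the trait models assume normality); the
#' original units are kept as the \code{"units"} attribute.
#'
#' @param table morphology table.
#' @return transformed data.frame with attribute \code{units}.
#' @export
logTransformTraits <- function(table) {
  for (tr in c("mass", "wing", "tarsus")) {
    bad <- which(!is.finite(table[[tr]]) | table[[tr]] <= 0)
    if (length(bad))
      stop("non-positive ", tr, " for record(s): ",
           paste(table$individual_id[bad], collapse = ", "))
    table[[tr]] <- log10(table[[tr]])
  }
  attr(table, "units") <- c(mass = "log10 g", wing = "log10 mm",
                            tarsus = "log10 mm")
  table
}

#' Structural body-size index
#'
#' Ordinary least-squares residuals of log10(wing) on log10(tarsus) over the
#' pooled sample: a size proxy independent of condition. Residuals sum to
#' zero and are orthogonal to log tarsus by construction.
#'
#' @param table morphology table in natural units (log10 is applied
#'   internally).
#' @return numeric vector of residuals, one per individual.
#' @export
sizeIndex <- function(table) {
  if (nrow(table) < 3L) stop("need at least 3 individuals")
  lw <- log10(table$wing)
  lt <- log10(table$tarsus)
  if (stats::sd(lt) == 0) stop("tarsus is constant; size index undefined")
  stats::resid(stats::lm(lw ~ lt))
}

#' Factorial ANOVA of a trait on geography and sex
#'
#' Fits \code{trait ~ geography * sex} (interaction optional) and reports
#' per-term F and p. For unbalanced data the default is Type II sums of
#' squares (each main effect after the other); Type I (sequential) and
#' Type III are available. The trait is analyzed on the log10 scale.
#'
#' @param table morphology table in natural units.
#' @param trait one of \code{"mass"}, \code{"wing"}, \code{"tarsus"},
#'   \code{"size"} (the structural-size index, already a residual and used
#'   as-is).
#' @param geography column name holding the geographic factor (default
#'   \code{"site_id"}; use \code{"group"} for the subspecies-level test).
#' @param interaction include the geography:sex interaction (default TRUE).
#' @param ssType \code{"II"} (default), \code{"I"} or \code{"III"}.
#' @return data.frame with columns \code{term}, \code{df}, \code{sum_sq},
#'   \code{f_value}, \code{p_value}.
#' @export
factorialAnova <- function(table, trait, geography = "site_id",
                           interaction = TRUE,
                           ssType = c("II", "I", "III")) {
  ssType <- match.arg(ssType)
  y <- switch(trait,
              size = sizeIndex(table),
              mass = , wing = , tarsus = log10(table[[trait]]),
              stop("unknown trait: ", trait))
  geo <- factor(table[[geography]])
  sex <- factor(table$sex)
  if (nlevels(geo) < 2L || nlevels(sex) < 2L)
    stop("each factor needs at least 2 levels")
  if (interaction) {
    cells <- table(geo, sex)
    if (any(cells == 0L))
      stop("empty geography x sex cell(s); drop the interaction term")
  }
  dat <- data.frame(y = y, geo = geo, sex = sex)
  form <- if (interaction) y ~ geo * sex else y ~ geo + sex
  fit <- stats::lm(form, data = dat)
  if (ssType == "I") {
    a <- stats::anova(fit)
    keep <- rownames(a) != "Residuals"
    out <- data.frame(term = rownames(a)[keep], df = a$Df[keep],
                      sum_sq = a$`Sum Sq`[keep],
                      f_value = a$`F value`[keep],
                      p_value = a$`Pr(>F)`[keep])
  } else {
    a <- if (ssType == "II") car::Anova(fit, type = 2) else {
      fit3 <- stats::lm(form, data = dat,
                        contrasts = list(geo = "contr.sum",
                                         sex = "contr.sum"))
      car::Anova(fit3, type = 3)
    }
    keep <- !rownames(a) %in% c("Residuals", "(Intercept)")
    out <- data.frame(term = rownames(a)[keep], df = a$Df[keep],
                      sum_sq = a$`Sum Sq`[keep],
                      f_value = a$`F value`[keep],
                      p_value = a$`Pr(>F)`[keep])
  }
  out$term <- gsub("geo", geography, out$term)
  rownames(out) <- NULL
  out
}

#' Small-sample corrected Akaike information criterion
#'
#' Least-squares form: AIC = n*log(rss/n) + 2k and AICc = AIC +
#' 2k(k+1)/(n-k-1), with k counting the intercept, slopes and the residual
#' variance (so a simple linear regression has k = 3).
#'
#' @param n sample size.
#' @param k parameter count including the residual variance.
#' @param rss residual sum of squares (> 0).
#' @return AICc value.
#' @examples
#' aicc(10, 3, 10)  # 10*log(1) + 6 + 24/6 = 10
#' @export
aicc <- function(n, k, rss) {
  stopifnot(is.numeric(n), is.numeric(k), is.numeric(rss))
  if (rss <= 0) stop("rss must be positive (perfect fit: criterion degenerate)")
  if (n <= k + 1) stop("AICc undefined: need n > k + 1")
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc differences
#'
#' w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2), the relative support of
#' each model in the candidate set.
#'
#' @param deltaAicc numeric vector of AICc differences (minimum 0).
#' @return numeric weights summing to 1.
#' @examples
#' akaikeWeights(c(0, 2))
#' @export
akaikeWeights <- function(deltaAicc) {
  if (!length(deltaAicc)) stop("empty delta vector")
  if (any(!is.finite(deltaAicc))) stop("deltas must be finite")
  w <- exp(-deltaAicc / 2)
  w / sum(w)
}

#' Fit the four climate-regression models and rank them by AICc
#'
#' Regresses one (log-scale) trait on the site-level climate PC scores,
#' broadcast to individuals: trait ~ PC1, ~ PC1 + PC1^2, ~ PC2, and
#' ~ PC2 + PC2^2, and reports per-model R-squared, overall-F p-value, the
#' parameter count K (3 linear, 4 quadratic, residual variance included),
#' delta-AICc relative to the best model and Akaike weights.
#'
#' @param trait numeric response per individual (log10 scale for raw traits;
#'   the size index as-is).
#' @param pc1,pc2 climate scores per individual (site scores broadcast).
#' @return data.frame of class \code{"modelComparison"} with columns
#'   \code{model}, \code{r_squared}, \code{p_value}, \code{k}, \code{aicc},
#'   \code{delta_aicc}, \code{weight}.
#' @export
fitClimateModels <- function(trait, pc1, pc2) {
  n <- length(trait)
  stopifnot(length(pc1) == n, length(pc2) == n)
  if (n <= 5L) stop("need more than 5 observations")
  dat <- data.frame(y = trait, pc1 = pc1, pc2 = pc2)
  specs <- list(
    "PC1"        = y ~ pc1,
    "PC1+PC1^2"  = y ~ pc1 + I(pc1^2),
    "PC2"        = y ~ pc2,
    "PC2+PC2^2"  = y ~ pc2 + I(pc2^2)
  )
  rows <- lapply(names(specs), function(nm) {
    fit <- stats::lm(specs[[nm]], data = dat)
    sm <- summary(fit)
    rss <- sum(stats::resid(fit)^2)
    k <- length(stats::coef(fit)) + 1L  # + residual variance
    fs <- sm$fstatistic
    pv <- stats::pf(fs[[1L]], fs[[2L]], fs[[3L]], lower.tail = FALSE)
    data.frame(model = nm, r_squared = sm$r.squared, p_value = pv,
               k = k, aicc = aicc(n, k, rss), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$delta_aicc <- out$aicc - min(out$aicc)
  out$weight <- akaikeWeights(out$delta_aicc)
  rownames(out) <- NULL
  class(out) <- c("modelComparison", "data.frame")
  out
}
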