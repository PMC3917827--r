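# PCA, the Di statistic, its permutation null and the Wilks' lambda MANOVA.

make_scores <- function(s, g) list(s = s, g = g)

test_that("correlation-matrix PCA has the orthogonal-transform identities", {
  set.seed(21)
  tab <- generateClimateOccurrences(c(12, 12), nVars = 8, seed = 21)
  pca <- climatePCA(tab)
  x <- as.matrix(tab[paste0("bio", 1:8)])
  z <- scale(x, center = pca$center, scale = pca$scale)
  # reconstruction of the standardized data from scores %*% t(loadings)
  expect_lt(max(abs(pca$scores %*% t(pca$loadings) - z)), 1e-8)
  expect_true(all(diff(pca$varianceFraction) <= 1e-12))
  expect_lte(sum(pca$varianceFraction), 1 + 1e-12)
  # deterministic sign convention: dominant loading positive
  for (j in seq_len(ncol(pca$loadings))) {
    v <- pca$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("two perfectly collinear variables load on a single axis", {
  tab <- data.frame(site_id = paste0("s", 1:6),
                    group = rep(c("a", "b"), 3),
                    bio1 = 1:6, bio2 = 2 * (1:6) + 3)
  pca <- climatePCA(tab, nAxes = 1)
  expect_equal(pca$varianceFraction[1L], 1, tolerance = 1e-12)
  expect_error(climatePCA(tab, nAxes = 2), "rank")
})

test_that("constant columns are refused by name", {
  tab <- data.frame(site_id = paste0("s", 1:5), group = "a",
                    bio1 = rnorm(5), bio2 = 7)
  expect_error(climatePCA(tab), "bio2")
})

test_that("sample variance fractions approach the constructed eigenvalues", {
  # 3 latent factors with column scales 3, 2, 1 -> known covariance
  set.seed(31)
  L <- matrix(rnorm(19 * 3), 19, 3)
  L <- sweep(L, 2L, c(3, 2, 1), `*`)
  noiseSd <- 0.05
  tab <- generateClimateOccurrences(c(1500, 1500), nVars = 19, nLatent = 3,
                                    loadings = L, noiseSd = noiseSd,
                                    seed = 31)
  pca <- climatePCA(tab, nAxes = 4)
  sigma <- L %*% t(L) + diag(noiseSd^2, 19)
  expected <- eigen(stats::cov2cor(sigma), symmetric = TRUE,
                    only.values = TRUE)$values / 19
  expect_equal(pca$varianceFraction, expected[1:4], tolerance = 0.02)
})

test_that("Di is the signed difference of group means", {
  s <- c(1, 2, 3, 4, 6)
  g <- c("A", "A", "A", "B", "B")
  expect_equal(diObserved(cbind(s), g, axis = 1), -3)
  expect_equal(diObserved(cbind(s), g, axis = 1, levels = c("B", "A")), 3)
  expect_error(diObserved(cbind(s), rep("A", 5), axis = 1), "two group")
})

test_that("exhaustive permutation p equals the enumeration oracle", {
  s <- c(0.3, 1.2, -0.5, 2.0, 2.4, 3.1)
  g <- rep(c("A", "B"), each = 3)
  res <- diPermutationTest(cbind(s), g, axis = 1, exhaustive = TRUE)
  expect_equal(res@nPermutations, 20L)
  # independent enumeration
  obs <- mean(s[1:3]) - mean(s[4:6])
  nulls <- apply(combn(6, 3), 2L, function(idx) {
    mean(s[idx]) - mean(s[-idx])
  })
  expect_equal(sort(nullSample(res)), sort(nulls))
  expect_equal(pValue(res), sum(abs(nulls) >= abs(obs)) / 20)
  # literal one-sided formula
  res1 <- diPermutationTest(cbind(s), g, axis = 1, exhaustive = TRUE,
                            tail = "greater")
  expect_equal(pValue(res1), sum(nulls >= obs) / 20)
})

test_that("degenerate and extreme Di cases hit the p-value bounds", {
  sEq <- rep(2, 10)
  g <- rep(c("A", "B"), 5)
  res <- diPermutationTest(cbind(sEq), g, axis = 1, nPermutations = 99,
                           seed = 1)
  expect_equal(res@diObserved, 0)
  expect_equal(pValue(res), 1)
  # observed larger than every null value -> p = 0 under the plain ratio
  sX <- c(rep(0, 10), rep(100, 10))
  gX <- rep(c("A", "B"), each = 10)
  resX <- diPermutationTest(cbind(sX), gX, axis = 1, nPermutations = 199,
                            seed = 2, tail = "greater",
                            levels = c("B", "A"))
  expect_equal(pValue(resX), 0)
  resP <- diPermutationTest(cbind(sX), gX, axis = 1, nPermutations = 199,
                            seed = 2, tail = "greater",
                            levels = c("B", "A"), plusOne = TRUE)
  expect_equal(pValue(resP), 1 / 200)
})

test_that("Di permutation p is invariant to affine axis rescaling", {
  set.seed(77)
  s <- rnorm(20)
  g <- rep(c("A", "B"), 10)
  r1 <- diPermutationTest(cbind(s), g, axis = 1, nPermutations = 499,
                          seed = 5)
  r2 <- diPermutationTest(cbind(3.7 * s + 11), g, axis = 1,
                          nPermutations = 499, seed = 5)
  expect_equal(pValue(r1), pValue(r2))
  expect_equal(diObserved(cbind(s), g), -diObserved(cbind(s), g,
                                                    levels = c("B", "A")))
})

test_that("the stored seed regenerates the identical null sample", {
  set.seed(42)
  s <- rnorm(16)
  g <- rep(c("A", "B"), 8)
  r1 <- diPermutationTest(cbind(s), g, axis = 1, nPermutations = 299,
                          seed = 13)
  r2 <- diPermutationTest(cbind(s), g, axis = 1, nPermutations = 299,
                          seed = r1@seed)
  expect_identical(nullSample(r1), nullSample(r2))
})

test_that("Wilks' lambda matches hand determinants and stats::manova", {
  # hand-computable toy: two groups of 3 points in 2D
  x <- rbind(c(0, 0), c(1, 0), c(0, 1),
             c(2, 2), c(3, 2), c(2, 3))
  g <- rep(c("a", "b"), each = 3)
  w <- wilksManova(x, g)
  # E: within-group cross products; both groups have the same shape
  E <- 2 * matrix(c(2 / 3, -1 / 3, -1 / 3, 2 / 3), 2)
  m1 <- c(1 / 3, 1 / 3); m2 <- c(7 / 3, 7 / 3); grand <- (m1 + m2) / 2
  H <- 3 * tcrossprod(m1 - grand) + 3 * tcrossprod(m2 - grand)
  lambdaHand <- det(E) / det(E + H)
  expect_equal(w$wilksLambda, lambdaHand, tolerance = 1e-12)
  sm <- summary(stats::manova(x ~ factor(g)), test = "Wilks")$stats
  expect_equal(w$wilksLambda, unname(sm[1, 2]), tolerance = 1e-10)
  expect_equal(w$approxF, unname(sm[1, 3]), tolerance = 1e-8)
  expect_equal(w$pValue, unname(sm[1, 6]), tolerance = 1e-8)
})

test_that("identical group means give lambda = 1, p = 1", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, -1))
  x <- rbind(pts, pts)
  g <- rep(c("a", "b"), each = 4)
  w <- wilksManova(x, g)
  expect_equal(w$wilksLambda, 1, tolerance = 1e-12)
  expect_equal(w$pValue, 1, tolerance = 1e-10)
})

test_that("one response axis reduces Wilks to the one-way ANOVA F", {
  set.seed(8)
  y <- rnorm(18)
  g <- rep(c("a", "b", "c"), each = 6)
  w <- wilksManova(cbind(y), g)
  a <- anova(stats::lm(y ~ factor(g)))
  expect_equal(w$approxF, a$`F value`[1L], tolerance = 1e-10)
  expect_equal(w$pValue, a$`Pr(>F)`[1L], tolerance = 1e-10)
})
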