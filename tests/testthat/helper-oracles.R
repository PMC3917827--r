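# Independent brute-force oracles: O(n^2 L) character-level loops, written
# against the definitions, deliberately ignorant of the package's
# frequency-spectrum shortcuts.

aln_chars <- function(aln) {
  seqs <- as.character(divaxes::alignedSequences(aln))
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  mat[, divaxes::analyzedSites(aln), drop = FALSE]
}

bf_pair_diffs <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
  }
  d
}

bf_S <- function(mat) {
  sum(apply(mat, 2L, function(col) length(unique(col)) > 1L))
}

bf_pi_site <- function(mat) {
  d <- bf_pair_diffs(mat)
  n <- nrow(mat)
  sum(d[upper.tri(d)]) / (n * (n - 1) / 2) / ncol(mat)
}

bf_hd <- function(mat) {
  hap <- apply(mat, 1L, paste0, collapse = "")
  n <- length(hap)
  p <- as.numeric(table(hap)) / n
  n * (1 - sum(p^2)) / (n - 1)
}

bf_kst <- function(mat, pops) {
  d <- bf_pair_diffs(mat)
  u <- unique(pops)
  Kj <- sapply(u, function(p) {
    idx <- which(pops == p)
    s <- 0; np <- 0
    for (i in idx) for (j in idx) if (i < j) { s <- s + d[i, j]; np <- np + 1 }
    s / np
  })
  nj <- sapply(u, function(p) sum(pops == p))
  ks <- sum(nj / sum(nj) * Kj)
  kt <- sum(d[upper.tri(d)]) / (nrow(mat) * (nrow(mat) - 1) / 2)
  1 - ks / kt
}

bf_fixed <- function(mat, pops) {
  u <- unique(pops)
  cnt <- 0L
  for (col in seq_len(ncol(mat))) {
    b1 <- unique(mat[pops == u[1L], col])
    b2 <- unique(mat[pops == u[2L], col])
    if (length(intersect(b1, b2)) == 0L) cnt <- cnt + 1L
  }
  cnt
}

# random gap-free alignment with a controlled number of variable columns
random_alignment <- function(n, L, pVar = 0.15) {
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  mat <- matrix(rep(anc, each = n), nrow = n)
  nvar <- stats::rbinom(1L, L, pVar)
  if (nvar > 0) {
    cols <- sample.int(L, nvar)
    for (cl in cols) {
      alt <- sample(setdiff(bases, anc[cl]), 1L)
      carriers <- sample.int(n, sample.int(n - 1L, 1L))
      mat[carriers, cl] <- alt
    }
  }
  rownames(mat) <- sprintf("s%02d", seq_len(n))
  divaxes::LocusAlignment(stats::setNames(apply(mat, 1L, paste0, collapse = ""),
                                          rownames(mat)))
}
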