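# Two-deme isolation-with-migration coalescent simulator, infinite sites.
#
# Time runs backwards in ms-style coalescent units (4N_ref generations):
# * a deme of relative size x coalesces each lineage pair at rate 1/x,
# * each lineage in deme i migrates (backwards) to deme j at rate mig_ij/2,
#   where mig_ij = 4N_ref * m is the population-scaled migration rate,
# * mutations fall as Poisson(theta/2 * total branch length),
# so a single deme of size 1 gives E[S] = theta * a1, a1 = sum_{i<n} 1/i.
#
# The inheritance scalar h (1 autosomal, 0.75 Z-linked, 0.25 mtDNA) scales the
# relative size of every deme, so that within-deme diversity behaves as h*theta
# and the effective population-scaled migration as h*mig.

#' Simulate one locus under a two-deme isolation-with-migration model
#'
#' Runs a structured coalescent for two demes that exchange migrants until
#' \code{splitTime} (looking backwards), then coalesce in a single ancestral
#' deme, places mutations under the infinite-sites model and returns the
#' resulting alignment derived from a random (seed-determined) ancestral
#' sequence.
#'
#' @param theta population-scaled mutation rate 4N*mu per locus (> 0 allowed
#'   to be 0 for the degenerate no-mutation case).
#' @param splitTime divergence time, coalescent units (>= 0). 0 collapses the
#'   model to a single panmictic deme of size \code{ancestralSize}.
#' @param mig12,mig21 population-scaled backward migration rates 4N*m from
#'   deme 1 to deme 2 and vice versa (>= 0).
#' @param nSamples integer vector of length 2: sequences sampled per deme.
#' @param locusLength alignment length in bp.
#' @param inheritanceScalar 1.0 (autosomal), 0.75 (Z-linked) or 0.25 (mtDNA);
#'   any positive value is accepted.
#' @param ancestralSize relative size of the ancestral deme (default 1,
#'   i.e. equal to the daughter demes).
#' @param seed optional integer seed.
#' @return a \linkS4class{SimulatedLocus}.
#' @examples
#' loc <- simulateIMLocus(theta = 5, splitTime = 2, mig12 = 0, mig21 = 0,
#'                        nSamples = c(5, 5), locusLength = 500, seed = 1)
#' loc
#' @export
simulateIMLocus <- function(theta, splitTime, mig12 = 0, mig21 = 0,
                            nSamples = c(10, 10), locusLength = 1000,
                            inheritanceScalar = 1, ancestralSize = 1,
                            seed = NULL) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta >= 0,
            is.numeric(splitTime), splitTime >= 0,
            mig12 >= 0, mig21 >= 0,
            length(nSamples) == 2L, all(nSamples >= 1),
            inheritanceScalar > 0, ancestralSize > 0)
  locusLength <- stop_if_not_scalar_count(locusLength, "locusLength")
  nSamples <- as.integer(nSamples)
  with_seed(seed, {
    gen <- sim_im_genealogy(nSamples, splitTime, mig12, mig21,
                            sizes = inheritanceScalar * c(1, 1),
                            sizeAnc = inheritanceScalar * ancestralSize)
    total_len <- sum(gen$lengths)
    nmut <- stats::rpois(1L, theta / 2 * total_len)
    if (nmut > locusLength) {
      stop("infinite-sites violation: ", nmut, " mutations for ",
           locusLength, " sites; increase 'locusLength' or decrease 'theta'")
    }
    n <- sum(nSamples)
    anc <- sample(c("A", "C", "G", "T"), locusLength, replace = TRUE)
    mat <- matrix(rep(anc, each = n), nrow = n)
    if (nmut > 0L) {
      br <- sample.int(length(gen$lengths), nmut, replace = TRUE,
                       prob = gen$lengths)
      pos <- sample.int(locusLength, nmut, replace = FALSE)
      bases <- c("A", "C", "G", "T")
      for (i in seq_len(nmut)) {
        carriers <- gen$tips[[br[i]]]
        derived <- sample(setdiff(bases, anc[pos[i]]), 1L)
        mat[carriers, pos[i]] <- derived
      }
    }
    ids <- c(sprintf("d1_%02d", seq_len(nSamples[1L])),
             sprintf("d2_%02d", seq_len(nSamples[2L])))
    seqs <- Biostrings::DNAStringSet(apply(mat, 1L, paste0, collapse = ""))
    names(seqs) <- ids
    new("SimulatedLocus", alignment = seqs,
        demeLabels = rep(c("deme1", "deme2"), nSamples),
        mutationCount = as.integer(nmut), treeDepth = gen$tmrca)
  })
}

# Structured-coalescent genealogy for two demes merging at splitTime.
# Returns branch lengths and, per branch, the tip indices descending from it.
sim_im_genealogy <- function(nSamples, splitTime, mig12, mig21,
                             sizes, sizeAnc) {
  n <- sum(nSamples)
  # active lineages: list of tip index vectors, plus birth time and deme
  tips <- lapply(seq_len(n), identity)
  birth <- numeric(n)
  deme <- rep(c(1L, 2L), nSamples)
  if (splitTime == 0) deme <- rep(0L, n)   # 0 = ancestral pool
  active <- seq_len(n)
  blen <- numeric(0)
  btips <- list()
  t <- 0
  merged <- splitTime == 0
  # explicit state loop; n is small so plain R is fine
  while (length(active) > 1L) {
    k1 <- sum(deme[active] == 1L)
    k2 <- sum(deme[active] == 2L)
    if (!merged) {
      r_c1 <- k1 * (k1 - 1) / 2 / sizes[1L]
      r_c2 <- k2 * (k2 - 1) / 2 / sizes[2L]
      r_m1 <- k1 * mig12 / 2
      r_m2 <- k2 * mig21 / 2
      total <- r_c1 + r_c2 + r_m1 + r_m2
      dt <- if (total > 0) stats::rexp(1L, total) else Inf
      if (t + dt >= splitTime) {
        t <- splitTime
        deme[active] <- 0L
        merged <- TRUE
        next
      }
      t <- t + dt
      ev <- sample.int(4L, 1L, prob = c(r_c1, r_c2, r_m1, r_m2))
      if (ev <= 2L) {
        d <- ev
        cand <- which(deme[active] == d)
        pair <- cand[sample.int(length(cand), 2L)]
        ids <- active[pair]
        newtips <- sort(unlist(tips[ids]))
        for (ch in ids) {
          blen <- c(blen, t - birth[ch])
          btips[[length(btips) + 1L]] <- tips[[ch]]
        }
        tips[[length(tips) + 1L]] <- newtips
        birth <- c(birth, t)
        deme <- c(deme, d)
        active <- c(active[-pair], length(tips))
      } else {
        d <- ev - 2L
        cand <- which(deme[active] == d)
        mv <- active[cand[sample.int(length(cand), 1L)]]
        deme[mv] <- if (d == 1L) 2L else 1L
      }
    } else {
      k <- length(active)
      total <- k * (k - 1) / 2 / sizeAnc
      t <- t + stats::rexp(1L, total)
      pair <- sample.int(k, 2L)
      ids <- active[pair]
      newtips <- sort(unlist(tips[ids]))
      for (ch in ids) {
        blen <- c(blen, t - birth[ch])
        btips[[length(btips) + 1L]] <- tips[[ch]]
      }
      tips[[length(tips) + 1L]] <- newtips
      birth <- c(birth, t)
      deme <- c(deme, 0L)
      active <- c(active[-pair], length(tips))
    }
  }
  list(lengths = blen, tips = btips, tmrca = t)
}

#' Simulate a phased multilocus dataset with a sample sheet
#'
#' Generates one alignment per locus under the isolation-with-migration model,
#' with the ploidy convention of phased sequence data from diploid birds:
#' each individual contributes 2 sequences per autosomal locus, 1 per
#' mitochondrial locus, and 2 (males, ZZ) or 1 (females, ZW) per Z-linked
#' locus. Inheritance scalars are set by genome: autosomal 1.0, Z 0.75,
#' mtDNA 0.25. Within each group, individuals are assigned round-robin to
#' \code{popsPerGroup} sampling populations (labels only; the generative model
#' has one deme per group).
#'
#' @param loci data.frame with columns \code{name}, \code{genome} (one of
#'   \code{"mtDNA"}, \code{"autosomal"}, \code{"Z"}), \code{theta},
#'   \code{locusLength}; optional \code{splitTime}, \code{mig12},
#'   \code{mig21} override the shared defaults.
#' @param nIndividuals integer vector of length 2: individuals per group.
#' @param splitTime,mig12,mig21,ancestralSize shared model parameters
#'   (see \code{\link{simulateIMLocus}}).
#' @param sexRatio probability that an individual is male.
#' @param popsPerGroup sampling populations per group in the sample sheet.
#' @param groupNames length-2 character, group labels.
#' @param outDir if non-NULL, write one wrapped FASTA per locus and a
#'   \code{samples.tsv} sheet there.
#' @param seed optional integer seed.
#' @return list with \code{alignments} (named list of
#'   \linkS4class{LocusAlignment}), \code{sampleSheet} (data.frame with
#'   columns individual, population, group, sex) and, when written,
#'   \code{files}.
#' @export
simulateMultilocusDataset <- function(loci, nIndividuals = c(12, 10),
                                      splitTime = 2, mig12 = 0, mig21 = 0,
                                      ancestralSize = 1, sexRatio = 0.5,
                                      popsPerGroup = 2,
                                      groupNames = c("group1", "group2"),
                                      outDir = NULL, seed = NULL) {
  if (!is.data.frame(loci) || nrow(loci) == 0L)
    stop("'loci' must be a non-empty data.frame (zero loci requested?)")
  needed <- c("name", "genome", "theta", "locusLength")
  if (!all(needed %in% names(loci)))
    stop("'loci' needs columns: ", paste(needed, collapse = ", "))
  if (!all(loci$genome %in% c("mtDNA", "autosomal", "Z")))
    stop("genome must be one of 'mtDNA', 'autosomal', 'Z'")
  if (anyDuplicated(loci$name)) stop("duplicate locus names")
  stopifnot(length(nIndividuals) == 2L, all(nIndividuals >= 1),
            length(groupNames) == 2L)
  with_seed(seed, {
    nInd <- as.integer(nIndividuals)
    ind <- sprintf("ind%03d", seq_len(sum(nInd)))
    grp <- rep(groupNames, nInd)
    sex <- ifelse(stats::rbinom(sum(nInd), 1L, sexRatio) == 1L,
                  "male", "female")
    pop <- unlist(lapply(seq_len(2L), function(g) {
      sprintf("%s_pop%d", groupNames[g],
              rep_len(seq_len(popsPerGroup), nInd[g]))
    }))
    sheet <- data.frame(individual = ind, population = pop, group = grp,
                        sex = sex, stringsAsFactors = FALSE)
    scalars <- c(mtDNA = 0.25, autosomal = 1.0, Z = 0.75)
    copies_of <- function(genome, sex) {
      switch(genome,
             mtDNA = 1L,
             autosomal = 2L,
             Z = ifelse(sex == "male", 2L, 1L))
    }
    alignments <- list()
    for (j in seq_len(nrow(loci))) {
      lc <- loci[j, ]
      st <- if (!is.null(lc$splitTime) && !is.na(lc$splitTime))
        lc$splitTime else splitTime
      m12 <- if (!is.null(lc$mig12) && !is.na(lc$mig12)) lc$mig12 else mig12
      m21 <- if (!is.null(lc$mig21) && !is.na(lc$mig21)) lc$mig21 else mig21
      copies <- vapply(seq_along(ind),
                       function(i) copies_of(lc$genome, sex[i]), integer(1L))
      nseq <- c(sum(copies[grp == groupNames[1L]]),
                sum(copies[grp == groupNames[2L]]))
      sim <- simulateIMLocus(theta = lc$theta, splitTime = st,
                             mig12 = m12, mig21 = m21, nSamples = nseq,
                             locusLength = lc$locusLength,
                             inheritanceScalar = scalars[[lc$genome]],
                             ancestralSize = ancestralSize)
      # rename simulated haplotypes to <individual>_<allele copy>
      ids <- unlist(lapply(order(match(grp, groupNames)), function(i) {
        sprintf("%s_%d", ind[i], seq_len(copies[i]))
      }))
      stopifnot(length(ids) == length(sim@alignment))
      seqs <- sim@alignment
      names(seqs) <- ids
      alignments[[lc$name]] <- LocusAlignment(seqs, name = lc$name)
    }
    out <- list(alignments = alignments, sampleSheet = sheet)
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      files <- character(0)
      for (nm in names(alignments)) {
        f <- file.path(outDir, paste0(nm, ".fasta"))
        writeLocusAlignment(alignments[[nm]], f)
        files <- c(files, f)
      }
      sheetFile <- file.path(outDir, "samples.tsv")
      utils::write.table(sheet, sheetFile, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out$files <- c(files, sheetFile)
    }
    out
  })
}

#' Convert a scaled divergence time to years
#'
#' Converts a divergence time expressed on the expected-substitutions-per-site
#' scale (mu * tau, the scale on which isolation-with-migration divergence
#' times are reported) into years, given a per-site mutation rate per
#' generation and a generation time: \code{years = tScaled / mu *
#' genTimeYears}. With the avian rates used here (e.g. 2.41e-8 per site per
#' generation) and a one-year generation time this is simply tScaled / mu.
#'
#' @param tScaled divergence time, substitutions-per-site scale.
#' @param mu per-site mutation rate per generation (> 0).
#' @param genTimeYears generation time in years (default 1).
#' @return time in years.
#' @examples
#' convertDivergenceTime(7.23e-2, mu = 2.41e-8)  # ~3 Myr
#' @export
convertDivergenceTime <- function(tScaled, mu, genTimeYears = 1) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("'mu' must be a single positive rate")
  stopifnot(is.numeric(tScaled), all(tScaled >= 0), genTimeYears > 0)
  tScaled / mu * genTimeYears
}
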