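# Sequence statistics: IO, diversity, divergence, AMOVA, amino-acid profile.

test_that("FASTA round trip normalizes case and enforces structure", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "acgtacgtac", ">s2", "ACGTACGTAT"), f)
  aln <- readLocusAlignment(f, name = "toy")
  expect_equal(as.character(alignedSequences(aln))[["s1"]], "ACGTACGTAC")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLocusAlignment(aln, f2)
  expect_identical(as.character(alignedSequences(readLocusAlignment(f2))),
                   as.character(alignedSequences(aln)))
  # ragged
  fr <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGTT"), fr)
  expect_error(readLocusAlignment(fr), "ragged")
  # duplicate ids
  fd <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGA"), fd)
  expect_error(readLocusAlignment(fd), "duplicate")
  # empty
  fe <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), fe)
  expect_error(readLocusAlignment(fe))
})

test_that("complete deletion drops gap/N columns from the analyzed length", {
  aln <- LocusAlignment(c(a = "ACGT-CGTAN", b = "ACGTACGTAA"))
  expect_equal(analyzedLength(aln), 8L)
  alnP <- LocusAlignment(c(a = "ACGT-CGTAN", b = "ACGTACGTAA"),
                         sitePolicy = "pairwise")
  expect_equal(analyzedLength(alnP), 10L)
})

test_that("segregating sites are counted by hand examples", {
  expect_equal(segregatingSites(LocusAlignment(
    c(a = "AAT", b = "AAA", c = "AGA"))), 2L)
  expect_equal(segregatingSites(LocusAlignment(
    c(a = "ACGT", b = "ACGT"))), 0L)
})

test_that("haplotype diversity hits its algebraic identities", {
  expect_equal(haplotypeDiversity(LocusAlignment(
    c(a = "AAA", b = "AAA", c = "AAA"))), 0)
  distinct <- LocusAlignment(c(a = "AAAA", b = "AAAT", c = "AATT",
                               d = "ATTT"))
  expect_equal(haplotypeDiversity(distinct), 1)
  twoTwo <- LocusAlignment(c(a = "AAAA", b = "AAAA", c = "TTTT",
                             d = "TTTT"))
  expect_equal(haplotypeDiversity(twoTwo), 2 / 3)
})

test_that("Watterson's theta and its SE follow the stated formulas", {
  # n = 2, S = 1, L = 100: a1 = 1, theta = 0.01
  th <- wattersonTheta(LocusAlignment(c(
    a = paste0(strrep("A", 99), "T"), b = strrep("A", 100))))
  expect_equal(th$theta, 0.01)
  # S = 0
  th0 <- wattersonTheta(LocusAlignment(c(a = "ACGT", b = "ACGT")))
  expect_equal(th0$theta, 0)
  expect_equal(th0$se, 0)
  # n = 4, S = 3, L = 100 hand fixture
  base <- strrep("A", 97)
  aln <- LocusAlignment(c(s1 = paste0(base, "AAA"), s2 = paste0(base, "TAA"),
                          s3 = paste0(base, "ATA"), s4 = paste0(base, "AAT")))
  th4 <- wattersonTheta(aln)
  expect_equal(th4$theta, 3 / (11 / 6) / 100, tolerance = 1e-12)
  expect_equal(th4$se, 0.0140602778963, tolerance = 1e-9)
})

test_that("nucleotide diversity matches hand counts", {
  expect_equal(nucleotideDiversity(LocusAlignment(c(a = "AAA", b = "AAT"))),
               1 / 3)
  expect_equal(nucleotideDiversity(LocusAlignment(c(a = "ACG", b = "ACG"))),
               0)
})

test_that("Tajima's D reproduces the hand-computed fixture and sentinels", {
  aln <- LocusAlignment(c(a = "AAAA", b = "AAAA", c = "AAAT", d = "AATT"))
  expect_equal(tajimasD(aln), 0.5915801399, tolerance = 1e-9)
  expect_true(is.na(tajimasD(LocusAlignment(c(a = "AC", b = "AC",
                                              c = "AC")))))
  expect_error(tajimasD(LocusAlignment(c(a = "AC", b = "AC"))), "3")
})

test_that("frequency-spectrum statistics equal the brute-force oracle", {
  set.seed(606)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    L <- sample(20:200, 1)
    aln <- random_alignment(n, L)
    mat <- aln_chars(aln)
    expect_equal(segregatingSites(aln), bf_S(mat))
    expect_equal(nucleotideDiversity(aln), bf_pi_site(mat),
                 tolerance = 1e-12)
    expect_equal(haplotypeDiversity(aln), bf_hd(mat), tolerance = 1e-12)
  }
})

test_that("pairwise differences agree with ape's distance matrix", {
  skip_if_not_installed("ape")
  set.seed(707)
  aln <- random_alignment(8, 120)
  d <- pairwiseDifferences(aln)
  bin <- ape::as.DNAbin(strsplit(as.character(alignedSequences(aln)), ""))
  dape <- as.matrix(ape::dist.dna(bin, model = "N"))
  expect_equal(unname(d), unname(dape[rownames(d), colnames(d)]))
})

test_that("Kst invariants, oracle equality and seed reproducibility", {
  # within identical, between different -> Ks = 0, Kst = 1
  aln <- LocusAlignment(c(p1a = "AAAA", p1b = "AAAA",
                          p2a = "TTTT", p2b = "TTTT"))
  part <- PopPartition(c(p1a = "p1", p1b = "p1", p2a = "p2", p2b = "p2"))
  k <- kstTest(aln, part, nPermutations = 99, seed = 1)
  expect_equal(k@ks, 0)
  expect_equal(k@kst, 1)
  # random alignment: statistic equals brute force; order invariance
  set.seed(808)
  r <- random_alignment(10, 80)
  pops <- stats::setNames(rep(c("x", "y"), each = 5),
                          names(alignedSequences(r)))
  pr <- PopPartition(pops)
  kr <- kstTest(r, pr, nPermutations = 99, seed = 2)
  expect_equal(kr@kst, bf_kst(aln_chars(r), unname(pops)), tolerance = 1e-12)
  shuffle <- sample(length(alignedSequences(r)))
  r2 <- LocusAlignment(alignedSequences(r)[shuffle])
  kr2 <- kstTest(r2, pr, nPermutations = 99, seed = 2)
  expect_equal(kr2@kst, kr@kst, tolerance = 1e-12)
  # reproducible from seed
  kr3 <- kstTest(r, pr, nPermutations = 99, seed = 2)
  expect_identical(kr3@pValue, kr@pValue)
})

test_that("Kst is near zero under simulated panmixia", {
  set.seed(909)
  loc <- simulateIMLocus(5, 0, nSamples = c(10, 10), locusLength = 500)
  aln <- LocusAlignment(loc@alignment)
  part <- PopPartition(stats::setNames(loc@demeLabels,
                                       names(loc@alignment)))
  k <- kstTest(aln, part, nPermutations = 199, seed = 3)
  expect_lt(abs(k@kst), 0.25)
  expect_gt(k@pValue, 0.01)
})

test_that("fixed differences and percent divergence follow the definitions", {
  aln <- LocusAlignment(c(a1 = "AAAAA", a2 = "ATAAA",
                          b1 = "TAAAA", b2 = "TTAAA"))
  part <- PopPartition(c(a1 = "pA", a2 = "pA", b1 = "pB", b2 = "pB"))
  # site 1 disjoint {A} vs {T}; site 2 shares A
  expect_equal(fixedDifferences(aln, part), 1L)
  # one sequence per population, 5 diffs over 100 sites -> 5%
  s1 <- paste0(strrep("A", 95), "TTTTT")
  s2 <- strrep("A", 100)
  aln2 <- LocusAlignment(c(x = s1, y = s2))
  part2 <- PopPartition(c(x = "p1", y = "p2"))
  expect_equal(percentDivergence(aln2, part2), 5)
  expect_equal(percentDivergence(LocusAlignment(c(x = s2, y = s2)), part2), 0)
  # brute-force oracle on a random case
  set.seed(111)
  r <- random_alignment(8, 60)
  pops <- stats::setNames(rep(c("x", "y"), each = 4),
                          names(alignedSequences(r)))
  expect_equal(fixedDifferences(r, PopPartition(pops)),
               bf_fixed(aln_chars(r), unname(pops)))
})

test_that("AMOVA reproduces the hand-worked balanced fixture", {
  seqs <- c(g1p1_1 = "AAAAAAAAAA", g1p1_2 = "AAAAAAAAAA",
            g1p1_3 = "AAAAAAAAAA",
            g1p2_1 = "AAAAAAAAAT", g1p2_2 = "AAAAAAAAAT",
            g1p2_3 = "AAAAAAAAAT",
            g2p1_1 = "TTTTTAAAAA", g2p1_2 = "TTTTTAAAAA",
            g2p1_3 = "TTTTTAAAAA",
            g2p2_1 = "TTTTTTAAAA", g2p2_2 = "TTTTTTAAAA",
            g2p2_3 = "TTTTTTAAAA")
  aln <- LocusAlignment(seqs)
  part <- PopPartition(
    stats::setNames(rep(c("p1", "p2", "p3", "p4"), each = 3), names(seqs)),
    popGroup = c(p1 = "G1", p2 = "G1", p3 = "G2", p4 = "G2"))
  am <- amova(aln, part, nPermutations = 99, seed = 4)
  # hand: balanced nested design, within-pop distances all 0,
  # delta^2 = 1 between pops within groups, mean 6 between groups
  # -> sigma_c = 0, sigma_b = MS_AP/n0 = 1.5/3 = 0.5,
  #    sigma_a = (16.5 - 3*0.5)/6 = 2.5
  expect_equal(unname(am@components),
               c(2.5, 0.5, 0), tolerance = 1e-12)
  expect_equal(sum(am@percentages), 100, tolerance = 1e-9)
  expect_equal(unname(am@fStatistics[["FCT"]]), 2.5 / 3, tolerance = 1e-12)
  expect_equal(unname(am@fStatistics[["FSC"]]), 1, tolerance = 1e-12)
  expect_equal(unname(am@fStatistics[["FST"]]), 1, tolerance = 1e-12)
})

test_that("AMOVA guards degenerate partitions and collapses cleanly", {
  aln <- LocusAlignment(c(a = "AAAA", b = "AAAT", c = "TTTA", d = "TTTT"))
  oneGroup <- PopPartition(c(a = "p1", b = "p1", c = "p2", d = "p2"),
                           popGroup = c(p1 = "G", p2 = "G"))
  expect_error(amova(aln, oneGroup, nPermutations = 9), "single group")
  same <- LocusAlignment(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"))
  twoGroups <- PopPartition(c(a = "p1", b = "p1", c = "p2", d = "p2"),
                            popGroup = c(p1 = "G1", p2 = "G2"))
  expect_error(amova(same, twoGroups, nPermutations = 9), "identical")
  # one population per group: F_ST equals F_CT (middle stratum vanishes)
  am <- amova(aln, twoGroups, nPermutations = 99, seed = 5)
  expect_equal(am@fStatistics[["FST"]], am@fStatistics[["FCT"]],
               tolerance = 1e-12)
  expect_true(is.na(am@fStatistics[["FSC"]]))
})

test_that("the amino-acid profile translates with the mitochondrial code", {
  # synonymous-only variation: CTT/CTC are both Leu
  syn <- LocusAlignment(c(a1 = "CTTATG", a2 = "CTCATG",
                          b1 = "CTTATG", b2 = "CTCATG"))
  part <- PopPartition(c(a1 = "g1", a2 = "g1", b1 = "g2", b2 = "g2"))
  pr <- aaProfile(syn, part)
  expect_equal(pr$nSegregating, 0L)
  # Leu (TTA) vs Phe (TTT): one diagnostic position
  dia <- LocusAlignment(c(a1 = "TTAATG", a2 = "TTAATG",
                          b1 = "TTTATG", b2 = "TTTATG"))
  pr2 <- aaProfile(dia, part)
  expect_equal(pr2$nSegregating, 1L)
  expect_equal(pr2$nDiagnostic, 1L)
  # shared amino acid in one group -> not diagnostic
  mix <- LocusAlignment(c(a1 = "TTAATG", a2 = "TTTATG",
                          b1 = "TTTATG", b2 = "TTTATG"))
  pr3 <- aaProfile(mix, part)
  expect_equal(pr3$nSegregating, 1L)
  expect_equal(pr3$nDiagnostic, 0L)
  # internal stop (AGA is a stop in the vertebrate mitochondrial code)
  stopAln <- LocusAlignment(c(a1 = "AGAATG", a2 = "AGAATG",
                              b1 = "AGAATG", b2 = "AGAATG"))
  expect_warning(aaProfile(stopAln, part), "stop")
})

test_that("diversity statistics are invariant to sequence input order", {
  set.seed(121)
  aln <- random_alignment(9, 90)
  shuffled <- LocusAlignment(alignedSequences(aln)[sample(9)])
  expect_equal(segregatingSites(aln), segregatingSites(shuffled))
  expect_equal(nucleotideDiversity(aln), nucleotideDiversity(shuffled),
               tolerance = 1e-12)
  expect_equal(haplotypeDiversity(aln), haplotypeDiversity(shuffled),
               tolerance = 1e-12)
  expect_equal(tajimasD(aln), tajimasD(shuffled), tolerance = 1e-12)
})

test_that("locusStats bundles consistent per-group summaries", {
  set.seed(131)
  loc <- simulateIMLocus(4, 3, 0, 0, c(6, 6), 400)
  aln <- LocusAlignment(loc@alignment)
  st <- locusStats(aln)
  expect_s4_class(st, "LocusStats")
  expect_equal(st@S, segregatingSites(aln))
  expect_equal(st@piSite, nucleotideDiversity(aln), tolerance = 1e-12)
  ids1 <- names(alignedSequences(aln))[loc@demeLabels == "deme1"]
  st1 <- locusStats(aln, ids = ids1, name = "deme1")
  expect_equal(st1@n, length(ids1))
  expect_error(locusStats(aln, ids = "nope"), "unknown")
  tab <- locusStatsTable(list(st, st1))
  expect_equal(nrow(tab), 2L)
})
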