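# Configuration-driven orchestration: reads a YAML run configuration,
# resolves each data axis (paths or synthetic specification), runs the three
# analysis stages and writes TSV reports plus a JSON manifest with every seed.

default_config <- function() {
  list(
    seed = 1L,
    n_permutations = list(di = 9999L, kst = 999L, amova = 100000L),
    fast = FALSE,
    n_axes = 3L,
    tail = "two.sided",
    plus_one = FALSE,
    ss_type = "II",
    kst_weighting = "size",
    deletion = "complete",
    dump_null = FALSE
  )
}

#' Read and validate a run configuration
#'
#' The YAML file may contain an \code{inputs:} block (paths
#' \code{climate_csv}, \code{morphology_csv}, \code{loci} (list of FASTA
#' paths), \code{sample_sheet}) and/or a \code{synthetic:} block with
#' sub-blocks \code{climate}, \code{morphology}, \code{loci} giving generator
#' arguments. For each data axis exactly one source must be given. Remaining
#' keys override the defaults: \code{seed}, \code{n_permutations} (di, kst,
#' amova), \code{fast} (permutation profile 999/199/999), \code{n_axes},
#' \code{tail}, \code{plus_one}, \code{ss_type}, \code{kst_weighting},
#' \code{deletion}, \code{dump_null}.
#'
#' @param path YAML file, or a list already parsed.
#' @return validated config list of class \code{"runConfig"}.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  conf <- utils::modifyList(default_config(), cfg)
  for (axis in c("climate", "morphology", "loci")) {
    inp <- switch(axis, climate = conf$inputs$climate_csv,
                  morphology = conf$inputs$morphology_csv,
                  loci = conf$inputs$loci)
    syn <- conf$synthetic[[axis]]
    if (!is.null(inp) && !is.null(syn))
      stop("both input paths and a synthetic block given for '", axis, "'")
  }
  if (isTRUE(conf$fast))
    conf$n_permutations <- list(di = 999L, kst = 199L, amova = 999L)
  class(conf) <- "runConfig"
  conf
}

resolve_climate <- function(conf) {
  if (!is.null(conf$inputs$climate_csv))
    return(readClimateTable(conf$inputs$climate_csv))
  syn <- conf$synthetic$climate
  if (is.null(syn)) stop("no climate data configured")
  args <- syn
  args$seed <- if (!is.null(syn$seed)) syn$seed else conf$seed
  if (!is.null(args$nPerGroup)) args$nPerGroup <- unlist(args$nPerGroup)
  if (!is.null(args$shift)) args$shift <- unlist(args$shift)
  do.call(generateClimateOccurrences, args)
}

resolve_morphology <- function(conf, climateScores) {
  if (!is.null(conf$inputs$morphology_csv))
    return(readMorphologyTable(conf$inputs$morphology_csv))
  syn <- conf$synthetic$morphology
  if (is.null(syn)) stop("no morphology data configured")
  args <- syn
  args$seed <- if (!is.null(syn$seed)) syn$seed else conf$seed + 1L
  if (is.null(args$sites)) {
    # derive sites from the climate table's PC2 scores
    args$sites <- data.frame(site_id = climateScores$site_id,
                             group = climateScores$group,
                             climate = climateScores$climate)
  } else {
    args$sites <- as.data.frame(lapply(args$sites, unlist))
  }
  for (v in c("intercepts", "sexEffect", "linear", "quad", "residualSd"))
    if (!is.null(args[[v]])) args[[v]] <- unlist(args[[v]])
  do.call(generateMorphology, args)
}

resolve_loci <- function(conf, outDir) {
  if (!is.null(conf$inputs$loci)) {
    paths <- unlist(conf$inputs$loci)
    aln <- lapply(paths, readLocusAlignment, sitePolicy = conf$deletion)
    names(aln) <- vapply(aln, locusName, character(1L))
    sheet <- readSampleSheet(conf$inputs$sample_sheet)
    return(list(alignments = aln, sampleSheet = sheet))
  }
  syn <- conf$synthetic$loci
  if (is.null(syn)) stop("no sequence data configured")
  args <- syn
  args$seed <- if (!is.null(syn$seed)) syn$seed else conf$seed + 2L
  args$loci <- as.data.frame(lapply(args$loci, unlist),
                             stringsAsFactors = FALSE)
  if (!is.null(args$nIndividuals)) args$nIndividuals <-
      unlist(args$nIndividuals)
  do.call(simulateMultilocusDataset, args)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the niche-divergence stage
#'
#' PCA on the climate table, per-axis Di permutation tests and the Wilks'
#' lambda MANOVA on the retained axes. Writes \code{niche_di.tsv} (axis, Di,
#' p, variance fraction), \code{niche_loadings.tsv}, \code{niche_manova.tsv}
#' and optionally one \code{niche_null_axis<k>.tsv} per axis.
#'
#' @param config a \code{runConfig} (or path to one).
#' @param outDir output directory (created).
#' @return list with the PCA, the per-axis \linkS4class{DiTestResult}s, the
#'   MANOVA and the file paths.
#' @export
runNiche <- function(config, outDir) {
  conf <- if (inherits(config, "runConfig")) config else readRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  climate <- resolve_climate(conf)
  if (!all(c("site_id", "group") %in% names(climate)) ||
      length(unique(climate$group)) < 2L)
    stop("climate table lacks usable group labels")
  pca <- climatePCA(climate, nAxes = conf$n_axes)
  seeds <- conf$seed + 100L + seq_len(conf$n_axes)
  tests <- lapply(seq_len(conf$n_axes), function(ax) {
    diPermutationTest(pca, axis = ax,
                      nPermutations = conf$n_permutations$di,
                      seed = seeds[ax], tail = conf$tail,
                      plusOne = isTRUE(conf$plus_one))
  })
  man <- wilksManova(pca)
  report <- data.frame(
    axis = seq_len(conf$n_axes),
    di_observed = vapply(tests, function(t) t@diObserved, numeric(1L)),
    p_value = vapply(tests, pValue, numeric(1L)),
    variance_fraction = pca$varianceFraction,
    n_permutations = conf$n_permutations$di,
    seed = seeds)
  files <- c(
    write_tsv(report, file.path(outDir, "niche_di.tsv")),
    write_tsv(data.frame(variable = rownames(pca$loadings),
                         pca$loadings, check.names = FALSE),
              file.path(outDir, "niche_loadings.tsv")),
    write_tsv(data.frame(wilks_lambda = man$wilksLambda,
                         approx_f = man$approxF, df1 = man$df1,
                         df2 = man$df2, p_value = man$pValue),
              file.path(outDir, "niche_manova.tsv")))
  if (isTRUE(conf$dump_null)) {
    for (ax in seq_len(conf$n_axes)) {
      files <- c(files, write_tsv(
        data.frame(di_null = nullSample(tests[[ax]])),
        file.path(outDir, sprintf("niche_null_axis%d.tsv", ax))))
    }
  }
  list(pca = pca, diTests = tests, manova = man, files = files,
       seeds = seeds)
}

#' Run the morphology stage
#'
#' Builds the site-level PC1/PC2 climate scores, broadcasts them to
#' individuals, fits the four climate models per trait (mass, wing, tarsus,
#' structural size) and runs the factorial ANOVA per trait. Writes
#' \code{morpho_models.tsv} (16 rows) and \code{morpho_anova.tsv}.
#'
#' @inheritParams runNiche
#' @return list with the model-comparison table, ANOVA table and files.
#' @export
runMorpho <- function(config, outDir) {
  conf <- if (inherits(config, "runConfig")) config else readRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  climate <- resolve_climate(conf)
  pca <- climatePCA(climate, nAxes = max(2L, conf$n_axes))
  siteScores <- data.frame(site_id = pca$siteId,
                           group = pca$group,
                           pc1 = pca$scores[, 1L], pc2 = pca$scores[, 2L],
                           climate = pca$scores[, 2L])
  morph <- resolve_morphology(conf, siteScores)
  hit <- match(morph$site_id, siteScores$site_id)
  if (anyNA(hit))
    stop("morphology sites without climate scores: ",
         paste(unique(morph$site_id[is.na(hit)]), collapse = ", "))
  pc1 <- siteScores$pc1[hit]
  pc2 <- siteScores$pc2[hit]
  traits <- list(mass = log10(morph$mass), wing = log10(morph$wing),
                 tarsus = log10(morph$tarsus), size = sizeIndex(morph))
  models <- do.call(rbind, lapply(names(traits), function(tr) {
    cbind(trait = tr, fitClimateModels(traits[[tr]], pc1, pc2))
  }))
  anovas <- do.call(rbind, lapply(names(traits), function(tr) {
    cbind(trait = tr,
          factorialAnova(morph, tr, geography = "group",
                         interaction = TRUE, ssType = conf$ss_type))
  }))
  files <- c(write_tsv(models, file.path(outDir, "morpho_models.tsv")),
             write_tsv(anovas, file.path(outDir, "morpho_anova.tsv")))
  list(models = models, anova = anovas, files = files)
}

#' Run the population-genetics stage
#'
#' Per-locus diversity statistics for each group and overall (n, sites, S,
#' Hd, theta with SE, pi, Tajima's D), the overall Kst permutation test per
#' locus, an AMOVA on the first locus with populations nested in groups, and
#' the amino-acid profile of any mtDNA locus. Writes
#' \code{popgen_stats.tsv}, \code{popgen_kst.tsv}, \code{popgen_amova.tsv}
#' and \code{popgen_aa_profile.tsv}.
#'
#' @inheritParams runNiche
#' @param amovaLocus name of the locus used for the AMOVA (default: first).
#' @return list with per-locus stats, Kst results, the AMOVA, AA profile and
#'   files.
#' @export
runPopgen <- function(config, outDir, amovaLocus = NULL) {
  conf <- if (inherits(config, "runConfig")) config else readRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  dat <- resolve_loci(conf, outDir)
  aln <- dat$alignments
  sheet <- dat$sampleSheet
  if (!length(aln)) stop("no loci resolved")
  statRows <- list()
  kstRows <- list()
  kstSeeds <- conf$seed + 200L + seq_along(aln)
  ksts <- list()
  for (j in seq_along(aln)) {
    a <- aln[[j]]
    grpPart <- partitionFromSheet(a, sheet, level = "group")
    ids <- names(alignedSequences(a))
    for (g in unique(populations(grpPart))) {
      sel <- ids[populations(grpPart)[ids] == g]
      if (length(sel) >= 2L)
        statRows[[length(statRows) + 1L]] <-
          locusStatsTable(locusStats(a, ids = sel,
                                     name = paste0(locusName(a), "|", g)))
    }
    statRows[[length(statRows) + 1L]] <- locusStatsTable(locusStats(a))
    k <- kstTest(a, grpPart, nPermutations = conf$n_permutations$kst,
                 seed = kstSeeds[j], weighting = conf$kst_weighting)
    ksts[[locusName(a)]] <- k
    kstRows[[j]] <- data.frame(locus = locusName(a), kst = k@kst,
                               ks = k@ks, kt = k@kt, p_value = k@pValue,
                               n_permutations = k@nPermutations,
                               seed = kstSeeds[j])
  }
  if (is.null(amovaLocus)) amovaLocus <- names(aln)[1L]
  amv <- NULL
  amvSeed <- conf$seed + 300L
  popPart <- partitionFromSheet(aln[[amovaLocus]], sheet,
                                level = "population")
  amv <- amova(aln[[amovaLocus]], popPart,
               nPermutations = conf$n_permutations$amova, seed = amvSeed)
  amovaTab <- data.frame(
    stratum = c(names(amv@components), "total"),
    ssd = amv@ssd[c(names(amv@components), "total")],
    df = c(amv@df, sum(amv@df)),
    component = c(amv@components, sum(amv@components)),
    percent = c(amv@percentages, 100),
    f_statistic = c(amv@fStatistics, NA),
    p_value = c(amv@pValues, NA),
    row.names = NULL)
  files <- c(
    write_tsv(do.call(rbind, statRows),
              file.path(outDir, "popgen_stats.tsv")),
    write_tsv(do.call(rbind, kstRows), file.path(outDir, "popgen_kst.tsv")),
    write_tsv(amovaTab, file.path(outDir, "popgen_amova.tsv")))
  profile <- NULL
  mtLoci <- names(aln)[grepl("^(mt|atp)", tolower(names(aln)))]
  if (length(mtLoci)) {
    a <- aln[[mtLoci[1L]]]
    profile <- aaProfile(a, partitionFromSheet(a, sheet, level = "group"))
    files <- c(files, write_tsv(profile$segregating,
                                file.path(outDir, "popgen_aa_profile.tsv")))
  }
  list(stats = do.call(rbind, statRows), kst = ksts, amova = amv,
       aaProfile = profile, files = files,
       seeds = c(kst = kstSeeds, amova = amvSeed))
}

#' Run the full pipeline with a manifest
#'
#' Runs the niche, morphology and population-genetics stages into one output
#' directory; stages that fail are recorded in the manifest and the completed
#' ones kept. The manifest (\code{manifest.json}) records inputs, seeds,
#' permutation counts, toggles, package version and per-stage status/files.
#'
#' @inheritParams runNiche
#' @return list with per-stage results and the manifest (also written as
#'   JSON).
#' @export
runAll <- function(config, outDir) {
  conf <- if (inherits(config, "runConfig")) config else readRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stages <- list(niche = runNiche, morpho = runMorpho, popgen = runPopgen)
  results <- list()
  status <- list()
  for (nm in names(stages)) {
    res <- tryCatch(stages[[nm]](conf, outDir), error = function(e) e)
    if (inherits(res, "error")) {
      status[[nm]] <- list(ok = FALSE, error = conditionMessage(res))
    } else {
      results[[nm]] <- res
      status[[nm]] <- list(ok = TRUE, files = basename(res$files))
    }
  }
  manifest <- list(
    package = "divaxes",
    version = as.character(utils::packageVersion("divaxes")),
    seed = conf$seed,
    n_permutations = conf$n_permutations,
    settings = conf[c("n_axes", "tail", "plus_one", "ss_type",
                      "kst_weighting", "deletion")],
    inputs = conf$inputs,
    synthetic = !is.null(conf$synthetic),
    stages = status)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  c(results, list(manifest = manifest))
}
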