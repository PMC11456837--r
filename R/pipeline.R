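#' Clade pan-genome analysis: cores, cross-clade links, unique genes
#'
#' Clusters each clade's proteome at `identityWithin` (single linkage),
#' takes clade cores (clusters single-copy in every member), links one
#' representative per core cluster across clades at `identityAcross`, and
#' screens clade-restricted candidates with [uniqueGenes()] against all
#' out-of-clade proteomes.
#'
#' @param genomes named list of [GenomeRecord-class] objects with clade
#'   labels.
#' @param identityWithin,identityAcross clustering identity cutoffs (%).
#' @param coverageMin,eStrict,eFloor unique-gene screen thresholds.
#' @return list with `cladeCores` (per clade: clusters, core ids, members),
#'   `coreReps` (per clade `AAStringSet` of core representatives), `cross`
#'   (the cross-clade [OrthologClusterSet-class]) and `unique` (the
#'   [uniqueGenes()] table with a `clade` column, or `NULL`).
#' @export
pangenomeAnalysis <- function(genomes, identityWithin = 95,
                              identityAcross = 70, coverageMin = 50,
                              eStrict = 1e-50, eFloor = 1e-10) {
  cladeOf <- vapply(genomes, clade, character(1))
  cladeIds <- sort(unique(cladeOf))
  cladeCores <- list()
  coreReps <- list()
  for (cl in cladeIds) {
    members <- names(genomes)[cladeOf == cl]
    prots <- lapply(genomes[members], proteome)
    cls <- clusterOrthologs(prots, identityCutoff = identityWithin)
    coreIds <- cladeCore(cls, members)
    mem <- clusterMembers(cls)
    pick <- function(ci) {
      mm <- mem[mem$cluster == ci, ]
      mm[order(mm$genome, mm$protein), ][1, ]
    }
    reps <- vapply(coreIds, function(ci) {
      mm <- pick(ci)
      as.character(proteome(genomes[[mm$genome]])[[mm$protein]])
    }, character(1))
    repNames <- vapply(coreIds, function(ci) pick(ci)$protein, character(1))
    rs <- AAStringSet(reps)
    names(rs) <- repNames
    cladeCores[[cl]] <- list(clusters = cls, core = coreIds,
                             members = members)
    coreReps[[cl]] <- rs
  }
  crossCls <- clusterOrthologs(coreReps, identityCutoff = identityAcross,
                               coverageCutoff = coverageMin)
  cm <- clusterMembers(crossCls)
  spanByCluster <- tapply(cm$genome, cm$cluster,
                          function(g) length(unique(g)))
  uniqueTabs <- list()
  for (cl in cladeIds) {
    own <- cm[cm$genome == cl, ]
    candidate <- own$protein[spanByCluster[as.character(own$cluster)] == 1L]
    if (!length(candidate)) next
    focal <- coreReps[[cl]][candidate]
    others <- lapply(genomes[cladeOf != cl], proteome)
    within <- lapply(genomes[cladeOf == cl], proteome)
    ut <- uniqueGenes(focal, within, others, coverageMin = coverageMin,
                      eStrict = eStrict, eFloor = eFloor)
    ut$clade <- cl
    uniqueTabs[[cl]] <- ut
  }
  uniqueTab <- if (length(uniqueTabs)) do.call(rbind, uniqueTabs) else NULL
  list(cladeCores = cladeCores, coreReps = coreReps, cross = crossCls,
       unique = uniqueTab)
}

#' Run the full synthetic-study analysis pipeline
#'
#' Orchestrates simulate -> composition -> pangenome -> phylogenomics ->
#' trait models -> physiology from one configuration. The pangenome stage
#' clusters each clade's proteome at `identityWithin`, takes clade cores
#' (single-copy in every member), links core representatives across clades
#' at `identityAcross`, and screens the clade-restricted candidates with
#' [uniqueGenes()]. The phylogenomics stage estimates species and gene
#' trees by neighbor joining on Poisson-corrected distances of the
#' fully-shared core families, scores branches with [geneConcordance()],
#' scans every genome for GC3 outliers and reports dN/dS of the implanted
#' transferred gene between its recipient clades. Trait models regress
#' genome size and Asp/Glu usage on collection temperature (PGLS with OU
#' correlation, OLS alongside). Physiology fits Platt curves, growth
#' windows, oxygen slopes and thermal performance summaries to the
#' generated measurements.
#'
#' Given the same config (including its seed) the run is deterministic.
#'
#' @param config a [syntheticConfig()].
#' @param inputDir optional directory holding a user-supplied genome bundle
#'   (see [readGenomeBundle()]); when given, the simulate stage is replaced
#'   by ingest and only the physiology measurements are generated from
#'   `config`.
#' @param outDir optional directory: per-stage TSVs plus `report.json` are
#'   written there.
#' @param identityWithin within-clade clustering identity cutoff (%).
#' @param identityAcross cross-clade core comparison cutoff (%).
#' @param coverageMin,eStrict,eFloor unique-gene screen thresholds.
#' @param zThreshold GC3 outlier threshold.
#' @return (invisibly) a list with `sim`, `composition`, `pangenome`,
#'   `phylo`, `traitModels`, `physiology` and the headline `report`.
#' @export
runAll <- function(config = syntheticConfig(), inputDir = NULL,
                   outDir = NULL,
                   identityWithin = 95, identityAcross = 70,
                   coverageMin = 50, eStrict = 1e-50, eFloor = 1e-10,
                   zThreshold = 3) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  sim <- if (is.null(inputDir)) stage("simulate", generateGenomes(config))
         else stage("ingest", readGenomeBundle(inputDir))
  genomes <- sim$genomes
  cladeOf <- vapply(genomes, clade, character(1))
  cladeIds <- sort(unique(cladeOf))

  comp <- stage("composition", compositionReport(genomes))

  pan <- stage("pangenome",
               pangenomeAnalysis(genomes, identityWithin = identityWithin,
                                 identityAcross = identityAcross,
                                 coverageMin = coverageMin,
                                 eStrict = eStrict, eFloor = eFloor))

  phylo <- stage("phylogenomics", {
    cm <- clusterMembers(pan$cross)
    spanByCluster <- tapply(cm$genome, cm$cluster,
                            function(g) length(unique(g)))
    shared <- as.integer(names(spanByCluster)[
      spanByCluster == length(cladeIds)])
    blocks <- list()
    for (ci in shared) {
      rows <- cm[cm$cluster == ci, ]
      seqs <- character()
      for (ri in seq_len(nrow(rows))) {
        cl <- rows$genome[ri]
        cc <- pan$cladeCores[[cl]]
        mem <- clusterMembers(cc$clusters)
        repCluster <- mem$cluster[mem$protein == rows$protein[ri]][1]
        fam <- mem[mem$cluster == repCluster, ]
        s <- vapply(seq_len(nrow(fam)), function(fi)
          as.character(proteome(genomes[[fam$genome[fi]]])[[fam$protein[fi]]]),
          character(1))
        names(s) <- fam$genome
        seqs <- c(seqs, s)
      }
      if (length(unique(nchar(seqs))) != 1L) next  # unalignable family
      b <- AAStringSet(seqs)
      blocks[[paste0("fam", ci)]] <- b
    }
    superm <- concatenateAlignments(blocks, taxa = names(genomes))
    D <- proteinDistance(superm)
    speciesTree <- njTree(D)
    geneTrees <- lapply(blocks, function(b) {
      njTree(proteinDistance(b))
    })
    support <- geneConcordance(speciesTree, geneTrees)
    scan <- do.call(rbind, lapply(genomes, function(g) {
      sc <- gc3OutlierScan(g, zThreshold = zThreshold)
      sc$strain <- strain(g)
      sc
    }))
    rownames(scan) <- NULL
    recips <- config$hgtRecipientClades
    dnds <- NULL
    if (length(recips) >= 2L) {
      g1 <- genomes[[which(cladeOf == as.character(recips[1]))[1]]]
      g2 <- genomes[[which(cladeOf == as.character(recips[2]))[1]]]
      c1 <- cdsSequences(g1)
      c2 <- cdsSequences(g2)
      h1 <- grep("_hgt", names(c1))
      h2 <- grep("_hgt", names(c2))
      if (length(h1) && length(h2))
        dnds <- neiGojobori(c1[[h1[1]]], c2[[h2[1]]])
    }
    list(speciesTree = speciesTree, geneTrees = geneTrees,
         support = support, gc3scan = scan, dnds = dnds,
         supermatrixWidth = nchar(as.character(superm)[1]))
  })

  tm <- stage("trait_models", {
    strains <- comp[!startsWith(comp$strain, "clade_mean:"), ]
    tr <- if (!is.null(sim$tree)) sim$tree else phylo$speciesTree
    fitSize <- pglsFit(genome_size ~ collection_temperature, strains, tr)
    fitAsp <- pglsFit(D ~ collection_temperature, strains, tr)
    fitGlu <- pglsFit(E ~ collection_temperature, strains, tr)
    list(size = fitSize, asp = fitAsp, glu = fitGlu)
  })

  phys <- stage("physiology", {
    pi <- generatePIData(config)
    key <- unique(pi[, c("strain", "assay_temperature")])
    platt <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
      d <- pi[pi$strain == key$strain[i] &
                pi$assay_temperature == key$assay_temperature[i], ]
      f <- plattFitNLS(d$irradiance, d$rate)
      data.frame(strain = key$strain[i],
                 assay_temperature = key$assay_temperature[i],
                 ps = f$ps, alpha = f$alpha, pm = f$pm,
                 true_ps = d$true_ps[1], true_alpha = d$true_alpha[1],
                 converged = f$converged, stringsAsFactors = FALSE)
    }))
    od <- generateODSeries(config)
    keyG <- unique(od[, c("strain", "temperature")])
    growth <- do.call(rbind, lapply(seq_len(nrow(keyG)), function(i) {
      d <- od[od$strain == keyG$strain[i] &
                od$temperature == keyG$temperature[i], ]
      f <- growthRate(d$time_h, d$od)
      data.frame(strain = keyG$strain[i], temperature = keyG$temperature[i],
                 mu = f$mu, generation_time = f$generation_time,
                 growth = f$growth, true_mu = d$true_mu[1],
                 stringsAsFactors = FALSE)
    }))
    thermal <- do.call(rbind, lapply(split(growth, growth$strain),
                                     function(d) {
      tp <- thermalPerformance(d$temperature,
                               ifelse(d$growth, d$mu, NA_real_))
      data.frame(strain = d$strain[1], topt = tp$topt, ctmax = tp$ctmax,
                 niche_breadth = tp$niche_breadth, stringsAsFactors = FALSE)
    }))
    o2 <- generateO2Traces(config)
    o2rates <- vapply(split(o2, o2$trace), function(d)
      oxygenSlope(d$time_s, d$o2), numeric(1))
    list(pi = pi, platt = platt, growth = growth, thermal = thermal,
         o2 = o2rates)
  })

  # headline report
  strainsComp <- comp[!startsWith(comp$strain, "clade_mean:"), ]
  uniqTab <- pan$unique
  uniqueByClade <- if (!is.null(uniqTab))
    tapply(uniqTab$unique, uniqTab$clade, sum) else integer()
  falseUniqueCore <- if (!is.null(uniqTab))
    sum(uniqTab$unique & grepl("_core", uniqTab$gene)) else 0L
  hgtScan <- phylo$gc3scan[grepl("_hgt", phylo$gc3scan$gene), ]
  report <- list(
    seed = config$seed,
    n_strains = length(genomes),
    n_clades = length(cladeIds),
    supermatrix_width = phylo$supermatrixWidth,
    size_pgls_slope = tm$size$coefficients["collection_temperature",
                                           "estimate"],
    size_pgls_F = tm$size$F,
    size_pgls_p = tm$size$p.value,
    size_pgls_alpha = tm$size$alpha,
    asp_slope_per_5C = 5 * tm$asp$coefficients["collection_temperature",
                                               "estimate"],
    glu_slope_per_5C = 5 * tm$glu$coefficients["collection_temperature",
                                               "estimate"],
    unique_genes_by_clade = as.list(uniqueByClade),
    false_unique_core_calls = falseUniqueCore,
    hgt_genes_flagged = if (nrow(hgtScan)) mean(hgtScan$outlier) else NA,
    hgt_mean_abs_z = if (nrow(hgtScan)) mean(abs(hgtScan$z)) else NA,
    hgt_dnds = if (!is.null(phylo$dnds)) phylo$dnds$ratio else NA,
    mean_gcf = mean(phylo$support$gcf, na.rm = TRUE),
    mean_ic = mean(phylo$support$ic, na.rm = TRUE))

  out <- list(sim = sim, composition = comp, pangenome = pan, phylo = phylo,
              traitModels = tm, physiology = phys, report = report)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) write.table(d, file.path(outDir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(comp, "composition.tsv")
    wt(comp[startsWith(comp$strain, "clade_mean:"), ],
       "composition_heatmap.tsv")
    wt(clusterMembers(pan$cross), "clusters.tsv")
    if (!is.null(uniqTab)) wt(uniqTab, "unique_genes.tsv")
    wt(phylo$support, "branch_support.tsv")
    wt(phylo$gc3scan, "gc3_outliers.tsv")
    wt(phys$platt, "platt_fits.tsv")
    wt(phys$growth, "growth_fits.tsv")
    wt(phys$thermal, "thermal_summary.tsv")
    pg <- do.call(rbind, lapply(names(tm), function(nm) {
      f <- tm[[nm]]
      data.frame(model = nm,
                 slope = f$coefficients["collection_temperature", "estimate"],
                 se = f$coefficients["collection_temperature", "se"],
                 F = f$F, df1 = f$df1, df2 = f$df2, p = f$p.value,
                 alpha = f$alpha, r2 = f$r.squared,
                 stringsAsFactors = FALSE)
    }))
    wt(pg, "pgls_results.tsv")
    cat(writeNewick(phylo$speciesTree),
        file = file.path(outDir, "species_tree_estimated.nwk"), sep = "\n")
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
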