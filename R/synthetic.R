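#' Configuration for the synthetic thermal-gradient study
#'
#' Defaults emulate the structure of a six-clade thermophilic cyanobacterial
#' radiation along a hot-spring gradient: clades ordered by collection
#' temperature, genome size declining with temperature, a clade-specific GC
#' offset for the coolest clade, aspartate lost (and glutamate gained) with
#' increasing temperature, one horizontally transferred gene restricted to
#' the two hottest clades with donor-like GC3, and Platt-shaped
#' photosynthesis-irradiance data at the 13-point assay design. Genome sizes
#' are desk-scale (tens of kb) so the full pipeline runs in seconds; the
#' statistical structure, not the absolute scale, is what downstream
#' analyses consume.
#'
#' @param seed integer seed; every generator is a pure function of
#'   `(config, seed)`.
#' @param nClades,taxaPerClade clade structure (default 6 x 8 = 48 strains).
#' @param cladeTemperatures strictly increasing clade temperatures (degrees
#'   C).
#' @param tempJitter half-width of the uniform per-strain jitter around the
#'   clade temperature.
#' @param genomeSizeAt55,genomeSizeSlope,genomeSizeNoiseSd expected genome
#'   size (bp) at 55 degrees C, its slope in bp per degree C (negative), and
#'   the Gaussian noise SD.
#' @param cladeGC per-clade intergenic/genomic GC fraction targets.
#' @param cladeGC3 per-clade third-codon-position GC targets for host genes.
#' @param rnaGCTarget per-clade GC of structural RNA genes.
#' @param aspSlopePer5C relative change (%) in aspartate usage per 5 degrees
#'   C (negative); implemented as deterministic Asp-to-Glu replacement, so
#'   glutamate gains mirror aspartate losses.
#' @param nCoreGenes,coreGeneLen core gene families shared by all strains
#'   and their protein length (residues).
#' @param nCladeUniqueGenes,uniqueGeneLen clade-private gene families (drawn
#'   from independent random sequence, so they share no detectable
#'   similarity across clades).
#' @param cladeDivergence,strainDivergence fraction of protein positions
#'   shuffled between the root and a clade ancestor, and between a clade
#'   ancestor and a strain (composition-preserving divergence).
#' @param hgtDonorGC3Offset,hgtRecipientClades,hgtGeneLen the implanted
#'   horizontally transferred gene: GC3 offset of the donor relative to the
#'   host target, recipient clade indices, protein length.
#' @param hgtSynDivergence per-strain fraction of transferred-gene codons
#'   receiving a synonymous substitution (recent transfer under purifying
#'   selection: shared donor codons, small dS, near-zero dN).
#' @param nRRNA,rrnaLen,nTRNA,trnaLen structural RNA features per genome.
#' @param assayTemperatures,piNoiseSd,nPiReplicates P-I assay design.
#' @param ouAlpha,ouSigma Ornstein-Uhlenbeck parameters for trait
#'   simulation on the tree.
#' @return a list of class `"SyntheticConfig"` (validated).
#' @export
syntheticConfig <- function(seed = 1L,
                            nClades = 6L,
                            taxaPerClade = 8L,
                            cladeTemperatures = c(55, 57, 60, 63, 68, 71),
                            tempJitter = 1,
                            genomeSizeAt55 = 30000,
                            genomeSizeSlope = -250,
                            genomeSizeNoiseSd = 400,
                            cladeGC = c(0.585, 0.603, 0.605, 0.607, 0.604,
                                        0.606),
                            cladeGC3 = c(0.52, 0.58, 0.58, 0.59, 0.575,
                                         0.58),
                            rnaGCTarget = c(0.59, 0.59, 0.59, 0.59, 0.60,
                                            0.60),
                            aspSlopePer5C = -1.6,
                            nCoreGenes = 18L,
                            coreGeneLen = 120L,
                            nCladeUniqueGenes = 3L,
                            uniqueGeneLen = 110L,
                            cladeDivergence = 0.08,
                            strainDivergence = 0.01,
                            hgtDonorGC3Offset = 0.25,
                            hgtRecipientClades = c(5L, 6L),
                            hgtGeneLen = 150L,
                            hgtSynDivergence = 0.02,
                            nRRNA = 1L,
                            rrnaLen = 600L,
                            nTRNA = 2L,
                            trnaLen = 80L,
                            assayTemperatures = c(45, 55, 60, 70),
                            piNoiseSd = 0.05,
                            nPiReplicates = 3L,
                            ouAlpha = 2,
                            ouSigma = 1) {
  cfg <- as.list(environment())
  stopifnot(nClades >= 2L, taxaPerClade >= 1L)
  if (length(cladeTemperatures) != nClades ||
      any(diff(cladeTemperatures) <= 0))
    stop("cladeTemperatures must be strictly increasing, one per clade")
  maxT <- max(cladeTemperatures)
  if (genomeSizeAt55 + genomeSizeSlope * (maxT - 55) <= 0)
    stop("genome size non-positive at the hottest clade")
  for (nm in c("cladeGC", "cladeGC3", "rnaGCTarget"))
    if (length(cfg[[nm]]) != nClades)
      stop(sprintf("%s must have one value per clade", nm))
  fmax <- abs(aspSlopePer5C) / 100 * (maxT - min(cladeTemperatures)) / 5
  if (fmax >= 1)
    stop("aspartate replacement fraction reaches 1 across the gradient; infeasible composition target")
  if (piNoiseSd < 0) stop("negative noise sd")
  if (any(hgtRecipientClades > nClades))
    stop("hgtRecipientClades out of range")
  class(cfg) <- "SyntheticConfig"
  cfg
}

# baseline proteome amino-acid frequencies (percent, heat-map midpoints of a
# moderately thermophilic cyanobacterial proteome), renormalised
.baseAAFreq <- function() {
  f <- c(D = 4.5, E = 6.2, R = 7.25, K = 2.95, L = 12.65, I = 4.65,
         V = 7.05, M = 1.75, F = 3.45, W = 1.75, Y = 2.65, A = 10.0,
         S = 5.55, T = 4.65, Q = 5.65, N = 2.45, H = 1.95, C = 1.05,
         P = 6.35, G = 7.85)
  f / sum(f)
}

# random protein from the frequency profile, with a leading Met
.sampleProteinMulti <- function(len, freq) {
  c("M", sample(names(freq), len - 1L, replace = TRUE, prob = freq))
}

# composition-identical but homology-free copy: full permutation of the body
.permuteProtein <- function(aa) {
  c(aa[1], sample(aa[-1]))
}

# protein with exact largest-remainder residue counts (used for the
# transferred gene, so its insertion shifts recipient-clade composition
# identically rather than by multinomial luck)
.sampleProteinExact <- function(len, freq) {
  n <- len - 1L
  counts <- floor(freq * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- freq * n - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  c("M", sample(rep(names(freq), counts)))
}

# composition-preserving divergence: cyclically rotate a random subset of
# positions
.shuffleMutate <- function(aa, frac) {
  k <- round(frac * length(aa))
  if (k < 2L) return(aa)
  pos <- sample(seq_along(aa), k)
  aa[pos] <- aa[c(pos[-1], pos[1])]
  aa
}

.CODON_SETS <- NULL
.codonSets <- function() {
  if (is.null(.CODON_SETS)) {
    gc <- Biostrings::GENETIC_CODE
    sets <- lapply(setdiff(unique(gc), "*"), function(aa) {
      cods <- names(gc)[gc == aa]
      third <- substr(cods, 3, 3)
      list(gcEnd = cods[third %in% c("G", "C")],
           atEnd = cods[third %in% c("A", "T")])
    })
    names(sets) <- setdiff(unique(gc), "*")
    utils::assignInMyNamespace(".CODON_SETS", sets)
  }
  .CODON_SETS
}

# back-translate with per-gene exact GC3 control: the fraction of GC-ending
# codons among GC3-free amino acids is solved so the whole gene hits the
# target; Met/Trp are obligate-G and enter the calibration
.backTranslate <- function(aa, gc3Target, asCodons = FALSE) {
  sets <- .codonSets()
  tab <- table(aa)
  pMW <- sum(tab[names(tab) %in% c("M", "W")]) / length(aa)
  q <- (gc3Target - pMW) / (1 - pMW)
  q <- min(max(q, 0), 1)
  codons <- character(length(aa))
  for (a in names(tab)) {
    pos <- which(aa == a)
    st <- sets[[a]]
    if (!length(st$atEnd)) {
      codons[pos] <- sample(st$gcEnd, length(pos), replace = TRUE)
    } else if (!length(st$gcEnd)) {
      codons[pos] <- sample(st$atEnd, length(pos), replace = TRUE)
    } else {
      nGC <- round(q * length(pos))
      gcPos <- if (nGC > 0) sample(pos, nGC) else integer()
      codons[gcPos] <- sample(st$gcEnd, length(gcPos), replace = TRUE)
      rest <- setdiff(pos, gcPos)
      codons[rest] <- sample(st$atEnd, length(rest), replace = TRUE)
    }
  }
  if (asCodons) return(codons)
  paste(c(codons, "TAA"), collapse = "")
}

# one codon for amino acid `a`, GC-ending with probability q
.codonFor <- function(a, q) {
  st <- .codonSets()[[a]]
  if (!length(st$atEnd)) return(sample(st$gcEnd, 1))
  if (!length(st$gcEnd)) return(sample(st$atEnd, 1))
  if (stats::runif(1) < q) sample(st$gcEnd, 1) else sample(st$atEnd, 1)
}

.randomDNA <- function(len, gc) {
  if (len <= 0L) return("")
  paste(sample(c("G", "C", "A", "T"), len, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

.strainName <- function(cl, s) sprintf("c%d_s%d", cl, s)

#' Clade-ladder species tree for the synthetic study
#'
#' A pectinate backbone of clades ordered by temperature (coolest clade
#' basal, hotter clades successively nested) with random coalescent
#' subtrees inside each clade. Deterministic given the config seed.
#'
#' @param config a [syntheticConfig()].
#' @return an `ape::phylo` with positive branch lengths.
#' @export
generateTree <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (config$taxaPerClade < 1L) stop("taxaPerClade must be >= 1")
  set.seed(config$seed)
  subNewick <- vapply(seq_len(config$nClades), function(cl) {
    labs <- vapply(seq_len(config$taxaPerClade), function(s)
      .strainName(cl, s), character(1))
    if (length(labs) == 1L) return(sprintf("%s:0.02", labs))
    tr <- ape::rcoal(length(labs), tip.label = labs)
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) *
      0.02
    sub(";$", "", ape::write.tree(tr))
  }, character(1))
  # nest hotter clades inside: coolest basal
  nw <- subNewick[config$nClades]
  for (cl in rev(seq_len(config$nClades - 1L))) {
    nw <- sprintf("(%s:0.05,%s:0.05)", subNewick[cl], nw)
  }
  ape::read.tree(text = paste0(nw, ";"))
}

#' Generate clade-structured genomes and the strain trait table
#'
#' Core gene families are shared by all strains and diverged by
#' composition-preserving shuffling (so every strain's baseline amino-acid
#' composition is identical before the temperature-dependent Asp-to-Glu
#' replacement is applied); clade-unique families are per-clade random
#' permutations of shared composition templates, so they carry the same
#' residue pool but no detectable cross-clade similarity; the horizontally
#' transferred
#' gene is inserted into the recipient clades with donor-like GC3 and is
#' exempt from the host composition gradient. Genome length is padded with
#' intergenic sequence at the clade GC to hit the configured
#' size-temperature trend plus seeded noise.
#'
#' @param config a [syntheticConfig()].
#' @param tree optional species tree (defaults to [generateTree()]); clade
#'   structure, not individual branch lengths, drives sequence divergence.
#' @return list with `genomes` (list of [GenomeRecord-class]), `traits`
#'   (strain/clade/collection_temperature/genome_size `data.frame`) and
#'   `tree`.
#' @export
generateGenomes <- function(config, tree = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (is.null(tree)) tree <- generateTree(config)
  set.seed(config$seed + 1000L)
  freq <- .baseAAFreq()
  minT <- min(config$cladeTemperatures)

  rootCore <- lapply(seq_len(config$nCoreGenes), function(i)
    .sampleProteinMulti(config$coreGeneLen, freq))
  cladeCoreAnc <- lapply(seq_len(config$nClades), function(cl)
    lapply(rootCore, .shuffleMutate, frac = config$cladeDivergence))
  # clade-unique families: permutations of shared composition templates, so
  # every clade carries the same residue pool but no cross-clade similarity
  uniqueTemplates <- lapply(seq_len(config$nCladeUniqueGenes), function(i)
    .sampleProteinMulti(config$uniqueGeneLen, freq))
  cladeUniqueAnc <- lapply(seq_len(config$nClades), function(cl)
    lapply(uniqueTemplates, .permuteProtein))
  # transferred gene: exact counts from the realized host residue pool, so
  # inserting it shifts recipient-clade composition identically and only
  # marginally (its signature is the donor-like GC3, not the residues)
  pool <- table(unlist(c(rootCore, uniqueTemplates)))
  pool <- pool[names(pool) %in% names(freq)]
  poolFreq <- stats::setNames(as.numeric(pool) / sum(pool), names(pool))
  poolFreq <- poolFreq[names(freq)]
  poolFreq[is.na(poolFreq)] <- 0
  names(poolFreq) <- names(freq)
  hgtProtein <- .sampleProteinExact(config$hgtGeneLen, poolFreq)
  gc3Donor <- min(max(mean(config$cladeGC3[config$hgtRecipientClades]) +
                        config$hgtDonorGC3Offset, 0.02), 0.98)
  hgtCodons <- .backTranslate(hgtProtein, gc3Donor, asCodons = TRUE)

  genomes <- list()
  traitRows <- list()
  for (cl in seq_len(config$nClades)) {
    cladeT <- config$cladeTemperatures[cl]
    for (s in seq_len(config$taxaPerClade)) {
      sname <- .strainName(cl, s)
      temp <- cladeT + stats::runif(1, -config$tempJitter, config$tempJitter)
      swapFrac <- abs(config$aspSlopePer5C) / 100 * (temp - minT) / 5

      hostProteins <- list()
      geneNames <- character()
      isHgt <- logical()
      for (i in seq_len(config$nCoreGenes)) {
        p <- .shuffleMutate(cladeCoreAnc[[cl]][[i]],
                            config$strainDivergence)
        hostProteins[[length(hostProteins) + 1L]] <- p
        geneNames <- c(geneNames, sprintf("%s_core%02d", sname, i))
        isHgt <- c(isHgt, FALSE)
      }
      for (i in seq_len(config$nCladeUniqueGenes)) {
        p <- .shuffleMutate(cladeUniqueAnc[[cl]][[i]],
                            config$strainDivergence)
        hostProteins[[length(hostProteins) + 1L]] <- p
        geneNames <- c(geneNames, sprintf("%s_uniq%02d", sname, i))
        isHgt <- c(isHgt, FALSE)
      }
      if (cl %in% config$hgtRecipientClades) {
        p <- .shuffleMutate(hgtProtein, config$strainDivergence / 2)
        hostProteins[[length(hostProteins) + 1L]] <- p
        geneNames <- c(geneNames, sprintf("%s_hgt01", sname))
        isHgt <- c(isHgt, TRUE)
      }
      # Asp -> Glu replacement pooled over the host proteome, so the swap
      # count is deterministic in temperature even when per-gene Asp counts
      # are small
      hostIdx <- which(!isHgt)
      dPos <- do.call(rbind, lapply(hostIdx, function(i) {
        w <- which(hostProteins[[i]] == "D")
        if (length(w)) cbind(i, w) else NULL
      }))
      k <- round(swapFrac * NROW(dPos))
      if (k > 0L) {
        pick <- dPos[sample(NROW(dPos), k), , drop = FALSE]
        for (r in seq_len(NROW(pick)))
          hostProteins[[pick[r, 1]]][pick[r, 2]] <- "E"
      }

      gc3Host <- config$cladeGC3[cl]
      cdsSeqs <- vapply(seq_along(hostProteins), function(i) {
        if (isHgt[i]) {
          # recent transfer: shared donor codons, a few synonymous tweaks,
          # codon replacement only where the protein itself drifted
          p <- hostProteins[[i]]
          cod <- hgtCodons
          changed <- which(p != hgtProtein)
          for (ii in changed) cod[ii] <- .codonFor(p[ii], gc3Donor)
          nSyn <- round(config$hgtSynDivergence * length(cod))
          free <- setdiff(seq_along(cod), changed)
          if (nSyn > 0 && length(free)) {
            for (ii in sample(free, min(nSyn, length(free))))
              cod[ii] <- .codonFor(p[ii], gc3Donor)
          }
          paste(c(cod, "TAA"), collapse = "")
        } else {
          .backTranslate(hostProteins[[i]], gc3Host)
        }
      }, character(1))
      cdsSeqs <- vapply(cdsSeqs, function(s) paste0("ATG", s), character(1))
      names(cdsSeqs) <- geneNames

      rnaSeqs <- c(
        vapply(seq_len(config$nRRNA), function(i)
          .randomDNA(config$rrnaLen, config$rnaGCTarget[cl]), character(1)),
        vapply(seq_len(config$nTRNA), function(i)
          .randomDNA(config$trnaLen, config$rnaGCTarget[cl]), character(1)))
      rnaNames <- c(sprintf("%s_rrna%02d", sname, seq_len(config$nRRNA)),
                    sprintf("%s_trna%02d", sname, seq_len(config$nTRNA)))
      rnaTypes <- c(rep("rRNA", config$nRRNA), rep("tRNA", config$nTRNA))

      allSeqs <- c(cdsSeqs, stats::setNames(rnaSeqs, rnaNames))
      allTypes <- c(rep("CDS", length(cdsSeqs)), rnaTypes)
      geneLen <- sum(nchar(allSeqs))
      targetSize <- round(config$genomeSizeAt55 +
                            config$genomeSizeSlope * (temp - 55) +
                            stats::rnorm(1, 0, config$genomeSizeNoiseSd))
      nGaps <- length(allSeqs) + 1L
      spare <- targetSize - geneLen
      if (spare < 2L * nGaps)
        stop("genome size target too small for the configured gene content")
      gapBase <- spare %/% nGaps
      gaps <- rep(gapBase, nGaps)
      gaps[nGaps] <- gaps[nGaps] + (spare - gapBase * nGaps)

      pieces <- character(0)
      starts <- integer(length(allSeqs))
      ends <- integer(length(allSeqs))
      strands <- rep(c("+", "-"), length.out = length(allSeqs))
      pos <- 0L
      for (i in seq_along(allSeqs)) {
        gapSeq <- .randomDNA(gaps[i], config$cladeGC[cl])
        pieces <- c(pieces, gapSeq)
        pos <- pos + gaps[i]
        starts[i] <- pos + 1L
        sq <- allSeqs[[i]]
        if (strands[i] == "-")
          sq <- as.character(reverseComplement(Biostrings::DNAString(sq)))
        pieces <- c(pieces, sq)
        pos <- pos + nchar(sq)
        ends[i] <- pos
      }
      pieces <- c(pieces, .randomDNA(gaps[nGaps], config$cladeGC[cl]))
      contig <- DNAStringSet(paste(pieces, collapse = ""))
      names(contig) <- paste0(sname, "_ctg1")

      gr <- GRanges(names(contig),
                    IRanges(starts, ends), strand = strands)
      GenomeInfoDb::seqlengths(gr) <- width(contig)
      mcols(gr)$type <- allTypes
      mcols(gr)$feature_id <- names(allSeqs)
      mcols(gr)$phase <- ifelse(allTypes == "CDS", 0L, NA_integer_)

      prot <- AAStringSet(vapply(hostProteins, paste, character(1),
                                 collapse = ""))
      names(prot) <- geneNames

      genomes[[sname]] <- GenomeRecord(sname, contig, gr, prot,
                                       clade = as.character(cl),
                                       collectionTemperature = temp)
      traitRows[[sname]] <- data.frame(
        strain = sname, clade = as.character(cl),
        collection_temperature = temp,
        genome_size = sum(width(contig)), stringsAsFactors = FALSE)
    }
  }
  traits <- do.call(rbind, traitRows)
  rownames(traits) <- NULL
  list(genomes = genomes, traits = traits, tree = tree)
}

#' Simulate a trait on a tree with OU-correlated noise
#'
#' `y = intercept + slope * predictor + e`, `e ~ N(0, sigma^2 C)` with
#' `C = exp(-alpha * patristic distance)`.
#'
#' @param tree `ape::phylo`.
#' @param predictor named numeric vector (names = tip labels).
#' @param intercept,slope regression coefficients.
#' @param alpha,sigma OU correlation strength and noise SD.
#' @param seed RNG seed.
#' @return `data.frame` with `strain`, `predictor`, `y`.
#' @export
simulateTraitOU <- function(tree, predictor, intercept = 0, slope = 0,
                            alpha = 2, sigma = 1, seed = 1L) {
  set.seed(seed)
  tips <- tree$tip.label
  stopifnot(all(tips %in% names(predictor)))
  C <- ouCorrelation(tree, alpha)
  L <- chol(C[tips, tips])
  e <- sigma * as.numeric(t(L) %*% stats::rnorm(length(tips)))
  data.frame(strain = tips, predictor = unname(predictor[tips]),
             y = intercept + slope * unname(predictor[tips]) + e,
             stringsAsFactors = FALSE)
}

# clade-representative Platt parameters for the assay design: performance
# peaks near the clade's thermal home; the hottest clades trade maximal rate
# for thermal reach
.plattTruth <- function(cladeT, assayT) {
  ps <- 10 * exp(-((assayT - cladeT) / 18)^2) *
    (1 - 0.25 * (cladeT - 55) / 16)
  alpha <- 0.08 * exp(-((assayT - cladeT) / 25)^2) *
    (1 - 0.3 * (cladeT - 55) / 16)
  c(ps = ps, alpha = alpha)
}

#' Synthetic photosynthesis-irradiance measurements
#'
#' One representative strain per clade, assayed at the configured
#' temperatures over the 13-point irradiance design with Gaussian replicate
#' noise proportional to the scale parameter. `noiseSd = 0` puts every
#' point exactly on the Platt curve.
#'
#' @param config a [syntheticConfig()].
#' @param noiseSd relative noise SD (defaults to `config$piNoiseSd`).
#' @return `data.frame`: strain, clade, assay_temperature, replicate,
#'   irradiance, rate, plus the true `ps`/`alpha` used.
#' @export
generatePIData <- function(config, noiseSd = config$piNoiseSd) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (noiseSd < 0) stop("negative noise sd")
  set.seed(config$seed + 2000L)
  II <- piIrradiances()
  rows <- list()
  for (cl in seq_len(config$nClades)) {
    sname <- .strainName(cl, 1L)
    for (aT in config$assayTemperatures) {
      tru <- .plattTruth(config$cladeTemperatures[cl], aT)
      if (tru["ps"] < 0.05) next  # effectively no activity at this assay temp
      for (rep_ in seq_len(config$nPiReplicates)) {
        mu <- plattModel(II, tru["ps"], tru["alpha"])
        rate <- mu + stats::rnorm(length(II), 0, noiseSd * tru["ps"])
        rows[[length(rows) + 1L]] <- data.frame(
          strain = sname, clade = as.character(cl),
          assay_temperature = aT, replicate = rep_,
          irradiance = II, rate = rate,
          true_ps = unname(tru["ps"]), true_alpha = unname(tru["alpha"]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Synthetic OD750 growth series
#'
#' Lag / exponential / plateau segments sampled every 48 h; the exponential
#' segment has the clade- and temperature-dependent specific growth rate.
#'
#' @param config a [syntheticConfig()].
#' @param odNoiseSd multiplicative log-normal noise SD on OD (0 = exact).
#' @return `data.frame`: strain, clade, temperature, time_h, od, true_mu.
#' @export
generateODSeries <- function(config, odNoiseSd = 0.02) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (odNoiseSd < 0) stop("negative noise sd")
  set.seed(config$seed + 3000L)
  rows <- list()
  times <- seq(0, 48 * 9, by = 48)
  for (cl in seq_len(config$nClades)) {
    sname <- .strainName(cl, 1L)
    cladeT <- config$cladeTemperatures[cl]
    growT <- seq(cladeT - 10, cladeT + 5, by = 5)
    for (Tq in growT) {
      mu <- 0.03 * exp(-((Tq - cladeT) / 8)^2) *
        (1 - 0.3 * (cladeT - 55) / 16)
      if (Tq > cladeT + 3) mu <- 0  # above the strain's thermal limit
      od0 <- 0.005
      lagEnd <- 48
      od <- vapply(times, function(tt) {
        if (mu == 0) return(od0)
        te <- max(tt - lagEnd, 0)
        pmin(od0 * exp(mu * te), 0.6)
      }, numeric(1))
      od <- od * exp(stats::rnorm(length(od), 0, odNoiseSd))
      rows[[length(rows) + 1L]] <- data.frame(
        strain = sname, clade = as.character(cl), temperature = Tq,
        time_h = times, od = od, true_mu = mu, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Synthetic oxygen micro-sensor traces
#'
#' Linear O2 accumulation plus Gaussian noise over a 0-15 s light step,
#' sampled at 1 s.
#'
#' @param config a [syntheticConfig()].
#' @param slopes true slopes (umol O2 L^-1 s^-1), one trace per element.
#' @param noiseFrac noise SD as a fraction of the trace range.
#' @return `data.frame`: trace, time_s, o2, true_slope.
#' @export
generateO2Traces <- function(config, slopes = c(0.01, 0.02, 0.05),
                             noiseFrac = 0.01) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (noiseFrac < 0) stop("negative noise sd")
  set.seed(config$seed + 4000L)
  tt <- 0:15
  do.call(rbind, lapply(seq_along(slopes), function(i) {
    o2 <- 250 + slopes[i] * tt
    o2 <- o2 + stats::rnorm(length(tt), 0, noiseFrac * diff(range(o2)))
    data.frame(trace = i, time_s = tt, o2 = o2, true_slope = slopes[i])
  }))
}

#' Write a synthetic study to disk as FASTA/GFF3/Newick/TSV
#'
#' @param sim result of [generateGenomes()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeGenomeBundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in sim$genomes) {
    base <- file.path(dir, strain(g))
    writeFasta(contigs(g), paste0(base, ".fna"))
    writeFasta(proteome(g), paste0(base, ".faa"))
    writeGff3(features(g), paste0(base, ".gff3"))
  }
  ape::write.tree(sim$tree, file.path(dir, "species_tree.nwk"))
  write.table(sim$traits, file.path(dir, "traits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
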