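# Synthetic-data module: reference genomes with CpG islands, mutation
# catalogs drawn from 96-class signature mixtures with a controlled
# island-core rate elevation, and whole-cohort emulation profiles.
#
# Sequences are assembled from dinucleotide tiles: with probability q a tile
# is the literal "CG", otherwise two independent draws from the segment's
# base composition with every accidental CG (within a tile or across a tile
# boundary) broken by replacing the G. CpG-start frequency per position is
# therefore q/2 by construction, which makes the island-to-background CpG
# ratio a direct parameter.
#
# Mutations are placed class-first, site-second: a 96-class is drawn from
# the mixture, then a genomic site is drawn uniformly among the positions
# whose pyrimidine-strand trinucleotide matches the class context, with
# island-core positions up- or down-weighted by a factor calibrated (per
# genome and mixture, by root finding) so that the EXPECTED pooled
# core-to-flank mutation-rate ratio equals `islandMultiplier`. The catalog's
# 96-class distribution therefore equals the mixture exactly in expectation,
# and the enrichment pipeline's fold estimator targets the multiplier even
# though CpG-rich cores and CpG-poor flanks differ in trinucleotide
# composition.

BASES4 <- c("A", "C", "G", "T")

# one sequence segment as a character vector of single bases
tileSegment <- function(len, comp, cpgTileProb) {
  nT <- ceiling(len / 2)
  isCG <- stats::runif(nT) < cpgTileProb
  b1 <- sample(BASES4, nT, replace = TRUE, prob = comp)
  b2 <- sample(BASES4, nT, replace = TRUE, prob = comp)
  b1[isCG] <- "C"; b2[isCG] <- "G"
  acc <- !isCG & b1 == "C" & b2 == "G"
  b2[acc] <- "A"
  if (nT > 1L) {
    j <- which(b2[-nT] == "C" & b1[-1L] == "G")
    b1[j + 1L] <- "A"
  }
  out <- character(2L * nT)
  out[c(TRUE, FALSE)] <- b1
  out[c(FALSE, TRUE)] <- b2
  out[seq_len(len)]
}

#' Simulate a reference genome with CpG islands
#'
#' Builds one chromosome of CpG-depleted background sequence with evenly
#' spaced CpG-dense islands, returning the genome and the island annotation.
#' Islands are spaced so that core and flank windows never collide with the
#' chromosome edges or each other in the default profiles. Deterministic
#' given \code{seed}.
#'
#' @param length chromosome length (bp).
#' @param nIslands,islandLength island count and length (bp).
#' @param backgroundComp,islandComp base compositions (named A/C/G/T probs).
#' @param backgroundCpg,islandCpg CpG tile probabilities; the per-position
#'   CpG-start frequency is half the tile probability.
#' @param chrom chromosome name.
#' @param seed integer seed (\code{NULL}: use the current RNG stream).
#' @return list: \code{genome} (a \linkS4class{ReferenceGenome}),
#'   \code{islands} (\code{GRanges}).
#' @export
simulateGenome <- function(length = 1e6, nIslands = 20, islandLength = 1000,
                           backgroundComp = c(A = 0.30, C = 0.20, G = 0.20, T = 0.30),
                           islandComp = c(A = 0.17, C = 0.33, G = 0.33, T = 0.17),
                           backgroundCpg = 0.02, islandCpg = 0.10,
                           chrom = "1", seed = NULL) {
  spacing <- floor(length / nIslands)
  stopifnot2(spacing - islandLength >= 4000,
             "island geometry overflow: spacing must leave >= 2 kb on each side")
  withSeed(seed, {
    chars <- tileSegment(length, backgroundComp[BASES4], backgroundCpg)
    starts <- (seq_len(nIslands) - 1L) * spacing +
      floor((spacing - islandLength) / 2) + 1L
    for (s in starts) {
      e <- s + islandLength - 1L
      chars[s:e] <- tileSegment(islandLength, islandComp[BASES4], islandCpg)
      # break CpGs straddling the splice junctions
      if (chars[s - 1L] == "C" && chars[s] == "G") chars[s] <- "A"
      if (chars[e] == "C" && chars[e + 1L] == "G") chars[e + 1L] <- "A"
    }
    seqs <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(seqs) <- chrom
    islands <- GenomicRanges::GRanges(chrom,
                                      IRanges::IRanges(starts, width = islandLength))
    list(genome = methods::new("ReferenceGenome", sequences = seqs),
         islands = GenomicRanges::reduce(islands))
  })
}

# site index: every genomic position with a fully determined pyrimidine-
# strand trinucleotide, grouped by the 32 contexts and split into
# island-core / non-core (and flank membership for calibration)
siteIndex <- function(genome, windows) {
  ctxNames <- pyrimidineContexts()
  corePos <- vector("list", 32L); otherPos <- vector("list", 32L)
  nFlank <- numeric(32L)
  chromOf <- list(core = character(0))
  chroms <- names(genome@sequences)
  coreL <- vector("list", length(chroms)); otherL <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    codes <- match(strsplit(chromString(genome, ch), "")[[1]], BASES4)
    L <- length(codes)
    if (L < 3L) next
    ctr <- codes[2:(L - 1L)]; up <- codes[1:(L - 2L)]; dn <- codes[3:L]
    flip <- ctr == 1L | ctr == 3L
    r <- ifelse(flip, 5L - ctr, ctr)              # 2 = C, 4 = T
    p <- ifelse(flip, 5L - dn, up)
    q <- ifelse(flip, 5L - up, dn)
    ctx <- (r == 4L) * 16L + (p - 1L) * 4L + q    # 1..32
    pos <- 2:(L - 1L)
    ok <- !is.na(ctx)
    pos <- pos[ok]; ctx <- ctx[ok]
    ir <- IRanges::IRanges(pos, width = 1L)
    core <- windows@core[GenomicRanges::seqnames(windows@core) == ch]
    flank <- windows@flank[GenomicRanges::seqnames(windows@flank) == ch]
    inCore <- IRanges::overlapsAny(ir, GenomicRanges::ranges(core))
    inFlank <- IRanges::overlapsAny(ir, GenomicRanges::ranges(flank))
    coreL[[ci]] <- split(pos[inCore], factor(ctx[inCore], levels = 1:32))
    otherL[[ci]] <- split(pos[!inCore], factor(ctx[!inCore], levels = 1:32))
    nFlank <- nFlank + tabulate(ctx[inFlank], nbins = 32L)
  }
  list(chroms = chroms, coreL = coreL, otherL = otherL, nFlank = nFlank,
       nCore = vapply(1:32, function(c)
       sum(vapply(coreL, function(x) length(x[[c]]), numeric(1))), numeric(1)),
       nOther = vapply(1:32, function(c)
       sum(vapply(otherL, function(x) length(x[[c]]), numeric(1))), numeric(1)),
       coreBp = windows@coreBp, flankBp = windows@flankBp)
}

# Per-context core weights such that EVERY context's expected core-to-flank
# rate ratio equals the multiplier:
#   (w_c n_core_c / coreBp) / (n_flank_c / flankBp) = m
# This makes the pooled fold equal m in expectation for any mixture, and
# keeps the core-window class composition matched to the flank composition
# (a raw positional multiplier would instead pile NCG-class mutations into
# the CpG-dense cores and confound the fold with trinucleotide composition).
# Contexts absent from core or flank keep weight 1 (placement unchanged).
calibrateCoreWeight <- function(multiplier, idx) {
  w <- rep(1, 32L)
  ok <- idx$nCore > 0 & idx$nFlank > 0
  w[ok] <- multiplier * (idx$nFlank[ok] / idx$flankBp) /
    (idx$nCore[ok] / idx$coreBp)
  w
}

# expected pooled core/flank rate ratio under per-context core weights
expectedFold <- function(w, ctxProb, idx) {
  denom <- w * idx$nCore + idx$nOther
  coreRate <- sum(ctxProb * w * idx$nCore / denom) / idx$coreBp
  flankRate <- sum(ctxProb * idx$nFlank / denom) / idx$flankBp
  coreRate / flankRate
}

#' Simulate a mutation catalog from a signature mixture
#'
#' Draws \code{nMut} substitutions class-first, site-second (see the module
#' notes at the top of the source file). The drawn class of every record is
#' recorded in \code{provenance(catalog)$truth}, and classification of the
#' emitted reference-strand record always reproduces the drawn class.
#'
#' @param genome a \linkS4class{ReferenceGenome}.
#' @param islands island \code{GRanges} (core/flank windows are built with
#'   \code{\link{buildWindows}}, so the rate elevation is applied to exactly
#'   the windows the enrichment estimator measures).
#' @param mixture probability vector over the 96 canonical classes (e.g.
#'   \code{mixtureVector}).
#' @param nMut number of substitutions to draw (the catalog size is exact).
#' @param islandMultiplier target expected core-to-flank rate ratio.
#' @param sample sample identifier.
#' @param seed integer seed (\code{NULL}: current RNG stream).
#' @param index optional precomputed site index (internal reuse across a
#'   cohort).
#' @return a \linkS4class{MutationCatalog} with a \code{truth} provenance
#'   entry.
#' @export
simulateCatalog <- function(genome, islands, mixture, nMut,
                            islandMultiplier = 1, sample = "S1", seed = NULL,
                            index = NULL) {
  stopifnot2(abs(sum(mixture) - 1) < 1e-6 && all(mixture >= 0),
             "mixture must be a probability vector")
  stopifnot2(length(mixture) == 96L, "mixture must have 96 entries")
  if (is.null(index)) {
    windows <- buildWindows(islands, genome)
    index <- siteIndex(genome, windows)
  }
  cls2ctx <- classToContext()
  w <- calibrateCoreWeight(islandMultiplier, index)
  withSeed(seed, {
    cnt <- as.integer(stats::rmultinom(1L, nMut, mixture))
    chromV <- character(0); posV <- integer(0); clsV <- character(0)
    for (j in which(cnt > 0L)) {
      c32 <- cls2ctx[j]
      nc <- index$nCore[c32]; no <- index$nOther[c32]
      if (nc + no < cnt[j])
        stop("not enough eligible sites for class ", contextClasses()[j],
             call. = FALSE)
      pCore <- w[c32] * nc / (w[c32] * nc + no)
      kCore <- stats::rbinom(1L, cnt[j], pCore)
      kCore <- min(kCore, nc); kOut <- min(cnt[j] - kCore, no)
      drawFrom <- function(lists, k) {
        # pool positions of this context across chromosomes, draw k w/o repl.
        pools <- lapply(seq_along(index$chroms),
                        function(ci) lists[[ci]][[c32]])
        sizes <- vapply(pools, length, integer(1))
        pick <- sample.int(sum(sizes), k)
        chromIdx <- findInterval(pick, cumsum(c(0L, sizes)) + 1L)
        off <- pick - cumsum(c(0L, sizes))[chromIdx]
        list(chrom = index$chroms[chromIdx],
             pos = vapply(seq_len(k), function(t) pools[[chromIdx[t]]][off[t]],
                          integer(1)))
      }
      if (kCore > 0L) {
        d <- drawFrom(index$coreL, kCore)
        chromV <- c(chromV, d$chrom); posV <- c(posV, d$pos)
        clsV <- c(clsV, rep(contextClasses()[j], kCore))
      }
      if (kOut > 0L) {
        d <- drawFrom(index$otherL, kOut)
        chromV <- c(chromV, d$chrom); posV <- c(posV, d$pos)
        clsV <- c(clsV, rep(contextClasses()[j], kOut))
      }
    }
    refP <- substr(clsV, 1, 1)   # pyrimidine-strand ref
    altP <- substr(clsV, 3, 3)
    base <- character(length(posV))
    for (ch in unique(chromV)) {
      i <- chromV == ch
      base[i] <- substring(chromString(genome, ch), posV[i], posV[i])
    }
    flip <- base != refP
    ref <- ifelse(flip, complementBase(refP), refP)
    alt <- ifelse(flip, complementBase(altP), altP)
    cat_ <- makeCatalog(data.frame(sample = sample, chrom = chromV, pos = posV,
                                   ref = ref, alt = alt,
                                   stringsAsFactors = FALSE),
                        source = "simulateCatalog")
    cat_@provenance$truth <- data.frame(sample = sample, chrom = chromV,
                                        pos = posV, class = clsV,
                                        stringsAsFactors = FALSE)
    cat_@provenance$coreWeight <- w
    cat_
  })
}

#' Packaged synthetic signatures
#'
#' Three fixed 96-class signatures emulating the processes active in tongue
#' carcinoma: \code{SigNCG}, a CpG-methylation-type process concentrating
#' mass on C>T at NCG contexts (ACG/CCG/GCG/TCG, GCG strongest);
#' \code{SigTCN}, an APOBEC-type process concentrating on C>G and C>T at TCN
#' contexts; and \code{SigFlat}, a near-uniform clock-like process with a
#' mild T>C lean. Shapes are fixed numeric constructions, not downloads.
#'
#' @return a \linkS4class{SignatureSet} with 3 columns.
#' @export
syntheticSignatures <- function() {
  cls <- contextClasses()
  sub <- substr(cls, 1, 3)
  ctx <- paste0(substr(cls, 5, 5), substr(cls, 1, 1), substr(cls, 7, 7))

  ncg <- numeric(96)
  ncg[cls == "C>T:GCG"] <- 0.200
  ncg[cls == "C>T:ACG"] <- 0.130
  ncg[cls == "C>T:TCG"] <- 0.120
  ncg[cls == "C>T:CCG"] <- 0.100
  otherCT <- sub == "C>T" & !endsWith(ctx, "G")
  ncg[otherCT] <- 0.21 / sum(otherCT)
  rest <- ncg == 0
  ncg[rest] <- 0.24 / sum(rest)

  tcn <- numeric(96)
  tcnCtx <- startsWith(ctx, "T") & substr(ctx, 2, 2) == "C"
  tcn[sub == "C>G" & tcnCtx] <- 0.42 / 4
  tcn[sub == "C>T" & tcnCtx] <- 0.34 / 4
  rest <- tcn == 0
  tcn[rest] <- 0.24 / sum(rest)

  flat <- numeric(96)
  flat[sub == "T>C"] <- 0.30 / 16
  flat[sub == "C>T"] <- 0.17 / 16
  rest <- flat == 0
  flat[rest] <- 0.53 / sum(rest)

  m <- cbind(SigNCG = ncg, SigTCN = tcn, SigFlat = flat)
  rownames(m) <- cls
  signatureSet(m)
}

#' Collapse a signature set and weights to a 96-class mixture vector
#'
#' @param signatures a \linkS4class{SignatureSet}.
#' @param weights nonnegative weights, one per signature (normalized to sum
#'   to 1).
#' @return named probability vector over the 96 classes.
#' @export
mixtureVector <- function(signatures, weights) {
  P <- signatureProbs(signatures)
  stopifnot2(length(weights) == ncol(P), "one weight per signature")
  stopifnot2(all(weights >= 0) && sum(weights) > 0, "weights must be nonnegative")
  as.numeric(P %*% (weights / sum(weights))) |>
    stats::setNames(rownames(P))
}

#' Cohort emulation profiles
#'
#' \code{bqTcProfile} emulates the betel-quid-associated tongue carcinoma
#' cohort: at \code{scale = "wgs"} 5 genome-sequenced samples averaging 8056
#' SBS each; at \code{scale = "exome"} 15 samples averaging 70 SBS each.
#' The signature mixture averages 53\% SigNCG / 9\% SigTCN / 38\% SigFlat
#' and the island-core mutation rate is elevated 2.05-fold over the flanks.
#' \code{tcgaTcProfile} emulates the general-population cohort: 82
#' exome-scale samples, mixture 18\% SigNCG / 22\% SigTCN / 60\% SigFlat,
#' no island elevation. Per-sample loads are negative-binomial around the
#' mean; per-sample mixture weights are Dirichlet around the means with the
#' stated precision (precision 30 reproduces the reported 35--72\% spread of
#' the dominant-signature proportion).
#'
#' @param scale \code{"wgs"} or \code{"exome"} (BQ-TC only).
#' @return a \code{CohortProfile} (list) understood by
#'   \code{\link{simulateCohort}}.
#' @export
bqTcProfile <- function(scale = c("exome", "wgs")) {
  scale <- match.arg(scale)
  g <- if (scale == "wgs")
    list(length = 1e7, nIslands = 100, islandLength = 1000)
  else
    list(length = 1e6, nIslands = 20, islandLength = 1000)
  structure(list(
    name = "BQ-TC", scale = scale, nSamples = if (scale == "wgs") 5L else 15L,
    loadMean = if (scale == "wgs") 8056 else 70, loadDispersion = 8,
    mixtureMeans = c(SigNCG = 0.53, SigTCN = 0.09, SigFlat = 0.38),
    mixtureConcentration = 30,
    tcnBimodal = list(pHigh = 0.2, meanHigh = 0.25, meanLow = 0.05,
                      precision = 12),
    islandMultiplier = 2.05,
    genome = c(g, list(backgroundCpg = 0.02, islandCpg = 0.10))),
    class = "CohortProfile")
}

#' @rdname bqTcProfile
#' @export
tcgaTcProfile <- function() {
  structure(list(
    name = "TCGA-TC", scale = "exome", nSamples = 82L,
    loadMean = 70, loadDispersion = 8,
    mixtureMeans = c(SigNCG = 0.18, SigTCN = 0.22, SigFlat = 0.60),
    mixtureConcentration = 30,
    tcnBimodal = list(pHigh = 0.3, meanHigh = 0.50, meanLow = 0.10,
                      precision = 12),
    islandMultiplier = 1,
    genome = list(length = 1e6, nIslands = 20, islandLength = 1000,
                  backgroundCpg = 0.02, islandCpg = 0.10)),
    class = "CohortProfile")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

# Per-sample mixture weights. The APOBEC-type (SigTCN) weight is drawn from
# a two-state Beta mixture -- a small "hypermutator" subset with high
# activity, the rest low -- whose marginal mean equals the profile mean;
# APOBEC activity in head-and-neck tumours is episodic rather than uniform,
# and this heterogeneity is also what renders the mixture identifiable to
# the factorization. The remaining mass is split between the other
# components by a Dirichlet draw around their relative means.
drawMixtureWeights <- function(profile) {
  mm <- profile$mixtureMeans
  bi <- profile$tcnBimodal
  iTcn <- which(names(mm) == "SigTCN")
  if (is.null(bi) || length(iTcn) == 0L)
    return(rdirichlet1(profile$mixtureConcentration * mm))
  m <- if (stats::runif(1) < bi$pHigh) bi$meanHigh else bi$meanLow
  tcn <- stats::rbeta(1, m * bi$precision, (1 - m) * bi$precision)
  restMeans <- mm[-iTcn] / sum(mm[-iTcn])
  rest <- (1 - tcn) * rdirichlet1(profile$mixtureConcentration * restMeans)
  w <- numeric(length(mm))
  w[iTcn] <- tcn
  w[-iTcn] <- rest
  stats::setNames(w, names(mm))
}

#' Simulate a whole cohort
#'
#' Draws one genome per cohort, then per sample a mutation load
#' (negative-binomial around the profile mean, floored at 1) and Dirichlet
#' mixture weights around the profile means, and a catalog from the
#' resulting mixture. All drawn parameters are returned as a truth table for
#' recovery tests.
#'
#' @param profile a \code{CohortProfile}
#'   (\code{\link{bqTcProfile}}/\code{\link{tcgaTcProfile}}).
#' @param seed integer seed.
#' @param totalMutations optional total cohort load; when given, per-sample
#'   loads are scaled to sum to it.
#' @return list: \code{catalog} (all samples combined), \code{genome},
#'   \code{islands}, \code{windows}, \code{cohort} (sample -> label table),
#'   \code{truth} (per-sample loads and mixture weights),
#'   \code{signatures} (the generating \linkS4class{SignatureSet}).
#' @export
simulateCohort <- function(profile, seed = 1L, totalMutations = NULL) {
  stopifnot2(inherits(profile, "CohortProfile"), "profile must be a CohortProfile")
  sigs <- syntheticSignatures()
  withSeed(seed, {
    g <- do.call(simulateGenome, c(profile$genome, list(seed = NULL)))
    windows <- buildWindows(g$islands, g$genome)
    index <- siteIndex(g$genome, windows)
    n <- profile$nSamples
    ids <- sprintf("%s_%02d", gsub("[^A-Za-z]", "", profile$name), seq_len(n))
    loads <- pmax(1L, stats::rnbinom(n, mu = profile$loadMean,
                                     size = profile$loadDispersion))
    if (!is.null(totalMutations))
      loads <- pmax(1L, round(loads * totalMutations / sum(loads)))
    W <- t(vapply(seq_len(n), function(i)
      drawMixtureWeights(profile), numeric(length(profile$mixtureMeans))))
    colnames(W) <- names(profile$mixtureMeans)
    cats <- lapply(seq_len(n), function(i)
      simulateCatalog(g$genome, g$islands,
                      mixtureVector(sigs, W[i, ]), loads[i],
                      islandMultiplier = profile$islandMultiplier,
                      sample = ids[i], seed = NULL, index = index))
    comb <- do.call(rbind, lapply(cats, function(x) {
      gr <- mutations(x); m <- S4Vectors::mcols(gr)
      data.frame(sample = m$sample,
                 chrom = as.character(GenomicRanges::seqnames(gr)),
                 pos = GenomicRanges::start(gr), ref = m$ref, alt = m$alt,
                 stringsAsFactors = FALSE)
    }))
    catalog <- makeCatalog(comb, source = sprintf("simulateCohort(%s)", profile$name))
    catalog@provenance$truth <- do.call(rbind, lapply(cats, function(x)
      provenance(x)$truth))
    truth <- data.frame(sample = ids, load = loads, W,
                        stringsAsFactors = FALSE)
    list(catalog = catalog, genome = g$genome, islands = g$islands,
         windows = windows,
         cohort = data.frame(sample = ids, cohort = profile$name,
                             stringsAsFactors = FALSE),
         truth = truth, signatures = sigs)
  })
}
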