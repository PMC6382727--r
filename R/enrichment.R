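# CpG-island regional mutation enrichment: core windows (island +/- 50 nt)
# versus flank windows (501-1000 nt outward from each island edge), rate
# ratio and Fisher's exact test, with 6-class and 16-C>T-class decomposition.

#' Build core and flank windows around a region set
#'
#' For each island the core window extends the island by 50 nt on both sides
#' (1-based inclusive: \code{[start-50, end+50]}); the flank windows are the
#' two 500-nt blocks 501-1000 nt outward from each island edge
#' (\code{[start-1000, start-501]} and \code{[end+501, end+1000]}). The
#' 51-500 nt buffer belongs to neither set. Cores are merged first; flanks
#' are clipped against every core and merged among themselves, so near
#' clustered islands no position is double-counted and the two sets are
#' disjoint by construction. Windows are clipped at chromosome edges, with a
#' count of clipped islands reported as an attribute.
#'
#' @param islands sorted, merged \code{GRanges} (see \code{\link{readRegions}}).
#' @param genome a \linkS4class{ReferenceGenome} supplying chromosome lengths.
#' @return a \linkS4class{WindowSet}.
#' @export
buildWindows <- function(islands, genome) {
  islands <- GenomicRanges::reduce(GenomicRanges::sort(islands))
  lens <- seqLengths(genome)
  chrom <- normChrom(as.character(GenomicRanges::seqnames(islands)))
  stopifnot2(all(chrom %in% names(lens)),
             "island chromosome(s) missing from the reference")
  L <- lens[chrom]
  s <- GenomicRanges::start(islands); e <- GenomicRanges::end(islands)
  clip <- function(a, b) {
    a2 <- pmax(a, 1L); b2 <- pmin(b, L)
    keep <- b2 >= a2
    GenomicRanges::GRanges(chrom[keep], IRanges::IRanges(a2[keep], b2[keep]))
  }
  nClipped <- sum(s - 1000 < 1 | e + 1000 > L)
  core <- GenomicRanges::reduce(clip(s - 50L, e + 50L))
  flank <- c(clip(s - 1000L, s - 501L), clip(e + 501L, e + 1000L))
  flank <- GenomicRanges::reduce(GenomicRanges::sort(flank))
  flank <- GenomicRanges::setdiff(flank, core)
  ws <- methods::new("WindowSet", core = core, flank = flank,
                     coreBp = sum(GenomicRanges::width(core)),
                     flankBp = sum(GenomicRanges::width(flank)))
  attr(ws, "nClipped") <- nClipped
  ws
}

# assign each catalog record to "core", "flank" or "neither" and attach its
# 6-class and (for C>T) 16-class labels
assignWindows <- function(catalog, windows, genome) {
  gr <- mutations(catalog)
  m <- S4Vectors::mcols(gr)
  ctx <- recordContexts(catalog, genome)
  cls <- classifySubstitution(m$ref, m$alt, ctx$fivePrime, ctx$threePrime)
  zone <- rep("neither", length(gr))
  zone[GenomicRanges::countOverlaps(gr, windows@core) > 0L] <- "core"
  zone[GenomicRanges::countOverlaps(gr, windows@flank) > 0L] <- "flank"
  data.frame(zone = zone, class96 = cls, class6 = substr(cls, 1, 3),
             stringsAsFactors = FALSE)
}

#' Rate-ratio enrichment test on one mutation class
#'
#' Builds the 2x2 table \code{[[nCore, coreBp - nCore], [nFlank, flankBp -
#' nFlank]]} of mutated versus non-mutated nucleotide positions and applies a
#' two-sided Fisher's exact test. The fold change is the rate ratio
#' \code{(nCore/coreBp) / (nFlank/flankBp)}; \code{Inf} (flagged) when
#' \code{nFlank} is 0, \code{NA} when both counts are 0.
#'
#' @param nCore,nFlank mutation counts in the two window sets.
#' @param coreBp,flankBp total nucleotide positions in each set.
#' @return list: \code{fold}, \code{pValue}, \code{infinite} flag.
#' @export
enrichmentTest <- function(nCore, nFlank, coreBp, flankBp) {
  stopifnot2(coreBp > 0 && flankBp > 0, "window sizes must be positive")
  if (nCore > coreBp || nFlank > flankBp)
    stop("mutation count exceeds window size (upstream bug)", call. = FALSE)
  if (nCore == 0 && nFlank == 0)
    return(list(fold = NA_real_, pValue = NA_real_, infinite = FALSE))
  tab <- matrix(c(nCore, coreBp - nCore, nFlank, flankBp - nFlank),
                nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  fold <- if (nFlank == 0) Inf else (nCore / coreBp) / (nFlank / flankBp)
  list(fold = fold, pValue = p, infinite = !is.finite(fold))
}

#' Per-class CpG-island enrichment table
#'
#' Assigns every classified record of the catalog to core, flank or neither,
#' then applies \code{\link{enrichmentTest}} to the pooled counts for: all
#' mutations, each of the six substitution types, and each of the 16 C>T
#' context classes. Raw two-sided p-values are reported;
#' Benjamini-Hochberg-adjusted values are added as a column only on request
#' (off by default: the headline analysis reports uncorrected values).
#'
#' @param catalog a \linkS4class{MutationCatalog} (may pool several samples).
#' @param windows a \linkS4class{WindowSet} from \code{\link{buildWindows}}.
#' @param genome a \linkS4class{ReferenceGenome}.
#' @param bh add a BH-adjusted p column (adjusted within the 6-class and
#'   16-class families separately).
#' @return data.frame (the enrichment table): \code{class}, \code{family}
#'   ("all"/"six"/"sixteen"), \code{nCore}, \code{nFlank}, \code{coreBp},
#'   \code{flankBp}, \code{fold}, \code{pValue} (+ \code{pBH}).
#' @export
perClassEnrichment <- function(catalog, windows, genome, bh = FALSE) {
  a <- assignWindows(catalog, windows, genome)
  a <- a[!is.na(a$class96), , drop = FALSE]
  cb <- windows@coreBp; fb <- windows@flankBp
  row1 <- function(label, family, nc, nf) {
    et <- enrichmentTest(nc, nf, cb, fb)
    data.frame(class = label, family = family, nCore = nc, nFlank = nf,
               coreBp = cb, flankBp = fb, fold = et$fold, pValue = et$pValue,
               stringsAsFactors = FALSE)
  }
  out <- row1("all", "all", sum(a$zone == "core"), sum(a$zone == "flank"))
  for (s in substitutionTypes()) {
    sel <- a$class6 == s
    out <- rbind(out, row1(s, "six",
                           sum(sel & a$zone == "core"),
                           sum(sel & a$zone == "flank")))
  }
  ct16 <- contextClasses()[substr(contextClasses(), 1, 3) == "C>T"]
  for (cl in ct16) {
    sel <- a$class96 == cl
    out <- rbind(out, row1(cl, "sixteen",
                           sum(sel & a$zone == "core"),
                           sum(sel & a$zone == "flank")))
  }
  if (bh) {
    out$pBH <- NA_real_
    for (fam in c("six", "sixteen")) {
      i <- out$family == fam
      out$pBH[i] <- stats::p.adjust(out$pValue[i], method = "BH")
    }
  }
  rownames(out) <- NULL
  out
}

#' Write an enrichment table to TSV
#'
#' @param table data.frame from \code{\link{perClassEnrichment}}.
#' @param path output file.
#' @export
writeEnrichmentTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
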