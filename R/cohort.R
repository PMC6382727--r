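# Cohort-level comparison statistics: mutation loads, one-way ANOVA across
# cohorts, and 2x2 Fisher tests on gene mutation frequencies.

#' Per-sample mutation loads
#'
#' Counts SBS records per sample, optionally restricted to a mask (e.g. an
#' exome BED for whole-genome catalogs, so WGS and WES cohorts can be
#' compared on the same footprint).
#'
#' @param catalog a \linkS4class{MutationCatalog}.
#' @param mask optional \code{GRanges}; only records inside it are counted.
#' @return named integer vector of per-sample counts (all catalog samples,
#'   zero where the mask removes everything; a warning if the mask removes
#'   every record).
#' @export
mutationLoad <- function(catalog, mask = NULL) {
  gr <- mutations(catalog)
  samples <- sampleIds(catalog)
  if (!is.null(mask)) {
    keep <- GenomicRanges::countOverlaps(gr, mask) > 0L
    if (!any(keep)) warning("mask intersects no catalog record")
    gr <- gr[keep]
  }
  tab <- table(factor(S4Vectors::mcols(gr)$sample, levels = samples))
  stats::setNames(as.integer(tab), samples)
}

#' One-way ANOVA on mutation loads across cohorts
#'
#' Classic fixed-effects one-way ANOVA of per-sample SBS counts on the
#' cohort label. No post-hoc tests.
#'
#' @param loads named per-sample counts (\code{\link{mutationLoad}}).
#' @param cohorts data.frame with columns \code{sample}, \code{cohort}.
#' @return list: \code{F}, \code{pValue}, \code{dfBetween}, \code{dfWithin},
#'   \code{groupMeans}.
#' @export
anovaLoad <- function(loads, cohorts) {
  lab <- cohorts$cohort[match(names(loads), cohorts$sample)]
  stopifnot2(!anyNA(lab), "every sample needs a cohort label")
  tab <- table(lab)
  stopifnot2(length(tab) >= 2L && all(tab >= 2L),
             "need >= 2 cohorts with >= 2 samples each")
  d <- data.frame(load = as.numeric(loads), cohort = factor(lab))
  fit <- stats::aov(load ~ cohort, data = d)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], pValue = s[["Pr(>F)"]][1],
       dfBetween = s[["Df"]][1], dfWithin = s[["Df"]][2],
       groupMeans = tapply(d$load, d$cohort, mean))
}

#' Fisher's exact test on gene mutation frequencies
#'
#' Compares the fraction of mutated samples between two cohorts on the 2x2
#' table \code{[[k1, n1-k1], [k2, n2-k2]]} with a two-sided Fisher's exact
#' test; the reported odds ratio is the conditional maximum-likelihood
#' estimate.
#'
#' @param k1,n1 mutated and total sample counts in cohort 1.
#' @param k2,n2 same for cohort 2.
#' @return list: \code{freq1}, \code{freq2}, \code{oddsRatio}, \code{pValue}.
#' @export
#' @examples
#' # 3/15 vs 9/201 mutated samples
#' geneFrequencyTest(3, 15, 9, 201)$pValue
geneFrequencyTest <- function(k1, n1, k2, n2) {
  stopifnot2(n1 > 0 && n2 > 0, "cohort sizes must be positive")
  stopifnot2(k1 >= 0 && k1 <= n1 && k2 >= 0 && k2 <= n2,
             "mutated counts must lie in [0, n]")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(freq1 = k1 / n1, freq2 = k2 / n2,
       oddsRatio = unname(ft$estimate), pValue = ft$p.value)
}

#' Gene x sample mutation indicator table
#'
#' Binary indicator of whether each sample carries at least one catalog
#' record inside each gene's interval. The caller supplies the gene set
#' (already restricted to nonsynonymous records if that is the intended
#' frequency semantics).
#'
#' @param catalog a \linkS4class{MutationCatalog}.
#' @param genes \code{GRanges} with a \code{gene} metadata column.
#' @return integer 0/1 matrix, genes x samples.
#' @export
geneMutationTable <- function(catalog, genes) {
  stopifnot2("gene" %in% colnames(S4Vectors::mcols(genes)),
             "genes must carry a 'gene' metadata column")
  gr <- mutations(catalog)
  samples <- sampleIds(catalog)
  hits <- GenomicRanges::findOverlaps(genes, gr)
  out <- matrix(0L, nrow = length(genes), ncol = length(samples),
                dimnames = list(S4Vectors::mcols(genes)$gene, samples))
  if (length(hits) > 0L) {
    g <- S4Vectors::mcols(genes)$gene[S4Vectors::queryHits(hits)]
    s <- S4Vectors::mcols(gr)$sample[S4Vectors::subjectHits(hits)]
    out[cbind(match(g, rownames(out)), match(s, samples))] <- 1L
  }
  out
}
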