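#' The canonical 96 trinucleotide mutation classes
#'
#' Every somatic single-base substitution is described on the strand whose
#' mutated reference base is a pyrimidine (C or T); purine-reference records
#' are reverse-complemented before classification. The 96 classes are the six
#' pyrimidine substitution types (C>A, C>G, C>T, T>A, T>C, T>G) crossed with
#' the four 5' and four 3' flanking bases. Ordering is fixed:
#' substitution-major, then 5' base, then 3' base, both alphabetical, giving
#' stable matrix serialization. Labels read \code{"C>T:GCG"}: a C-to-T change
#' with G on the 5' side and G on the 3' side.
#'
#' @return character vector of the 96 class labels in canonical order.
#' @export
#' @examples
#' contextClasses()[1:4]
contextClasses <- function() {
  subs <- substitutionTypes()
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1, 1)
    for (p in c("A", "C", "G", "T"))
      for (q in c("A", "C", "G", "T"))
        out <- c(out, paste0(s, ":", p, ref, q))
  }
  out
}

#' @rdname contextClasses
#' @export
substitutionTypes <- function() c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# the 32 pyrimidine-centred trinucleotide contexts ("ACA", ..., "TTT" with
# central C or T); site eligibility in the simulator keys on these
pyrimidineContexts <- function() {
  out <- character(0)
  for (r in c("C", "T"))
    for (p in c("A", "C", "G", "T"))
      for (q in c("A", "C", "G", "T"))
        out <- c(out, paste0(p, r, q))
  out
}

# map each of the 96 classes to its context (1..32 into pyrimidineContexts())
classToContext <- function() {
  cls <- contextClasses()
  ctx <- paste0(substr(cls, 5, 5), substr(cls, 1, 1), substr(cls, 7, 7))
  match(ctx, pyrimidineContexts())
}

#' Classify substitutions into the 96 trinucleotide classes
#'
#' Vectorized classifier. Each record is described by its reference-strand
#' alleles and flanking bases; records whose reference base is a purine are
#' reverse-complemented (alleles swapped to their complements, flanks swapped
#' and complemented) so the returned class is always pyrimidine-centred.
#' Records with a non-ACGT base in the trinucleotide are unclassifiable.
#'
#' @param ref,alt reference and alternate bases on the reference strand.
#' @param fivePrime,threePrime reference-strand flanking bases.
#' @return character vector of class labels (\code{NA} where unclassifiable).
#' @export
#' @examples
#' classifySubstitution("C", "T", "A", "G")  # "C>T:ACG"
#' classifySubstitution("G", "A", "C", "T")  # also "C>T:ACG" (opposite strand)
classifySubstitution <- function(ref, alt, fivePrime, threePrime) {
  n <- length(ref)
  stopifnot2(length(alt) == n && length(fivePrime) == n && length(threePrime) == n,
             "ref, alt, fivePrime and threePrime must have equal length")
  bad <- !(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T")) |
    !(fivePrime %in% c("A", "C", "G", "T")) |
    !(threePrime %in% c("A", "C", "G", "T")) | ref == alt
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, complementBase(ref), ref)
  a <- ifelse(flip, complementBase(alt), alt)
  p <- ifelse(flip, complementBase(threePrime), fivePrime)
  q <- ifelse(flip, complementBase(fivePrime), threePrime)
  out <- paste0(r, ">", a, ":", p, r, q)
  out[bad] <- NA_character_
  out
}

# per-record trinucleotide lookup against the genome; returns a data.frame
# with fivePrime/threePrime ("N" outside the chromosome) and the genome base
recordContexts <- function(catalog, genome) {
  gr <- mutations(catalog)
  chrom <- normChrom(as.character(GenomicRanges::seqnames(gr)))
  pos <- GenomicRanges::start(gr)
  up <- dn <- ctr <- rep("N", length(gr))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    s <- chromString(genome, ch)
    L <- nchar(s)
    p <- pos[idx]
    ok <- p >= 1L & p <= L
    stopifnot2(all(ok), sprintf("positions outside chromosome %s", ch))
    ctr[idx] <- substring(s, p, p)
    has5 <- p > 1L
    has3 <- p < L
    up[idx[has5]] <- substring(s, p[has5] - 1L, p[has5] - 1L)
    dn[idx[has3]] <- substring(s, p[has3] + 1L, p[has3] + 1L)
  }
  data.frame(fivePrime = up, base = ctr, threePrime = dn,
             stringsAsFactors = FALSE)
}

#' Build the samples x 96 context matrix
#'
#' Counts each catalog record into its trinucleotide class after
#' pyrimidine-strand collapsing. Records at chromosome edges or with an
#' ambiguous (non-ACGT) flanking base are excluded and tallied per sample in
#' the \code{unclassified} slot; classified + unclassifiable always equals
#' the catalog size.
#'
#' @param catalog a \linkS4class{MutationCatalog}.
#' @param genome a \linkS4class{ReferenceGenome} covering every record.
#' @return a \linkS4class{ContextMatrix}.
#' @export
buildContextMatrix <- function(catalog, genome) {
  stopifnot2(length(mutations(catalog)) > 0L, "catalog is empty")
  gr <- mutations(catalog)
  m <- S4Vectors::mcols(gr)
  ctx <- recordContexts(catalog, genome)
  cls <- classifySubstitution(m$ref, m$alt, ctx$fivePrime, ctx$threePrime)
  samples <- sort(unique(m$sample))
  counts <- matrix(0L, nrow = length(samples), ncol = 96L,
                   dimnames = list(samples, contextClasses()))
  keep <- !is.na(cls)
  if (any(keep)) {
    tab <- table(factor(m$sample[keep], levels = samples),
                 factor(cls[keep], levels = contextClasses()))
    counts[] <- as.integer(tab)
  }
  uncl <- vapply(samples, function(s) sum(m$sample == s & !keep), integer(1))
  zero <- rowSums(counts) == 0L
  if (any(zero))
    warning("sample(s) with no classifiable records: ",
            paste(samples[zero], collapse = ", "))
  methods::new("ContextMatrix", counts = counts, unclassified = uncl)
}

#' Collapse the 96 classes to the six substitution types
#'
#' Sums the 16 flanking-context classes within each substitution type;
#' per-sample row sums are preserved.
#'
#' @param x a \linkS4class{ContextMatrix}.
#' @return integer matrix, samples x 6 (columns C>A ... T>G).
#' @export
collapseSix <- function(x) {
  counts <- contextCounts(x)
  subs <- substr(colnames(counts), 1, 3)
  out <- vapply(substitutionTypes(),
                function(s) rowSums(counts[, subs == s, drop = FALSE]),
                numeric(nrow(counts)))
  out <- matrix(out, nrow = nrow(counts),
                dimnames = list(rownames(counts), substitutionTypes()))
  out
}

#' The 16 C>T context classes
#'
#' Extracts the 16 C>T cells per sample in canonical context order
#' (5' then 3', alphabetical); used by the 16-class CpG-island enrichment
#' decomposition.
#'
#' @param x a \linkS4class{ContextMatrix}.
#' @return matrix, samples x 16, columns labeled \code{"C>T:ACA"} etc.
#' @export
ctContextTable16 <- function(x) {
  counts <- contextCounts(x)
  keep <- substr(colnames(counts), 1, 3) == "C>T"
  counts[, keep, drop = FALSE]
}

#' GCG and TCN shares of C>T mutations
#'
#' Per sample: \code{pGCG} is the fraction of all C>T mutations that occur in
#' the GCG context; \code{pTCN} the fraction in any of the TCA/TCC/TCG/TCT
#' contexts. Samples with zero C>T mutations get \code{NA} and are flagged.
#'
#' The GCG (CpG-methylation-type) pattern dominating over TCN (APOBEC-type)
#' is the hallmark of betel-quid-associated tumours.
#'
#' @param x a \linkS4class{ContextMatrix}.
#' @return data.frame with columns \code{sample}, \code{pGCG}, \code{pTCN},
#'   \code{nCT} and logical \code{flagged}.
#' @export
ctPatternProportions <- function(x) {
  ct <- ctContextTable16(x)
  tot <- rowSums(ct)
  tcn <- paste0("C>T:TC", c("A", "C", "G", "T"))
  pG <- ifelse(tot > 0, ct[, "C>T:GCG"] / tot, NA_real_)
  pT <- ifelse(tot > 0, rowSums(ct[, tcn, drop = FALSE]) / tot, NA_real_)
  if (any(tot == 0))
    warning("sample(s) with zero C>T mutations flagged: ",
            paste(rownames(ct)[tot == 0], collapse = ", "))
  data.frame(sample = rownames(ct), pGCG = unname(pG), pTCN = unname(pT),
             nCT = unname(tot), flagged = unname(tot == 0),
             stringsAsFactors = FALSE)
}

#' Strand-preference test for C>T mutations
#'
#' Counts C>T versus G>A records as written on the reference strand (i.e.
#' before pyrimidine collapsing) and tests the split against 1/2 with a
#' two-sided exact binomial test. This is a reference-strand proxy; no
#' transcriptional-strand assignment is attempted.
#'
#' @param catalog a \linkS4class{MutationCatalog}.
#' @return list with \code{nPyrimidineRef} (C>T count), \code{nPurineRef}
#'   (G>A count) and \code{pValue}.
#' @export
strandPreferenceTest <- function(catalog) {
  m <- S4Vectors::mcols(mutations(catalog))
  nC <- sum(m$ref == "C" & m$alt == "T")
  nG <- sum(m$ref == "G" & m$alt == "A")
  stopifnot2(nC + nG > 0L, "no C>T/G>A records in catalog")
  p <- stats::binom.test(nC, nC + nG, p = 0.5,
                         alternative = "two.sided")$p.value
  list(nPyrimidineRef = nC, nPurineRef = nG, pValue = p)
}
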