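#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   countOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

#' ReferenceGenome: random-access reference sequence
#'
#' Thin wrapper around a \link[Biostrings]{DNAStringSet} providing 1-based
#' inclusive subsequence queries with upper-cased output and normalized
#' chromosome names (any \code{"chr"} prefix is stripped so mixed hg19-style
#' dialects match).
#'
#' @slot sequences A \code{DNAStringSet}, one entry per chromosome, names
#'   normalized.
#' @export
setClass("ReferenceGenome", representation(sequences = "ANY"))

setValidity("ReferenceGenome", function(object) {
  s <- object@sequences
  if (!methods::is(s, "DNAStringSet")) return("sequences must be a DNAStringSet")
  if (is.null(names(s)) || anyDuplicated(names(s)))
    return("chromosome names must be present and unique")
  TRUE
})

#' MutationCatalog: a catalog of somatic single-base substitutions
#'
#' Records are stored as a \link[GenomicRanges]{GRanges} of width-1 positions
#' (1-based) with metadata columns \code{sample}, \code{ref} and \code{alt},
#' each allele a single base in \{A,C,G,T\} with \code{alt != ref}. Duplicate
#' (sample, chrom, pos, alt) tuples are collapsed at construction.
#'
#' @slot mutations \code{GRanges} with mcols \code{sample}, \code{ref},
#'   \code{alt}.
#' @slot provenance list: source file, filter counts (indels skipped,
#'   reference mismatches rejected, duplicates collapsed, ...).
#' @export
setClass("MutationCatalog",
         representation(mutations = "GRanges", provenance = "list"))

setValidity("MutationCatalog", function(object) {
  m <- S4Vectors::mcols(object@mutations)
  need <- c("sample", "ref", "alt")
  if (!all(need %in% colnames(m)))
    return("mutations must carry sample, ref and alt metadata columns")
  if (length(object@mutations) == 0L) return(TRUE)
  ok <- m$ref %in% c("A", "C", "G", "T") & m$alt %in% c("A", "C", "G", "T")
  if (!all(ok)) return("ref and alt must be single bases in A/C/G/T")
  if (any(m$ref == m$alt)) return("alt must differ from ref")
  if (any(GenomicRanges::width(object@mutations) != 1L))
    return("all records must be width-1 substitutions")
  TRUE
})

#' ContextMatrix: samples x 96 trinucleotide-class mutation counts
#'
#' Rows are samples, columns the 96 pyrimidine-strand classes in fixed order
#' (substitution-major, then 5' context, then 3' context, both alphabetical;
#' labels like \code{"C>T:GCG"}). Row sums equal the number of classifiable
#' substitutions per sample.
#'
#' @slot counts integer matrix, samples x 96, dimnames set.
#' @slot unclassified named integer, per-sample count of records that could
#'   not be classified (flanking N, chromosome edge).
#' @export
setClass("ContextMatrix",
         representation(counts = "matrix", unclassified = "integer"))

setValidity("ContextMatrix", function(object) {
  cn <- colnames(object@counts)
  if (is.null(cn) || length(cn) != 96L || !identical(cn, contextClasses()))
    return("counts must have the 96 canonical class columns in canonical order")
  if (any(object@counts < 0)) return("counts must be nonnegative")
  if (!identical(sort(names(object@unclassified)),
                 sort(rownames(object@counts))))
    return("unclassified must be named by the same samples as counts rows")
  TRUE
})

#' SignatureSet: mutational signatures as 96-class probability vectors
#'
#' @slot probs numeric matrix 96 x K; each column is a probability vector
#'   over the canonical 96 classes (sums to 1), rownames are class labels,
#'   colnames are signature names.
#' @export
setClass("SignatureSet", representation(probs = "matrix"))

setValidity("SignatureSet", function(object) {
  p <- object@probs
  if (nrow(p) != 96L || !identical(rownames(p), contextClasses()))
    return("probs must be 96 rows in canonical class order")
  if (any(p < 0)) return("signature probabilities must be nonnegative")
  cs <- colSums(p)
  if (any(abs(cs - 1) > 1e-6))
    return("each signature column must sum to 1")
  TRUE
})

#' WindowSet: paired core/flank windows around a region set
#'
#' Core windows are each region extended 50 nt on both sides; flank windows
#' are the two 500-nt blocks spanning 501-1000 nt outward from each region
#' edge, clipped to the chromosome and trimmed against every core so that no
#' position belongs to both sets. The 51-500 nt buffer belongs to neither.
#'
#' @slot core,flank \code{GRanges}, sorted and merged.
#' @slot coreBp,flankBp total nucleotide positions in each set.
#' @export
setClass("WindowSet",
         representation(core = "GRanges", flank = "GRanges",
                        coreBp = "numeric", flankBp = "numeric"))

setValidity("WindowSet", function(object) {
  if (length(GenomicRanges::findOverlaps(object@core, object@flank)) > 0L)
    return("core and flank windows must be disjoint")
  if (object@coreBp != sum(GenomicRanges::width(object@core)) ||
      object@flankBp != sum(GenomicRanges::width(object@flank)))
    return("coreBp/flankBp must equal summed interval widths")
  TRUE
})

#' NmfFit: one nonnegative matrix factorization of a context matrix
#'
#' @slot signatures \code{SignatureSet} (96 x K, columns sum to 1).
#' @slot exposures numeric matrix K x samples; \code{signatures %*% exposures}
#'   approximates the transposed count matrix.
#' @slot error Frobenius norm of the reconstruction residual.
#' @slot iterations iterations used by the best restart.
#' @export
setClass("NmfFit",
         representation(signatures = "SignatureSet", exposures = "matrix",
                        error = "numeric", iterations = "integer"))

setMethod("show", "ReferenceGenome", function(object) {
  ls <- seqLengths(object)
  cat("ReferenceGenome with", length(ls), "sequence(s),",
      format(sum(ls), big.mark = ","), "bp total\n")
})

setMethod("show", "MutationCatalog", function(object) {
  cat("MutationCatalog:", length(object@mutations), "SBS record(s),",
      length(sampleIds(object)), "sample(s)\n")
  fc <- object@provenance$filtered
  if (!is.null(fc) && any(unlist(fc) > 0))
    cat("  filtered:", paste(names(fc), unlist(fc), sep = "=", collapse = ", "),
        "\n")
})

setMethod("show", "ContextMatrix", function(object) {
  cat("ContextMatrix:", nrow(object@counts), "sample(s) x 96 classes,",
      sum(object@counts), "classified SBS\n")
  if (sum(object@unclassified) > 0)
    cat("  unclassifiable:", sum(object@unclassified), "\n")
})

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet with", ncol(object@probs), "signature(s):",
      paste(colnames(object@probs), collapse = ", "), "\n")
})

setMethod("show", "WindowSet", function(object) {
  cat("WindowSet:", length(object@core), "core interval(s) (",
      object@coreBp, "bp ),", length(object@flank), "flank interval(s) (",
      object@flankBp, "bp )\n")
})

setMethod("show", "NmfFit", function(object) {
  cat("NmfFit: K =", nrow(object@exposures),
      "| Frobenius error =", signif(object@error, 6), "\n")
})

# accessors -------------------------------------------------------------

#' Accessors for the core containers
#'
#' @param x a quidsig object.
#' @return \code{mutations} returns the underlying \code{GRanges};
#'   \code{sampleIds} the sorted unique sample identifiers; \code{provenance}
#'   the provenance list; \code{contextCounts} the samples x 96 count matrix;
#'   \code{unclassifiedCounts} the per-sample unclassifiable tallies;
#'   \code{signatureProbs} the 96 x K probability matrix; \code{seqLengths}
#'   the named chromosome lengths; \code{coreWindows}/\code{flankWindows}
#'   the window \code{GRanges}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
mutations <- function(x) x@mutations

#' @rdname accessors
#' @export
sampleIds <- function(x) {
  if (methods::is(x, "MutationCatalog"))
    sort(unique(S4Vectors::mcols(x@mutations)$sample))
  else rownames(x@counts)
}

#' @rdname accessors
#' @export
provenance <- function(x) x@provenance

#' @rdname accessors
#' @export
contextCounts <- function(x) x@counts

#' @rdname accessors
#' @export
unclassifiedCounts <- function(x) x@unclassified

#' @rdname accessors
#' @export
signatureProbs <- function(x) {
  if (methods::is(x, "NmfFit")) x@signatures@probs else x@probs
}

#' @rdname accessors
#' @export
exposures <- function(x) x@exposures

#' @rdname accessors
#' @export
reconstructionError <- function(x) x@error

#' @rdname accessors
#' @export
seqLengths <- function(x) {
  stats::setNames(Biostrings::width(x@sequences), names(x@sequences))
}

#' @rdname accessors
#' @export
coreWindows <- function(x) x@core

#' @rdname accessors
#' @export
flankWindows <- function(x) x@flank
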