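#' Read a reference genome from FASTA
#'
#' Sequence names are truncated at the first whitespace and any \code{"chr"}
#' prefix is stripped so that catalogs and region sets using either naming
#' dialect match. A sidecar \code{.fai} index is permitted but not required.
#'
#' @param path FASTA file.
#' @return a \linkS4class{ReferenceGenome}.
#' @export
readReference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stopifnot2(length(seqs) > 0L, "empty FASTA file")
  names(seqs) <- normChrom(sub("\\s.*$", "", names(seqs)))
  methods::new("ReferenceGenome", sequences = seqs)
}

# whole-chromosome sequence as an upper-case character string
chromString <- function(genome, chrom) {
  ch <- normChrom(chrom)
  stopifnot2(ch %in% names(genome@sequences),
             sprintf("chromosome '%s' not in reference", chrom))
  toupper(as.character(genome@sequences[[ch]]))
}

#' Query reference bases
#'
#' 1-based inclusive coordinates; bases are returned upper-cased. Queries
#' outside \code{[1, length]} fail.
#'
#' @param genome a \linkS4class{ReferenceGenome}.
#' @param chrom chromosome name (either naming dialect).
#' @param start,end 1-based inclusive bounds, \code{start <= end}.
#' @return character scalar of length \code{end - start + 1}.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa"); writeLines(c(">chr1", "ACGT"), fa)
#' getBases(readReference(fa), "chr1", 1, 4)  # "ACGT"
getBases <- function(genome, chrom, start, end) {
  ch <- normChrom(chrom)
  L <- seqLengths(genome)[[ch]]
  stopifnot2(start >= 1 && end <= L && start <= end,
             sprintf("query %s:%d-%d outside [1, %d]", ch, start, end, L))
  toupper(as.character(Biostrings::subseq(genome@sequences[[ch]], start, end)))
}

# internal constructor: data.frame(sample, chrom, pos, ref, alt) -> catalog.
# Normalizes chromosome names, optionally rejects reference mismatches,
# collapses duplicate (sample, chrom, pos, alt) tuples.
makeCatalog <- function(df, genome = NULL, source = NA_character_,
                        filtered = list()) {
  df$chrom <- normChrom(df$chrom)
  df$ref <- toupper(df$ref)
  df$alt <- toupper(df$alt)
  ok <- df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T") &
    df$ref != df$alt
  filtered$malformed_allele <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  if (!is.null(genome) && nrow(df) > 0) {
    refBase <- rep(NA_character_, nrow(df))
    for (ch in unique(df$chrom)) {
      idx <- which(df$chrom == ch)
      s <- chromString(genome, ch)
      stopifnot2(all(df$pos[idx] >= 1 & df$pos[idx] <= nchar(s)),
                 sprintf("positions outside chromosome %s", ch))
      refBase[idx] <- substring(s, df$pos[idx], df$pos[idx])
    }
    match_ <- refBase == df$ref
    filtered$ref_mismatch <- sum(!match_)
    if (any(!match_))
      warning(sum(!match_), " record(s) rejected: REF does not match reference")
    df <- df[match_, , drop = FALSE]
  }
  key <- paste(df$sample, df$chrom, df$pos, df$alt, sep = "\r")
  dup <- duplicated(key)
  filtered$duplicate_collapsed <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  o <- order(df$sample, df$chrom, df$pos, df$alt)
  df <- df[o, , drop = FALSE]
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L),
                               sample = df$sample, ref = df$ref, alt = df$alt)
  methods::new("MutationCatalog", mutations = gr,
               provenance = list(source = source, filtered = filtered))
}

#' Read a mutation catalog from VCF
#'
#' One record per biallelic SNV row; multi-allelic rows are split into one
#' record per alternate allele; non-SNV alternates (indels, symbolic alleles)
#' are skipped and counted in the provenance. If a reference genome is
#' supplied, records whose REF disagrees with it are rejected and counted.
#'
#' @param path VCF 4.x file (plain or bgzipped).
#' @param sampleId sample identifier to assign; defaults to the first VCF
#'   sample name or, failing that, the file name.
#' @param genome optional \linkS4class{ReferenceGenome} for REF validation.
#' @return a \linkS4class{MutationCatalog}.
#' @export
readVcfCatalog <- function(path, sampleId = NULL, genome = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (is.null(sampleId)) {
    sn <- colnames(vcf)
    sampleId <- if (length(sn) >= 1L) sn[1L] else basename(path)
  }
  vcf <- VariantAnnotation::expand(vcf)  # one row per ALT allele
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))
  snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  df <- data.frame(sample = sampleId,
                   chrom = as.character(GenomicRanges::seqnames(rr))[snv],
                   pos = GenomicRanges::start(rr)[snv],
                   ref = ref[snv], alt = alt[snv], stringsAsFactors = FALSE)
  makeCatalog(df, genome = genome, source = path,
              filtered = list(non_snv = sum(!snv)))
}

#' Read a mutation catalog from MAF
#'
#' TCGA-style tab-delimited MAF. Requires columns (case-insensitive match)
#' \code{Tumor_Sample_Barcode}, \code{Chromosome}, \code{Start_Position} (or
#' \code{Start_position}), \code{Reference_Allele}, \code{Tumor_Seq_Allele2}
#' and \code{Variant_Type}; a missing column is a fatal error naming it.
#' Only \code{Variant_Type == "SNP"} rows are admitted; coordinates are taken
#' as 1-based per the MAF convention. The tumor sample barcode is the sample
#' identifier.
#'
#' @param path MAF file.
#' @param genome optional \linkS4class{ReferenceGenome} for REF validation.
#' @return a \linkS4class{MutationCatalog}.
#' @export
readMafCatalog <- function(path, genome = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  stopifnot2(nrow(df) > 0L, "empty MAF file")
  pick <- function(cands) {
    hit <- which(tolower(colnames(df)) %in% tolower(cands))
    if (length(hit) == 0L)
      stop("MAF is missing required column: ", cands[1L], call. = FALSE)
    colnames(df)[hit[1L]]
  }
  cSam <- pick("Tumor_Sample_Barcode")
  cChr <- pick("Chromosome")
  cPos <- pick(c("Start_Position", "Start_position"))
  cRef <- pick("Reference_Allele")
  cAlt <- pick(c("Tumor_Seq_Allele2", "Tumor_Seq_Allele1"))
  cTyp <- pick("Variant_Type")
  snp <- toupper(df[[cTyp]]) == "SNP"
  out <- data.frame(sample = df[[cSam]][snp], chrom = df[[cChr]][snp],
                    pos = as.integer(df[[cPos]][snp]), ref = df[[cRef]][snp],
                    alt = df[[cAlt]][snp], stringsAsFactors = FALSE)
  makeCatalog(out, genome = genome, source = path,
              filtered = list(non_snp = sum(!snp)))
}

#' Read a region set from BED
#'
#' BED intervals are 0-based half-open; the returned \code{GRanges} follows
#' the Bioconductor 1-based inclusive convention (a BED row
#' \code{chr1 999 1200} covers 1-based positions 1000..1200). Rows with
#' \code{end <= start} are skipped with a warning; overlapping or adjacent
#' intervals are merged and the result is sorted.
#'
#' @param path BED3+ file.
#' @param label optional label stored in \code{metadata(x)$label}.
#' @return a sorted, merged \code{GRanges}.
#' @export
readRegions <- function(path, label = basename(path)) {
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           header = FALSE, fill = TRUE)
  stopifnot2(nrow(raw) >= 1L && ncol(raw) >= 3L, "empty or malformed BED file")
  raw <- stats::setNames(raw[, 1:3], c("chrom", "start", "end"))
  bad <- raw$end <= raw$start
  if (any(bad)) warning(sum(bad), " BED row(s) with end <= start skipped")
  raw <- raw[!bad, , drop = FALSE]
  tmp <- tempfile(fileext = ".bed")
  on.exit(unlink(tmp))
  utils::write.table(raw[, c("chrom", "start", "end")], tmp, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  gr <- rtracklayer::import(tmp, format = "BED")
  GenomeInfoDb::seqlevels(gr) <- normChrom(GenomeInfoDb::seqlevels(gr))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Read a cohort table
#'
#' Tab-delimited with a header; the first two columns are the sample
#' identifier and the cohort label, any further columns are kept as
#' covariates (HPV status, age, stage, ...). Duplicate sample rows are a
#' fatal error: every sample must carry exactly one label.
#'
#' @param path TSV file.
#' @return data.frame with columns \code{sample}, \code{cohort}, covariates.
#' @export
readCohortTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot2(nrow(df) > 0L, "empty cohort table")
  stopifnot2(ncol(df) >= 2L, "cohort table needs at least sample and cohort columns")
  colnames(df)[1:2] <- c("sample", "cohort")
  stopifnot2(!anyDuplicated(df$sample),
             "cohort table assigns more than one label to a sample")
  df
}

#' Write / read a catalog in the package TSV dialect
#'
#' Five tab-separated columns with header: \code{sample}, \code{chrom},
#' \code{pos} (1-based), \code{ref}, \code{alt}. Writing then re-reading
#' reproduces the catalog record for record.
#'
#' @param catalog a \linkS4class{MutationCatalog}.
#' @param path output / input file.
#' @return \code{readCatalogTsv} returns a \linkS4class{MutationCatalog};
#'   \code{writeCatalogTsv} returns \code{path} invisibly.
#' @export
writeCatalogTsv <- function(catalog, path) {
  gr <- mutations(catalog)
  m <- S4Vectors::mcols(gr)
  df <- data.frame(sample = m$sample,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   pos = GenomicRanges::start(gr),
                   ref = m$ref, alt = m$alt, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCatalogTsv
#' @param genome optional \linkS4class{ReferenceGenome} for REF validation.
#' @export
readCatalogTsv <- function(path, genome = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "pos", "ref", "alt")
  stopifnot2(all(need %in% colnames(df)),
             paste("catalog TSV must have columns:", paste(need, collapse = ", ")))
  makeCatalog(df[, need], genome = genome, source = path)
}

#' Construct a mutation catalog in code
#'
#' @param sample,chrom,pos,ref,alt parallel vectors of record fields
#'   (positions 1-based).
#' @param genome optional \linkS4class{ReferenceGenome}: records whose
#'   \code{ref} mismatches the genome are rejected with a count (never
#'   strand-rescued; a silent flip would corrupt context classes).
#' @return a \linkS4class{MutationCatalog}.
#' @export
mutationCatalog <- function(sample, chrom, pos, ref, alt, genome = NULL) {
  makeCatalog(data.frame(sample = as.character(sample),
                         chrom = as.character(chrom), pos = as.integer(pos),
                         ref = as.character(ref), alt = as.character(alt),
                         stringsAsFactors = FALSE),
              genome = genome, source = "in-memory")
}
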