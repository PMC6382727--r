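# fixtures built in code: tiny genomes, literal VCF/MAF/BED text, and
# independent oracles reused across test files

writeTempLines <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a fixed 60-bp two-chromosome genome (written as FASTA then read back)
tinyGenome <- function() {
  readReference(writeTempLines(c(
    ">chr1 test",
    "ACGTACGTGGCCAATTACGTACGTGGCCAATT",
    ">2",
    "TTGGCCAACGCGCGTTAACCGGTTAACCGGTT"), ".fa"))
}

tinyVcf <- function() {
  writeTempLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t2\t.\tC\tT\t.\tPASS\t.",
    "chr1\t6\t.\tC\tA\t.\tPASS\t.",
    "chr1\t10\t.\tG\tC,A\t.\tPASS\t.",
    "chr1\t13\t.\tAT\tA\t.\tPASS\t.",
    "chr1\t18\t.\tC\tG\t.\tPASS\t."), ".vcf")
}

# independent hand-built VCF SNV parser: returns sorted "chrom:pos:ref>alt"
# keys; used as the oracle for multi-allelic splitting
parseVcfByHand <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  out <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    for (alt in strsplit(f[5], ",")[[1]]) {
      if (nchar(f[4]) == 1L && nchar(alt) == 1L &&
          f[4] %in% c("A", "C", "G", "T") && alt %in% c("A", "C", "G", "T"))
        out <- c(out, paste0(sub("^chr", "", f[1]), ":", f[2], ":", f[4], ">", alt))
    }
  }
  sort(out)
}

catalogKeys <- function(catalog) {
  gr <- mutations(catalog)
  m <- S4Vectors::mcols(gr)
  sort(paste0(as.character(GenomicRanges::seqnames(gr)), ":",
              GenomicRanges::start(gr), ":", m$ref, ">", m$alt))
}

tinyMaf <- function(extraRow = NULL) {
  writeTempLines(c(
    paste("Hugo_Symbol", "Chromosome", "Start_Position", "Reference_Allele",
          "Tumor_Seq_Allele2", "Variant_Type", "Tumor_Sample_Barcode",
          sep = "\t"),
    "TP53\t17\t100\tC\tT\tSNP\tTCGA-01",
    "RASA1\t5\t200\tG\tA\tSNP\tTCGA-01",
    "TP53\t17\t300\tA\tC\tSNP\tTCGA-02",
    extraRow), ".maf")
}

# brute-force two-sided Fisher p by hypergeometric enumeration (the
# independent oracle for stats::fisher.test): sum of P(tables) whose
# probability does not exceed the observed table's (with a relative fuzz for
# floating-point ties, matching the conventional definition)
fisherOracle <- function(k1, n1, k2, n2) {
  m <- k1 + k2                 # total "mutated"
  support <- max(0, m - n2):min(m, n1)
  probs <- stats::dhyper(support, n1, n2, m)
  pObs <- stats::dhyper(k1, n1, n2, m)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# naive complete-linkage agglomeration on a distance matrix: returns sorted
# merge heights (the independent oracle for stats::hclust)
completeLinkageOracle <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestH <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      h <- max(D[clusters[[i]], clusters[[j]]])
      if (h < bestH) { bestH <- h; best <- c(i, j) }
    }
    heights <- c(heights, bestH)
    clusters[[best[2]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[1]]] <- NULL
  }
  sort(heights)
}

# independent per-position membership oracle: decides core/flank/neither for
# every position directly from the window definition
membershipOracle <- function(position, islandStarts, islandEnds, chromLen) {
  inCore <- any(position >= islandStarts - 50 & position <= islandEnds + 50)
  if (inCore) return("core")
  inFlank <- any((position >= islandStarts - 1000 & position <= islandStarts - 501) |
                 (position >= islandEnds + 501 & position <= islandEnds + 1000))
  if (inFlank && position >= 1 && position <= chromLen) return("flank")
  "neither"
}

# repetitive-sequence toy genome for coordinate-level window checks
flatGenome <- function(len, chrom = "1") {
  readReference(writeTempLines(
    c(paste0(">", chrom), paste(rep("ACGT", ceiling(len / 4)), collapse = "")),
    ".fa"))
}

# combine a list of single-sample catalogs into one
combineCatalogs <- function(cats) {
  df <- do.call(rbind, lapply(cats, function(x) {
    gr <- mutations(x); m <- S4Vectors::mcols(gr)
    data.frame(sample = m$sample,
               chrom = as.character(GenomicRanges::seqnames(gr)),
               pos = GenomicRanges::start(gr), ref = m$ref, alt = m$alt,
               stringsAsFactors = FALSE)
  }))
  mutationCatalog(df$sample, df$chrom, df$pos, df$ref, df$alt)
}

# a ContextMatrix built directly from a counts matrix (validity enforced)
asContextMatrix <- function(counts) {
  storage.mode(counts) <- "integer"
  colnames(counts) <- contextClasses()
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  methods::new("ContextMatrix", counts = counts,
               unclassified = stats::setNames(integer(nrow(counts)),
                                              rownames(counts)))
}
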