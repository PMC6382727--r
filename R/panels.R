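#' Construct a SignatureSet from a probability matrix
#'
#' @param probs 96 x K nonnegative matrix; rownames must be the canonical
#'   class labels (any order; rows are reordered), columns are normalized to
#'   sum to 1.
#' @param names optional signature names.
#' @return a \linkS4class{SignatureSet}.
#' @export
signatureSet <- function(probs, names = colnames(probs)) {
  stopifnot2(is.matrix(probs) && nrow(probs) == 96L,
             "probs must be a 96-row matrix")
  stopifnot2(!is.null(rownames(probs)) &&
               setequal(rownames(probs), contextClasses()),
             "rownames must be the 96 canonical class labels")
  probs <- probs[contextClasses(), , drop = FALSE]
  stopifnot2(all(probs >= 0), "signature probabilities must be nonnegative")
  probs <- sweep(probs, 2, colSums(probs), "/")
  if (is.null(names)) names <- paste0("S", seq_len(ncol(probs)))
  colnames(probs) <- names
  methods::new("SignatureSet", probs = probs)
}

#' Read / write a reference signature panel
#'
#' Tab-delimited COSMIC-v2-style layout: a header of signature names, then 96
#' labeled rows (first column the class label, e.g. \code{"C>T:GCG"}) by K
#' probability columns. Rows may appear in any order; they are reordered to
#' the canonical ordering on read.
#'
#' @param path panel file.
#' @return \code{readSignaturePanel} returns a \linkS4class{SignatureSet}.
#' @export
readSignaturePanel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot2(nrow(df) == 96L, "signature panel must have 96 rows")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  signatureSet(m)
}

#' @rdname readSignaturePanel
#' @param signatures a \linkS4class{SignatureSet}.
#' @export
writeSignaturePanel <- function(signatures, path) {
  P <- signatureProbs(signatures)
  df <- data.frame(class = rownames(P), P, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
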