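# internal helpers shared across modules

# evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# stream is untouched. seed = NULL runs in the current stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# "chr1" / "Chr1" / "1" -> "1"; keys compared after stripping the prefix
normChrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

complementBase <- function(x) chartr("ACGT", "TGCA", x)

reverseComplement1 <- function(s) {
  vapply(strsplit(complementBase(s), ""), function(b) paste(rev(b), collapse = ""),
         character(1))
}

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
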