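#' @importFrom methods new validObject is slot
#' @importFrom stats cor fisher.test median p.adjust phyper quantile rbinom
#'   rnbinom rnorm rpois runif sd setNames t.test var
#' @importFrom utils head read.delim write.table
NULL

## Variant keys ---------------------------------------------------------------

## allele-resolution key used for germline matching and benchmarking
variantKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

## position-resolution key used for recurrence ("mutated base positions")
positionKey <- function(chrom, pos) {
  paste(chrom, pos, sep = ":")
}

## Seeded evaluation ----------------------------------------------------------

## Run `expr` under a private RNG stream; the caller's RNG state is restored
## afterwards so independent generator calls do not perturb one another.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Sequence helpers -----------------------------------------------------------

DNA_BASES_CHR <- c("A", "C", "G", "T")

#' Reverse complement of character DNA sequences
#'
#' Vectorised reverse complement over plain character vectors. Non-ACGT
#' symbols are complemented via IUPAC rules by [Biostrings::reverseComplement].
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' revComp(c("ACGT", "AAAC"))
#' @export
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Canonical form: lexicographic min of a k-mer and its reverse complement.
canonicalKmers <- function(kmers) {
  if (length(kmers) == 0L) return(character(0))
  rc <- revComp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

## All k-mers of one sequence (character scalar); k-mers containing
## non-ACGT symbols are dropped.
extractKmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  km <- substring(seq, starts, starts + k - 1L)
  km[!grepl("[^ACGT]", km)]
}

## Quality string <-> integer Phred scores (Sanger offset 33)
phredToInt <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

intToPhred <- function(scores) {
  vapply(scores, function(s) intToUtf8(pmin(s, 60L) + 33L), character(1))
}

## Misc -----------------------------------------------------------------------

## log2 copy-number ratio with the zero-CN floor handled by callers
log2Ratio <- function(cn, baseline) {
  ifelse(cn <= 0, -Inf, log2(cn / baseline))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
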