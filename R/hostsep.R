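#' Quality preprocessing of paired-end reads
#'
#' Applies the read-level quality rules used before host-read removal:
#' (i) a read is discarded outright when at least `fractionThreshold`
#' (default 70%) of its bases fall below `qualityThreshold` (default Q30);
#' (ii) otherwise the maximal trailing run of bases below the threshold is
#' trimmed from the 3' end; (iii) the read is then discarded when fewer
#' than `fractionThreshold` of its original bases remain; (iv) a pair is
#' discarded when either mate is discarded.
#'
#' @param pairs data.frame with columns `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2` (Sanger/Phred+33 quality strings), as produced by
#'   [simulateReadSet()] or [readFastqPairs()].
#' @param qualityThreshold Minimum base quality (default 30).
#' @param fractionThreshold Fraction for both the low-quality discard rule
#'   and the post-trim length rule (default 0.70).
#' @return List with `kept` (the surviving pairs, trimmed) and `report`, a
#'   list with `reads_in`, `reads_out` (read counts, i.e. 2 per pair) and
#'   `disposition`, a per-read factor over kept / discarded_quality /
#'   discarded_short / discarded_mate.
#' @examples
#' p <- data.frame(id = "r1", seq1 = "ACGTACGT", qual1 = "IIIIIIII",
#'                 seq2 = "ACGTACGT", qual2 = "IIII####")
#' preprocessReads(p)$report$disposition
#' @export
preprocessReads <- function(pairs, qualityThreshold = 30,
                            fractionThreshold = 0.70) {
  need <- c("id", "seq1", "qual1", "seq2", "qual2")
  if (!all(need %in% names(pairs)))
    stop("'pairs' must have columns: ", paste(need, collapse = ", "))
  if (any(nchar(pairs$seq1) != nchar(pairs$qual1)) ||
      any(nchar(pairs$seq2) != nchar(pairs$qual2)))
    stop("sequence/quality length mismatch")

  processMate <- function(seq, qual) {
    q <- utf8ToInt(qual) - 33L
    n <- length(q)
    bad <- q < qualityThreshold
    if (n == 0L || mean(bad) >= fractionThreshold)
      return(list(status = "discarded_quality", seq = seq, qual = qual))
    ## trim maximal trailing run of below-threshold bases
    keepUpTo <- n
    while (keepUpTo >= 1L && bad[keepUpTo]) keepUpTo <- keepUpTo - 1L
    if (keepUpTo < fractionThreshold * n)
      return(list(status = "discarded_short", seq = seq, qual = qual))
    list(status = "kept",
         seq = substr(seq, 1L, keepUpTo),
         qual = substr(qual, 1L, keepUpTo))
  }

  n <- nrow(pairs)
  status1 <- character(n); status2 <- character(n)
  s1 <- pairs$seq1; q1 <- pairs$qual1; s2 <- pairs$seq2; q2 <- pairs$qual2
  for (i in seq_len(n)) {
    m1 <- processMate(s1[i], q1[i]); m2 <- processMate(s2[i], q2[i])
    status1[i] <- m1$status; status2[i] <- m2$status
    s1[i] <- m1$seq; q1[i] <- m1$qual; s2[i] <- m2$seq; q2[i] <- m2$qual
  }
  ## a kept mate whose partner failed is discarded for the mate's sake
  mateFail1 <- status1 == "kept" & status2 != "kept"
  mateFail2 <- status2 == "kept" & status1 != "kept"
  status1[mateFail1] <- "discarded_mate"
  status2[mateFail2] <- "discarded_mate"
  keptPair <- status1 == "kept" & status2 == "kept"

  kept <- data.frame(id = pairs$id[keptPair],
                     seq1 = s1[keptPair], qual1 = q1[keptPair],
                     seq2 = s2[keptPair], qual2 = q2[keptPair],
                     stringsAsFactors = FALSE)
  disposition <- factor(c(status1, status2),
                        levels = c("kept", "discarded_quality",
                                   "discarded_short", "discarded_mate"))
  list(kept = kept,
       report = list(reads_in = 2L * n, reads_out = 2L * sum(keptPair),
                     disposition = disposition))
}

#' Sample-level read-retention gate
#'
#' A sample fails when fewer than `minFraction` (default 50%) of its reads
#' survive preprocessing; exactly the threshold passes.
#'
#' @param report The `report` element of [preprocessReads()].
#' @param minFraction Minimum retained fraction (default 0.50).
#' @return `"pass"` or `"fail"`.
#' @export
sampleReadGate <- function(report, minFraction = 0.50) {
  if (is.null(report$reads_in) || report$reads_in == 0L)
    stop("report has zero input reads")
  if (report$reads_out / report$reads_in < minFraction) "fail" else "pass"
}

#' Build a graft/host canonical k-mer index
#'
#' Enumerates the canonical k-mers (lexicographic minimum of k-mer and
#' reverse complement) of both reference sets and partitions them into
#' graft-only, host-only and shared sets. K-mers containing non-ACGT
#' symbols are skipped. `k = 25` matches the default of the Xenome
#' classifier this partition emulates.
#'
#' @param graft,host [Biostrings::DNAStringSet] reference sets (or
#'   character vectors of sequences).
#' @param k K-mer length (default 25).
#' @return A [KmerIndex-class].
#' @examples
#' idx <- buildKmerIndex(Biostrings::DNAStringSet("ACGTACGTAC"),
#'                       Biostrings::DNAStringSet("ACGTTTTTTT"), k = 4)
#' @export
buildKmerIndex <- function(graft, host, k = 25L) {
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  asChr <- function(x) if (is.character(x)) x else as.character(x)
  gseq <- asChr(graft); hseq <- asChr(host)
  if (length(gseq) == 0L || length(hseq) == 0L)
    stop("references must be non-empty")
  if (k > min(nchar(c(gseq, hseq))))
    stop("'k' exceeds the shortest reference sequence length")
  kmerSet <- function(seqs) {
    km <- unlist(lapply(seqs, extractKmers, k = k), use.names = FALSE)
    unique(canonicalKmers(km))
  }
  g <- kmerSet(gseq); h <- kmerSet(hseq)
  shared <- intersect(g, h)
  new("KmerIndex", k = k,
      graftOnly = setdiff(g, shared),
      hostOnly = setdiff(h, shared),
      shared = shared)
}

#' Classify a read against a k-mer index
#'
#' Counts the read's canonical k-mers falling in each index partition
#' (graft-only `g`, host-only `h`, shared `s`) and applies the rule:
#' `g>0 & h=0` human; `h>0 & g=0` mouse; `g=0 & h=0 & s>0` both;
#' `g>0 & h>0` ambiguous; all zero (including reads shorter than k)
#' neither. Classification is strand-agnostic because k-mers are stored
#' canonically.
#'
#' @param read Character scalar DNA sequence.
#' @param index A [KmerIndex-class].
#' @return List with `category` and the hit counts `g`, `h`, `s`, `n`
#'   (unmatched).
#' @export
classifyRead <- function(read, index) {
  stopifnot(is(index, "KmerIndex"))
  km <- canonicalKmers(extractKmers(read, index@k))
  g <- sum(km %in% index@graftOnly)
  h <- sum(km %in% index@hostOnly)
  s <- sum(km %in% index@shared)
  n <- length(km) - g - h - s
  category <- if (g > 0L && h == 0L) "human"
  else if (h > 0L && g == 0L) "mouse"
  else if (g == 0L && h == 0L && s > 0L) "both"
  else if (g > 0L && h > 0L) "ambiguous"
  else "neither"
  list(category = category, g = g, h = h, s = s, n = n)
}

#' Classify many reads
#'
#' @param reads Character vector of read sequences.
#' @inheritParams classifyRead
#' @return Character vector of categories, one per read.
#' @export
classifyReads <- function(reads, index) {
  vapply(reads, function(r) classifyRead(r, index)$category, character(1),
         USE.NAMES = FALSE)
}

#' Retain pairs with both mates classified human
#'
#' Applies the paired-read retention rule of the host-removal step: only
#' read pairs with both mates classified `human` are kept for variant
#' calling. Also reports per-category read counts and the fraction of
#' mouse-classified reads, a standard sample-level contamination
#' statistic.
#'
#' @param category1,category2 Character vectors of per-mate categories
#'   from [classifyReads()].
#' @return List with `keep` (logical per pair), `counts` (named category
#'   counts over all reads) and `fraction_mouse`.
#' @export
filterReadPairs <- function(category1, category2) {
  stopifnot(length(category1) == length(category2))
  lev <- c("human", "mouse", "both", "neither", "ambiguous")
  all_cat <- factor(c(category1, category2), levels = lev)
  counts <- table(all_cat)
  keep <- category1 == "human" & category2 == "human"
  list(keep = keep, counts = counts,
       fraction_mouse = if (length(all_cat)) unname(counts["mouse"]) /
         length(all_cat) else NA_real_)
}

#' Target-coverage gate
#'
#' A sample fails when less than `minFraction` (default 75%) of target
#' bases are covered at >= `minDepth` (default 100X) by human-classified
#' reads.
#'
#' @param depth Integer vector of per-base depth over the target region.
#' @param minDepth Depth threshold (default 100).
#' @param minFraction Minimum fraction of target bases at or above
#'   `minDepth` (default 0.75).
#' @return `"pass"` or `"fail"`.
#' @export
coverageGate <- function(depth, minDepth = 100, minFraction = 0.75) {
  if (length(depth) == 0L) stop("empty target region")
  if (mean(depth >= minDepth) < minFraction) "fail" else "pass"
}
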