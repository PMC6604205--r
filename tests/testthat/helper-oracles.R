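## Independent brute-force oracles, deliberately implemented without the
## package's own helpers (character-level loops only).

bfRevComp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

bfKmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  out <- character(0)
  for (i in seq_len(n - k + 1)) {
    km <- substr(seq, i, i + k - 1)
    if (!grepl("[^ACGT]", km)) out <- c(out, km)
  }
  out
}

bfCanonical <- function(kmers) {
  vapply(kmers, function(s) {
    rc <- bfRevComp(s)
    if (s <= rc) s else rc
  }, character(1), USE.NAMES = FALSE)
}

## brute-force five-way read classification against raw reference sequences
bfClassifyRead <- function(read, graftSeqs, hostSeqs, k) {
  gset <- unique(bfCanonical(unlist(lapply(graftSeqs, bfKmers, k = k))))
  hset <- unique(bfCanonical(unlist(lapply(hostSeqs, bfKmers, k = k))))
  shared <- intersect(gset, hset)
  gOnly <- setdiff(gset, shared)
  hOnly <- setdiff(hset, shared)
  km <- bfCanonical(bfKmers(read, k))
  g <- sum(km %in% gOnly); h <- sum(km %in% hOnly); s <- sum(km %in% shared)
  if (g > 0 && h == 0) "human"
  else if (h > 0 && g == 0) "mouse"
  else if (g == 0 && h == 0 && s > 0) "both"
  else if (g > 0 && h > 0) "ambiguous"
  else "neither"
}

## per-base scan oracle for gene-level copy number
bfGeneCn <- function(segments, gene) {
  cns <- numeric(0); segIdx <- integer(0); lohHit <- logical(0)
  for (b in gene$start:gene$end) {
    for (i in seq_len(nrow(segments))) {
      if (segments$chrom[i] == gene$chrom &&
          segments$start[i] <= b && segments$end[i] >= b) {
        cns <- c(cns, segments$nMajor[i] + segments$nMinor[i])
        segIdx <- c(segIdx, i)
        lohHit <- c(lohHit, segments$nMajor[i] >= 0.5 &&
                      segments$nMinor[i] <= 0.1)
      }
    }
  }
  if (length(cns) == 0)
    return(list(total_cn = NA_real_, n_segments = 0L, loh = NA))
  list(total_cn = min(cns), n_segments = length(unique(segIdx)),
       loh = any(lohHit))
}

## hypergeometric upper tail by direct enumeration with choose()
bfHyperTail <- function(obs, sizeA, sizeB, sizeU) {
  kk <- obs:min(sizeA, sizeB)
  sum(choose(sizeB, kk) * choose(sizeU - sizeB, sizeA - kk)) /
    choose(sizeU, sizeA)
}

## small variant-call row builder with clean defaults
makeCall <- function(sample_id = "S1", chrom = "chr1", pos = 100L,
                     ref = "A", alt = "T", vtype = "snv", caller = "gatk",
                     DP = 500L, ALT_AF = 0.25, QD = 10, FS = 1, MQ = 60,
                     MQRankSum = 0, ReadPosRankSum = 0,
                     effect = "non_silent_coding", gene = "GENE1", ...) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, vtype = vtype, caller = caller, DP = DP,
             ALT_AF = ALT_AF, QD = QD, FS = FS, MQ = MQ,
             MQRankSum = MQRankSum, ReadPosRankSum = ReadPosRankSum,
             effect = effect, gene = gene, ...,
             stringsAsFactors = FALSE)
}

emptyResource <- function() {
  buildGermlineResource(publicSources = data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), source = character(0), maf = numeric(0)))
}

makeResource <- function(chrom, pos, ref, alt, source = "dbsnp") {
  buildGermlineResource(publicSources = data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt, source = source,
    maf = NA_real_, stringsAsFactors = FALSE))
}

makeKb <- function(chrom = NA, pos = NA, ref = NA, alt = NA,
                   gene = NA, protein_change = NA,
                   tags = "treatment_approach") {
  new("ClinicalKB", entries = data.frame(
    gene = gene, protein_change = protein_change, chrom = chrom,
    pos = pos, ref = ref, alt = alt, tags = tags,
    stringsAsFactors = FALSE))
}

## quality string of n bases at a given Phred score
qualStr <- function(n, q = 37) strrep(intToUtf8(q + 33), n)
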