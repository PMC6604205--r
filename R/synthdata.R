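#' Simulation configuration for synthetic PDX inputs
#'
#' Bundles the parameters shared by the synthetic-data generators. Defaults
#' reproduce the benchmarking conditions of the targeted-panel simulation
#' study this package models: 150 bp paired-end reads at 500/1000/1500-fold
#' coverage with host (mouse) reads spiked at 10/15/25% of total coverage,
#' graft/host sequence divergence of 15% (the average mouse/human
#' protein-coding divergence), spiked variants spanning germline-like and
#' somatic-like allele fractions, and cohort-recurrent systematic
#' artifacts.
#'
#' @param seed Integer seed; identical seeds give bit-identical outputs.
#' @param refLength Reference length in bases.
#' @param divergence Per-base substitution fraction between graft and host
#'   references, in `[0, 1]`.
#' @param coverage Fold coverage of the simulated sample (benchmark grid:
#'   500, 1000, 1500).
#' @param contaminationFraction Fraction of total coverage contributed by
#'   host-origin read pairs, in `[0, 1)` (benchmark grid: 0.10/0.15/0.25).
#' @param readLength Read length in bases.
#' @param baseErrorRate Per-base substitution error probability.
#' @param nSamples Number of cohort samples for variant-cohort simulation.
#' @param germlineAfSet Allele fractions for planted germline variants
#'   (default heterozygous 0.5 and homozygous 1.0).
#' @param somaticAfRange Numeric `[min, max]` of somatic allele fractions,
#'   within `(0, 1]`.
#' @param fpRecurrence Minimum fraction of samples sharing each planted
#'   systematic-artifact locus.
#' @param nGermline,nSomatic,nArtifact Numbers of planted germline loci
#'   (cohort-level), somatic loci (per sample) and artifact loci.
#' @param germlineCarrierRate Probability that a given sample carries a
#'   given germline locus.
#' @param qualityFailFraction Fraction of emitted calls drawn from the
#'   "failing" quality-annotation regime (outside the hard-filter pass
#'   region); the rest are drawn from the "clean" regime.
#' @param lowQualTailFraction Fraction of simulated reads receiving a
#'   low-quality 3' tail, so preprocessing rules are exercisable.
#'
#' @return A validated list of class `SimConfig`.
#' @examples
#' cfg <- simConfig(seed = 1, refLength = 5000, coverage = 100)
#' @export
simConfig <- function(seed = 1L,
                      refLength = 10000L,
                      divergence = 0.15,
                      coverage = 500,
                      contaminationFraction = 0.15,
                      readLength = 150L,
                      baseErrorRate = 0.001,
                      nSamples = 20L,
                      germlineAfSet = c(0.5, 1.0),
                      somaticAfRange = c(0.05, 1.0),
                      fpRecurrence = 0.30,
                      nGermline = 50L,
                      nSomatic = 30L,
                      nArtifact = 10L,
                      germlineCarrierRate = 0.8,
                      qualityFailFraction = 0,
                      lowQualTailFraction = 0.2) {
  if (divergence < 0 || divergence > 1)
    stop("'divergence' must lie in [0, 1]")
  if (contaminationFraction < 0 || contaminationFraction >= 1)
    stop("'contaminationFraction' must lie in [0, 1)")
  if (coverage <= 0) stop("'coverage' must be positive")
  if (length(somaticAfRange) != 2L || somaticAfRange[1] <= 0 ||
      somaticAfRange[2] > 1 || somaticAfRange[1] > somaticAfRange[2])
    stop("'somaticAfRange' must be an increasing pair within (0, 1]")
  if (any(germlineAfSet <= 0) || any(germlineAfSet > 1))
    stop("'germlineAfSet' values must lie in (0, 1]")
  if (fpRecurrence < 0 || fpRecurrence > 1)
    stop("'fpRecurrence' must lie in [0, 1]")
  if (nSamples < 1L) stop("'nSamples' must be >= 1")
  structure(list(
    seed = as.integer(seed), refLength = as.integer(refLength),
    divergence = divergence, coverage = coverage,
    contaminationFraction = contaminationFraction,
    readLength = as.integer(readLength), baseErrorRate = baseErrorRate,
    nSamples = as.integer(nSamples), germlineAfSet = germlineAfSet,
    somaticAfRange = somaticAfRange, fpRecurrence = fpRecurrence,
    nGermline = as.integer(nGermline), nSomatic = as.integer(nSomatic),
    nArtifact = as.integer(nArtifact),
    germlineCarrierRate = germlineCarrierRate,
    qualityFailFraction = qualityFailFraction,
    lowQualTailFraction = lowQualTailFraction),
    class = "SimConfig")
}

## fixed per-generator RNG offsets (one stream per generator, so adding a
## generator call does not perturb the others)
.SEED_OFFSET <- c(refs = 101L, reads = 202L, variants = 303L,
                  expression = 404L, cn = 505L)

#' Simulate a graft/host reference pair
#'
#' Draws a random graft (human-like) reference and derives the host
#' (mouse-like) reference by i.i.d. substitutions at rate
#' `config$divergence`; a stand-in for targeted-panel regions of the human
#' genome and the corresponding host-strain sequence.
#'
#' @param config A [simConfig()] object.
#' @return List with `graft` and `host` [Biostrings::DNAStringSet]
#'   (one contig each, named `target`).
#' @examples
#' refs <- simulateReferencePair(simConfig(seed = 1, refLength = 2000))
#' @export
simulateReferencePair <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$refLength < 10L * config$readLength)
    stop("'refLength' must be >= 10 * readLength")
  withSeed(config$seed + .SEED_OFFSET[["refs"]], {
    graft <- sample(DNA_BASES_CHR, config$refLength, replace = TRUE)
    host <- graft
    flip <- runif(config$refLength) < config$divergence
    if (any(flip)) {
      ## substitute to a uniformly chosen different base
      host[flip] <- vapply(graft[flip], function(b)
        sample(setdiff(DNA_BASES_CHR, b), 1L), character(1), USE.NAMES = FALSE)
    }
    list(graft = Biostrings::DNAStringSet(setNames(paste(graft, collapse = ""),
                                                   "target")),
         host = Biostrings::DNAStringSet(setNames(paste(host, collapse = ""),
                                                  "target")))
  })
}

#' Simulate contaminated paired-end reads with origin labels
#'
#' Generates paired-end reads from the graft reference with a fraction of
#' pairs (`config$contaminationFraction`) drawn from the host reference,
#' emulating mouse stromal contamination of PDX sequencing libraries.
#' Base-call errors are substitutions at `config$baseErrorRate`; a fraction
#' of reads carry a low-quality 3' tail so that quality trimming rules can
#' be exercised. The number of pairs is
#' `round(coverage * refLength / (2 * readLength))`.
#'
#' @param config A [simConfig()] object.
#' @param graft,host Reference `DNAStringSet`s from
#'   [simulateReferencePair()].
#' @return List with `pairs` (data.frame: `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`; Sanger-encoded qualities) and `origin` (character vector,
#'   `"graft"` or `"host"` per pair).
#' @export
simulateReadSet <- function(config, graft, host) {
  stopifnot(inherits(config, "SimConfig"))
  nPairs <- round(config$coverage * config$refLength /
                  (2 * config$readLength))
  if (nPairs < 1L) stop("coverage too low: zero read pairs would be generated")
  gseq <- as.character(graft[[1]])
  hseq <- as.character(host[[1]])
  rl <- config$readLength
  frag <- 2L * rl + 50L
  if (nchar(gseq) < frag) stop("reference shorter than one fragment")
  withSeed(config$seed + .SEED_OFFSET[["reads"]], {
    origin <- ifelse(runif(nPairs) < config$contaminationFraction,
                     "host", "graft")
    starts <- sample.int(nchar(gseq) - frag + 1L, nPairs, replace = TRUE)
    template <- ifelse(origin == "host", hseq, gseq)
    fragSeq <- substring(template, starts, starts + frag - 1L)
    r1 <- substring(fragSeq, 1L, rl)
    r2 <- revComp(substring(fragSeq, frag - rl + 1L, frag))
    addErrors <- function(reads) {
      vapply(reads, function(s) {
        b <- strsplit(s, "", fixed = TRUE)[[1]]
        err <- which(runif(length(b)) < config$baseErrorRate)
        for (i in err) b[i] <- sample(setdiff(DNA_BASES_CHR, b[i]), 1L)
        paste(b, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    r1 <- addErrors(r1); r2 <- addErrors(r2)
    makeQual <- function(n) {
      vapply(seq_len(n), function(i) {
        q <- pmax(pmin(round(rnorm(rl, 37, 2)), 40L), 30L)
        if (runif(1) < config$lowQualTailFraction) {
          tail_len <- sample.int(max(1L, floor(0.4 * rl)), 1L)
          q[(rl - tail_len + 1L):rl] <- sample(2:20, tail_len, replace = TRUE)
        }
        intToPhred(list(q))
      }, character(1))
    }
    pairs <- data.frame(
      id = sprintf("read_%06d", seq_len(nPairs)),
      seq1 = r1, qual1 = makeQual(nPairs),
      seq2 = r2, qual2 = makeQual(nPairs),
      stringsAsFactors = FALSE)
    list(pairs = pairs, origin = origin)
  })
}

#' Simulate a variant-call cohort with planted truth labels
#'
#' Emulates per-sample tumor-only variant-call tables at the point where
#' the bespoke filtering computation begins (after alignment and calling),
#' together with a truth set and a matching germline resource. Three
#' classes of loci are planted: cohort-level germline loci (allele
#' fractions from `germlineAfSet`, present in the germline resource),
#' per-sample somatic loci (allele fractions uniform in `somaticAfRange`,
#' absent from the resource) and systematic-artifact loci shared by at
#' least `fpRecurrence` of samples at mid-range allele fraction and absent
#' from the resource. Observed allele fractions are binomially sampled at
#' the per-locus depth (Poisson around `coverage`); quality annotations
#' are drawn from a "clean" regime inside the hard-filter pass region or,
#' with probability `qualityFailFraction`, a "failing" regime outside it.
#' Planted variants whose sampled alternate read count is zero are absent
#' from the call table (the caller would not see them) but retained in the
#' truth set.
#'
#' @param config A [simConfig()] object.
#' @return List with `calls` (data.frame of variant calls: `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `vtype`, `caller`, `DP`, `ALT_AF`,
#'   `QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`, `effect`, `gene`),
#'   `truth` (data.frame: `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `true_af`, `label` in germline/somatic/artifact) and `resource`
#'   (a [GermlineResource-class] holding the planted germline alleles).
#' @examples
#' cohort <- simulateVariantCohort(simConfig(seed = 1, nSamples = 4))
#' table(cohort$truth$label)
#' @export
simulateVariantCohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  withSeed(config$seed + .SEED_OFFSET[["variants"]], {
    n <- config$nSamples
    samples <- sprintf("PDX%03d", seq_len(n))
    nPos <- config$nGermline + config$nArtifact + n * config$nSomatic
    if (nPos > config$refLength)
      stop("refLength too small for the requested number of planted loci")
    pool <- sample.int(config$refLength, nPos)
    germPos <- pool[seq_len(config$nGermline)]
    artPos <- pool[config$nGermline + seq_len(config$nArtifact)]
    somPool <- pool[-(seq_len(config$nGermline + config$nArtifact))]
    refAllele <- sample(DNA_BASES_CHR, nPos, replace = TRUE)
    names(refAllele) <- as.character(pool)
    altOf <- function(ref) vapply(ref, function(b)
      sample(setdiff(DNA_BASES_CHR, b), 1L), character(1), USE.NAMES = FALSE)
    altAllele <- altOf(refAllele)
    names(altAllele) <- names(refAllele)

    rows <- list()
    addRows <- function(sample_id, pos, true_af, label) {
      if (length(pos) == 0L) return(invisible(NULL))
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sample_id, chrom = "chr1", pos = pos,
        ref = refAllele[as.character(pos)],
        alt = altAllele[as.character(pos)],
        true_af = true_af, label = label, stringsAsFactors = FALSE,
        row.names = NULL)
    }

    ## germline: cohort-level loci, each carried by a sample with prob
    ## germlineCarrierRate, AF drawn from the het/hom set
    for (s in samples) {
      carried <- germPos[runif(length(germPos)) < config$germlineCarrierRate]
      if (length(carried))
        addRows(s, carried,
                sample(config$germlineAfSet, length(carried), replace = TRUE),
                "germline")
    }
    ## somatic: private per-sample loci
    if (config$nSomatic > 0L) {
      for (i in seq_len(n)) {
        pos <- somPool[(i - 1L) * config$nSomatic + seq_len(config$nSomatic)]
        addRows(samples[i], pos,
                runif(config$nSomatic, config$somaticAfRange[1],
                      config$somaticAfRange[2]), "somatic")
      }
    }
    ## artifacts: each locus planted in >= fpRecurrence of samples
    minCarriers <- ceiling(config$fpRecurrence * n)
    for (p in artPos) {
      k <- if (minCarriers >= n) n else sample(minCarriers:n, 1L)
      carriers <- sample(samples, k)
      for (s in carriers) addRows(s, p, runif(1, 0.10, 0.35), "artifact")
    }
    truth <- do.call(rbind, rows)
    truth <- truth[order(truth$sample_id, truth$pos), , drop = FALSE]
    rownames(truth) <- NULL

    ## observed calls: depth Poisson around coverage, AF binomial
    m <- nrow(truth)
    DP <- pmax(rpois(m, config$coverage), 1L)
    altReads <- rbinom(m, DP, truth$true_af)
    failing <- runif(m) < config$qualityFailFraction
    QD <- runif(m, 5, 35); FS <- runif(m, 0, 30); MQ <- runif(m, 50, 60)
    MQRankSum <- runif(m, -3, 3); ReadPosRankSum <- runif(m, -3, 3)
    if (any(failing)) {
      ## one hard-filter annotation pushed outside its pass region
      which_fail <- sample(5L, sum(failing), replace = TRUE)
      idx <- which(failing)
      QD[idx[which_fail == 1L]] <- runif(sum(which_fail == 1L), 0, 1.9)
      FS[idx[which_fail == 2L]] <- runif(sum(which_fail == 2L), 61, 200)
      MQ[idx[which_fail == 3L]] <- runif(sum(which_fail == 3L), 10, 39)
      MQRankSum[idx[which_fail == 4L]] <- runif(sum(which_fail == 4L), -20, -13)
      ReadPosRankSum[idx[which_fail == 5L]] <-
        runif(sum(which_fail == 5L), -20, -9)
    }
    effect <- sample(c("non_silent_coding", "silent", "noncoding"), m,
                     replace = TRUE, prob = c(0.7, 0.2, 0.1))
    gene <- sprintf("GENE%03d", (truth$pos - 1L) %/%
                      ceiling(config$refLength / 50L) + 1L)
    calls <- data.frame(
      sample_id = truth$sample_id, chrom = truth$chrom, pos = truth$pos,
      ref = truth$ref, alt = truth$alt, vtype = "snv", caller = "gatk",
      DP = DP, ALT_AF = altReads / DP, QD = QD, FS = FS, MQ = MQ,
      MQRankSum = MQRankSum, ReadPosRankSum = ReadPosRankSum,
      effect = effect, gene = gene, stringsAsFactors = FALSE)
    calls <- calls[altReads > 0L, , drop = FALSE]
    rownames(calls) <- NULL

    resEntries <- data.frame(
      chrom = "chr1", pos = germPos,
      ref = refAllele[as.character(germPos)],
      alt = altAllele[as.character(germPos)],
      sources = "dbsnp", maf = NA_real_,
      stringsAsFactors = FALSE, row.names = NULL)
    resource <- new("GermlineResource", entries = resEntries, nNormals = 20L)
    list(calls = calls, truth = truth, resource = resource)
  })
}

#' Simulate an expression cohort with a planted EBV-like signature
#'
#' Negative-binomial counts for `nEbv + nOther` samples; a planted
#' signature of `signatureSize` genes (half shifted up by `effect` on the
#' log2 scale in the EBV group, half shifted down), all other genes
#' exchangeable across groups. Emulates a cohort in which a subset of PDX
#' samples progressed to EBV-associated lymphoma with a reproducible
#' transcriptional program.
#'
#' @param nEbv,nOther Group sizes (each >= 2; published cohort 20 vs 100).
#' @param signatureSize Even number of planted genes (default 48: 24 up,
#'   24 down).
#' @param effect Log2 fold shift of planted genes (> 0).
#' @param seed Integer seed.
#' @param nGenes Total number of genes.
#' @param nbSize Negative-binomial size (dispersion = 1/nbSize).
#' @return List with `counts` (genes x samples integer matrix), `labels`
#'   (character, `"EBV"`/`"non_EBV"`), `signature` (data.frame `gene`,
#'   `sign`) and `humanReads` (per-sample human read counts, all above
#'   the expression gate).
#' @examples
#' sim <- simulateExpressionCohort(nEbv = 3, nOther = 5, signatureSize = 4,
#'                                 effect = 2, seed = 1, nGenes = 100)
#' @export
simulateExpressionCohort <- function(nEbv = 20L, nOther = 100L,
                                     signatureSize = 48L, effect = 2,
                                     seed = 1L, nGenes = 2000L,
                                     nbSize = 10) {
  if (nEbv < 2L || nOther < 2L) stop("'nEbv' and 'nOther' must each be >= 2")
  if (signatureSize %% 2L != 0L) stop("'signatureSize' must be even")
  if (effect <= 0) stop("'effect' must be positive")
  if (signatureSize > nGenes) stop("'signatureSize' exceeds 'nGenes'")
  withSeed(seed + .SEED_OFFSET[["expression"]], {
    genes <- sprintf("GENE%04d", seq_len(nGenes))
    samples <- c(sprintf("EBV%03d", seq_len(nEbv)),
                 sprintf("PDX%03d", seq_len(nOther)))
    labels <- c(rep("EBV", nEbv), rep("non_EBV", nOther))
    baseMu <- 2^runif(nGenes, 3, 10)          # base expression, log-uniform
    sigIdx <- sample.int(nGenes, signatureSize)
    upIdx <- sigIdx[seq_len(signatureSize / 2L)]
    downIdx <- sigIdx[(signatureSize / 2L + 1L):signatureSize]
    mu <- matrix(baseMu, nGenes, nEbv + nOther)
    mu[upIdx, labels == "EBV"] <- mu[upIdx, labels == "EBV"] * 2^effect
    mu[downIdx, labels == "EBV"] <- mu[downIdx, labels == "EBV"] * 2^(-effect)
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = nbSize),
                     nGenes, nEbv + nOther,
                     dimnames = list(genes, samples))
    signature <- data.frame(
      gene = genes[c(upIdx, downIdx)],
      sign = rep(c(1L, -1L), each = signatureSize / 2L),
      stringsAsFactors = FALSE)
    humanReads <- round(colSums(counts) * runif(ncol(counts), 2, 4))
    list(counts = counts, labels = setNames(labels, samples),
         signature = signature, humanReads = humanReads)
  })
}

#' Length-weighted mean total copy number (ploidy) of a segment table
#'
#' @param segments data.frame with `start`, `end` (1-based inclusive),
#'   `nMajor`, `nMinor` for one sample.
#' @return Numeric ploidy.
#' @examples
#' segs <- data.frame(chrom = "chr1", start = c(1, 501), end = c(500, 1000),
#'                    nMajor = c(2, 1), nMinor = c(2, 1))
#' computePloidy(segs)  # 3
#' @export
computePloidy <- function(segments) {
  len <- segments$end - segments$start + 1
  total <- segments$nMajor + segments$nMinor
  sum(len * total) / sum(len)
}

#' Simulate allele-specific copy-number profiles
#'
#' Per-sample segment tables emulating allele-specific copy-number caller
#' output: segments tile each chromosome without gaps or overlaps, each
#' carrying integer major/minor allele copy numbers, and the per-sample
#' ploidy equals the length-weighted mean total copy number. Optionally a
#' coupled expression matrix is produced in which each gene's log2(TPM+1)
#' equals a per-gene baseline plus `log2(CN/ploidy)` plus Gaussian noise,
#' so copy-number-driven expression changes are recoverable by
#' construction.
#'
#' @param nSamples Number of samples.
#' @param genes data.frame of gene models: `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive), sorted and non-overlapping within chromosome.
#' @param seed Integer seed.
#' @param coupleExpression Logical; also emit a coupled expression matrix.
#' @param noiseSd Gaussian noise SD on coupled expression (0 gives exact
#'   coupling).
#' @return List with `segments` (`sample`, `chrom`, `start`, `end`,
#'   `nMajor`, `nMinor`), `ploidy` (`sample`, `ploidy`) and, when
#'   requested, `expression` (genes x samples matrix of log2(TPM+1)-scale
#'   values).
#' @examples
#' genes <- data.frame(gene = c("G1", "G2"), chrom = "chr1",
#'                     start = c(100, 5000), end = c(600, 6000))
#' prof <- simulateCnProfiles(3, genes, seed = 1)
#' @export
simulateCnProfiles <- function(nSamples, genes, seed = 1L,
                               coupleExpression = FALSE, noiseSd = 0.1) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)))
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) > 1L && any(g$start[-1L] <= g$end[-nrow(g)]))
      stop("gene models must be non-overlapping within a chromosome")
  }
  withSeed(seed + .SEED_OFFSET[["cn"]], {
    samples <- sprintf("PDX%03d", seq_len(nSamples))
    chromLen <- vapply(split(genes$end, genes$chrom), max, numeric(1)) + 1000
    segRows <- list()
    for (s in samples) {
      for (ch in names(chromLen)) {
        nBreaks <- sample(0:4, 1L)
        bounds <- sort(unique(c(1, chromLen[[ch]] + 1,
                                if (nBreaks) sample.int(chromLen[[ch]] - 1L,
                                                        nBreaks) + 1L)))
        starts <- bounds[-length(bounds)]
        ends <- bounds[-1L] - 1L
        nMinor <- sample(0:2, length(starts), replace = TRUE,
                         prob = c(0.25, 0.6, 0.15))
        nMajor <- nMinor + sample(0:3, length(starts), replace = TRUE,
                                  prob = c(0.45, 0.3, 0.15, 0.1))
        nMajor <- pmax(nMajor, 1L)  # avoid fully null segments
        segRows[[length(segRows) + 1L]] <- data.frame(
          sample = s, chrom = ch, start = starts, end = ends,
          nMajor = nMajor, nMinor = nMinor, stringsAsFactors = FALSE)
      }
    }
    segments <- do.call(rbind, segRows)
    rownames(segments) <- NULL
    ploidy <- do.call(rbind, lapply(samples, function(s) {
      data.frame(sample = s,
                 ploidy = computePloidy(segments[segments$sample == s, ]),
                 stringsAsFactors = FALSE)
    }))
    out <- list(segments = segments, ploidy = ploidy)
    if (coupleExpression) {
      baseline <- runif(nrow(genes), 2, 8)
      expr <- matrix(NA_real_, nrow(genes), nSamples,
                     dimnames = list(genes$gene, samples))
      for (j in seq_along(samples)) {
        segs <- segments[segments$sample == samples[j], , drop = FALSE]
        pl <- ploidy$ploidy[j]
        for (i in seq_len(nrow(genes))) {
          ov <- segs$chrom == genes$chrom[i] &
            segs$start <= genes$end[i] & segs$end >= genes$start[i]
          cn <- min(segs$nMajor[ov] + segs$nMinor[ov])
          expr[i, j] <- baseline[i] + log2(max(cn, 0.5) / pl) +
            (if (noiseSd > 0) rnorm(1, 0, noiseSd) else 0)
        }
      }
      out$expression <- expr
    }
    out
  })
}
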