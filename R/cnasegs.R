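#' Loss-of-heterozygosity call for allele-specific segments
#'
#' A segment is LOH when the major-allele copy number is >= 0.5 and the
#' minor-allele copy number is <= 0.1 (fractional allele-specific copy
#' numbers are accepted unrounded).
#'
#' @param nMajor,nMinor Numeric vectors of allele-specific copy numbers.
#' @return Logical vector.
#' @examples
#' callLoh(c(2, 1, 0.4), c(0.05, 1, 0))  # TRUE FALSE FALSE
#' @export
callLoh <- function(nMajor, nMinor) {
  nMajor >= 0.5 & nMinor <= 0.1
}

#' Gene-level copy number and LOH from allele-specific segments
#'
#' Intersects gene models with a sample's copy-number segments. When a
#' segment boundary falls inside a gene, the most conservative (lowest)
#' total copy number over the overlapping segments represents the whole
#' gene, and the gene is annotated with the number of overlapping
#' segments. A gene is LOH when any overlapping segment is LOH. Genes
#' overlapping no segment get `NA` copy number. Alongside the raw copy
#' number, log2 ratios against the sample ploidy and against the diploid
#' state are reported, plus gain/loss calls under the requested baseline
#' (see [callGainLoss()]).
#'
#' @param segments data.frame for one sample: `chrom`, `start`, `end`
#'   (1-based inclusive), `nMajor`, `nMinor`; segments must not overlap
#'   within a chromosome.
#' @param genes data.frame of gene models: `gene`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param ploidy Sample mean cancer-genome ploidy.
#' @param baseline `"ploidy"` (default) or `"diploid"` — which log2 ratio
#'   drives the `call` column.
#' @return data.frame: `gene`, `total_cn`, `n_segments`, `loh`,
#'   `log2_vs_ploidy`, `log2_vs_diploid`, `call`, `baseline`.
#' @export
geneCopyNumber <- function(segments, genes, ploidy,
                           baseline = c("ploidy", "diploid")) {
  baseline <- match.arg(baseline)
  stopifnot(all(c("chrom", "start", "end", "nMajor", "nMinor") %in%
                  names(segments)),
            all(c("gene", "chrom", "start", "end") %in% names(genes)))
  if (any(segments$end < segments$start)) stop("segment end < start")
  segGr <- GenomicRanges::GRanges(segments$chrom,
                                  IRanges::IRanges(segments$start,
                                                   segments$end))
  if (!IRanges::isDisjoint(segGr))
    stop("segments overlap within a chromosome")
  geneGr <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$start, genes$end))
  ov <- GenomicRanges::findOverlaps(geneGr, segGr)
  total <- segments$nMajor + segments$nMinor
  segLoh <- callLoh(segments$nMajor, segments$nMinor)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  nSeg <- tabulate(qh, nbins = nrow(genes))
  totalCn <- rep(NA_real_, nrow(genes))
  loh <- rep(NA, nrow(genes))
  if (length(qh)) {
    minCn <- tapply(total[sh], qh, min)
    anyLoh <- tapply(segLoh[sh], qh, any)
    idx <- as.integer(names(minCn))
    totalCn[idx] <- as.numeric(minCn)
    loh[idx] <- as.logical(anyLoh)
  }
  baseValue <- if (baseline == "ploidy") ploidy else 2
  out <- data.frame(
    gene = genes$gene, total_cn = totalCn, n_segments = nSeg, loh = loh,
    log2_vs_ploidy = log2Ratio(totalCn, ploidy),
    log2_vs_diploid = log2Ratio(totalCn, 2),
    stringsAsFactors = FALSE)
  out$call <- callGainLoss(totalCn, baseValue)
  out$baseline <- baseline
  out
}

#' Ploidy- or diploid-relative gain/loss call
#'
#' Classifies a total copy number by `r = log2(CN / baseline)`:
#' `high_gain` for r > +1, `gain` for +0.4 < r <= +1, `normal` for
#' -0.4 <= r <= +0.4, `loss` for -1 <= r < -0.4, `high_loss` for r < -1.
#' Copy number 0 maps to `high_loss` without evaluating log2(0). The
#' low-level threshold of +-0.4 and the high-level threshold of +-1 are
#' the published cutoffs; the baseline is either the sample's mean
#' cancer-genome ploidy (recommended for aneuploid tumors) or the diploid
#' state 2.
#'
#' @param totalCn Numeric vector of total copy numbers (NA allowed).
#' @param baseline Positive baseline copy number (sample ploidy or 2).
#' @param lowThreshold,highThreshold Log2-ratio cutoffs (defaults 0.4, 1).
#' @return Character vector of calls (`NA` where `totalCn` is `NA`).
#' @examples
#' callGainLoss(c(2, 3, 6, 0), baseline = 2)
#' @export
callGainLoss <- function(totalCn, baseline, lowThreshold = 0.4,
                         highThreshold = 1.0) {
  if (any(baseline <= 0)) stop("'baseline' must be positive")
  r <- log2Ratio(totalCn, baseline)
  call <- rep(NA_character_, length(totalCn))
  ok <- !is.na(totalCn)
  call[ok & r > highThreshold] <- "high_gain"
  call[ok & r > lowThreshold & r <= highThreshold] <- "gain"
  call[ok & r >= -lowThreshold & r <= lowThreshold] <- "normal"
  call[ok & r < -lowThreshold & r >= -highThreshold] <- "loss"
  call[ok & r < -highThreshold] <- "high_loss"  # includes CN 0 (r = -Inf)
  call
}

#' Copy-number / expression concordance per gene
#'
#' For each gene, samples are classified into high-level copy-number
#' states by `log2(CN/ploidy)`: `high_loss` below -1, `normal` in
#' [-1, +1], `high_gain` above +1. The reference expression is the mean
#' `log2(TPM+1)` over samples in the stringent normal state
#' (-0.4 <= log2(CN/ploidy) <= 0.4); per-sample fold change is expression
#' minus that reference. Gain-state and loss-state fold changes are each
#' compared with normal-state fold changes by a two-sided two-sample
#' Student's t-test with pooled variance. A comparison with fewer than 2
#' samples in either state is reported untestable (NA).
#'
#' @param log2CnPloidy Genes x samples matrix of `log2(CN/ploidy)` values.
#' @param expression Genes x samples matrix of `log2(TPM+1)` expression,
#'   same dimnames.
#' @return data.frame per gene: mean fold change in normal/gain/loss
#'   states and `t_gain`, `p_gain`, `t_loss`, `p_loss`.
#' @export
cnExpressionConcordance <- function(log2CnPloidy, expression) {
  stopifnot(identical(dim(log2CnPloidy), dim(expression)),
            identical(rownames(log2CnPloidy), rownames(expression)))
  res <- lapply(seq_len(nrow(expression)), function(i) {
    r <- log2CnPloidy[i, ]
    state <- ifelse(r > 1, "high_gain",
                    ifelse(r < -1, "high_loss", "normal"))
    stringent <- !is.na(r) & r >= -0.4 & r <= 0.4
    refMean <- if (any(stringent)) mean(expression[i, stringent]) else NA_real_
    fc <- expression[i, ] - refMean
    tt <- function(a, b) {
      if (sum(!is.na(a)) < 2L || sum(!is.na(b)) < 2L)
        return(c(NA_real_, NA_real_))
      if (stats::var(a, na.rm = TRUE) == 0 &&
          stats::var(b, na.rm = TRUE) == 0) {
        if (mean(a, na.rm = TRUE) == mean(b, na.rm = TRUE))
          return(c(0, 1))         # identical constant groups: no effect
        return(c(Inf, 0))
      }
      ht <- t.test(a, b, var.equal = TRUE)
      c(unname(ht$statistic), ht$p.value)
    }
    gain <- tt(fc[state == "high_gain"], fc[state == "normal"])
    loss <- tt(fc[state == "high_loss"], fc[state == "normal"])
    data.frame(gene = rownames(expression)[i],
               mean_fc_normal = mean(fc[state == "normal"], na.rm = TRUE),
               mean_fc_gain = mean(fc[state == "high_gain"], na.rm = TRUE),
               mean_fc_loss = mean(fc[state == "high_loss"], na.rm = TRUE),
               t_gain = gain[1], p_gain = gain[2],
               t_loss = loss[1], p_loss = loss[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
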