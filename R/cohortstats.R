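#' Benchmark predicted variants against a truth set
#'
#' Confusion counts at (chrom, pos, alt) resolution over an explicit
#' universe of assessable loci: TP = predicted and true, FP = predicted
#' only, FN = true only, TN = neither. Precision is TP/(TP+FP) (0 when no
#' predictions), recall TP/(TP+FN), and
#' F1 = 2*(Recall*Precision)/(Recall+Precision) (0 when both are 0). The
#' allele-fraction correlation is the Pearson correlation of predicted
#' versus true allele fractions over true positives (NA with fewer than 2
#' true positives).
#'
#' @param predicted data.frame with `chrom`, `pos`, `alt` and optionally
#'   `ALT_AF`.
#' @param truth data.frame with `chrom`, `pos`, `alt` and optionally
#'   `true_af`.
#' @param universe data.frame with `chrom`, `pos`, `alt` enumerating the
#'   assessable loci; must contain every predicted and true locus.
#' @return A [BenchmarkResult-class].
#' @export
benchmarkCalls <- function(predicted, truth, universe) {
  key <- function(df) unique(paste(df$chrom, df$pos, df$alt, sep = ":"))
  pk <- key(predicted); tk <- key(truth); uk <- key(universe)
  if (!all(pk %in% uk))
    stop("predicted locus outside the assessable universe")
  if (!all(tk %in% uk))
    stop("truth locus outside the assessable universe")
  tp <- length(intersect(pk, tk))
  fp <- length(setdiff(pk, tk))
  fn <- length(setdiff(tk, pk))
  tn <- length(uk) - tp - fp - fn
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * recall * precision /
    (recall + precision) else 0
  afPearson <- NA_real_
  if (tp >= 2L && "ALT_AF" %in% names(predicted) &&
      "true_af" %in% names(truth)) {
    tpKeys <- intersect(pk, tk)
    predAf <- predicted$ALT_AF[match(tpKeys, paste(
      predicted$chrom, predicted$pos, predicted$alt, sep = ":"))]
    trueAf <- truth$true_af[match(tpKeys, paste(
      truth$chrom, truth$pos, truth$alt, sep = ":"))]
    if (sd(predAf) > 0 && sd(trueAf) > 0)
      afPearson <- cor(predAf, trueAf)
  }
  new("BenchmarkResult", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn), precision = precision,
      recall = recall, f1 = f1, afPearson = afPearson)
}

#' Per-sample mutational load
#'
#' Counts non-silent coding mutations in panel genes whose final pipeline
#' status is `somatic_pass` or `rescued_clinical`.
#'
#' @param trace data.frame with `effect`, `gene` and `final` columns (one
#'   sample's rows of a [runSomaticPipeline()] trace).
#' @param panelGenes Character vector of panel gene symbols.
#' @return Integer count.
#' @export
mutationalLoad <- function(trace, panelGenes) {
  if (is.null(trace) || nrow(trace) == 0L) return(0L)
  sum(trace$effect == "non_silent_coding" &
        trace$gene %in% panelGenes &
        trace$final %in% c("somatic_pass", "rescued_clinical"))
}

#' One-sided Fisher's exact test of mutated-gene overlap
#'
#' Builds the 2x2 table (in both sets / A only / B only / neither) over a
#' gene universe and tests overlap enrichment one-sided; the p-value
#' equals the hypergeometric upper tail P[X >= overlap].
#'
#' @param setA,setB Character vectors of genes, subsets of `universe`
#'   (e.g. genes mutated in >= 1 PDX sample, genes mutated at >= 5%
#'   frequency in a reference cohort).
#' @param universe Character vector of all assessable genes.
#' @return List with `table` (2x2 matrix) and `p`.
#' @export
geneOverlapFisher <- function(setA, setB, universe) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  setA <- unique(setA); setB <- unique(setB)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("sets must be subsets of the universe")
  both <- length(intersect(setA, setB))
  aOnly <- length(setA) - both
  bOnly <- length(setB) - both
  neither <- length(universe) - both - aOnly - bOnly
  tab <- matrix(c(both, aOnly, bOnly, neither), 2, 2,
                dimnames = list(inA = c("yes", "no"),
                                inB = c("yes", "no")))
  p <- fisher.test(tab, alternative = "greater")$p.value
  list(table = tab, p = p)
}

#' Hypergeometric p-value of set overlap
#'
#' P[overlap >= observed] when `|setA|` genes are drawn from the universe
#' and compared with `setB`.
#'
#' @inheritParams geneOverlapFisher
#' @return Numeric p-value.
#' @export
setOverlapHypergeom <- function(setA, setB, universe) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  setA <- unique(setA); setB <- unique(setB)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("sets must be subsets of the universe")
  obs <- length(intersect(setA, setB))
  if (obs == 0L) return(1)
  phyper(obs - 1L, length(setB), length(universe) - length(setB),
         length(setA), lower.tail = FALSE)
}

#' Per-gene over- and under-expression frequencies
#'
#' Fraction of samples with z-score strictly above `hi` (over-expressed)
#' or strictly below `lo` (under-expressed), per gene.
#'
#' @param z Genes x samples z-score matrix.
#' @param hi,lo Thresholds (defaults +1 and -1, strict inequalities).
#' @return data.frame: `gene`, `over_freq`, `under_freq`.
#' @export
expressionFrequencies <- function(z, hi = 1, lo = -1) {
  data.frame(gene = rownames(z),
             over_freq = rowMeans(z > hi),
             under_freq = rowMeans(z < lo),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson correlation of per-gene frequency vectors
#'
#' Correlates two cohorts' per-gene frequencies (over/under-expression or
#' copy-number gain/loss) over their shared genes. Returns NA when either
#' vector has zero variance.
#'
#' @param freqsA,freqsB Named numeric vectors (names are genes).
#' @return Pearson r, or NA when undefined.
#' @export
frequencyCorrelation <- function(freqsA, freqsB) {
  shared <- intersect(names(freqsA), names(freqsB))
  if (length(shared) < 3L)
    stop("need >= 3 shared genes")
  a <- freqsA[shared]; b <- freqsB[shared]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Top varying genes by expression variance
#'
#' Removes non-expressed genes (maximum per-cohort mean expression below
#' `expressionFloor` on the log2(TPM+1) scale) and returns the `n` genes
#' with the largest variance across samples of the supplied matrix.
#' Variance ties break lexicographically by gene identifier, so the
#' selection is deterministic. Note that a matrix z-normalized per gene
#' over the same samples has unit variance everywhere; pass log2-scale
#' expression, or z-scores standardized on a wider sample set than the
#' one being ranked.
#'
#' @param z Genes x samples matrix (log2(TPM+1) or z-scores).
#' @param n Number of genes to return (default 1000).
#' @param meanExpr Optional named vector or genes x cohorts matrix of mean
#'   log2(TPM+1) expression used for the floor; NULL skips the floor.
#' @param expressionFloor Expression floor (default 2).
#' @return Character vector of gene identifiers, highest variance first.
#' @export
topVaryingGenes <- function(z, n = 1000L, meanExpr = NULL,
                            expressionFloor = 2) {
  keep <- rep(TRUE, nrow(z))
  if (!is.null(meanExpr)) {
    maxExpr <- if (is.matrix(meanExpr)) apply(meanExpr, 1, max)
               else meanExpr
    stopifnot(identical(names(maxExpr), rownames(z)) ||
                all(rownames(z) %in% names(maxExpr)))
    keep <- maxExpr[rownames(z)] >= expressionFloor
  }
  zk <- z[keep, , drop = FALSE]
  if (n > nrow(zk))
    stop("'n' exceeds the number of expressed genes (", nrow(zk), ")")
  v <- apply(zk, 1, var)
  ord <- order(-v, rownames(zk))
  rownames(zk)[ord[seq_len(n)]]
}
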