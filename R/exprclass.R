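#' Minimum human-read gate for expression analysis
#'
#' Samples with fewer than one million human-classified reads are removed
#' before expression quantification; exactly the threshold passes.
#'
#' @param humanReads Named numeric vector of per-sample human read counts.
#' @param minReads Threshold (default 1e6).
#' @return Named character vector of `"pass"`/`"fail"` per sample.
#' @export
humanReadGate <- function(humanReads, minReads = 1e6) {
  if (is.null(humanReads) || length(humanReads) == 0L || anyNA(humanReads))
    stop("per-sample human read counts are required")
  setNames(ifelse(humanReads < minReads, "fail", "pass"), names(humanReads))
}

#' Upper-quartile normalization of expression counts
#'
#' Per sample, divides counts by the 75th percentile (linear interpolation
#' between order statistics) of that sample's non-zero counts and
#' multiplies by `scale` (default 1000). Zero counts remain zero, and
#' after normalization the per-sample 75th percentile of non-zero values
#' equals `scale` by construction.
#'
#' @param counts Genes x samples matrix of non-negative expected counts.
#' @param scale Scaling constant (default 1000).
#' @return Matrix of normalized values, same dimnames.
#' @examples
#' m <- matrix(c(0, 10, 20, 40), 4, 1, dimnames = list(letters[1:4], "s1"))
#' upperQuantileNormalize(m)
#' @export
upperQuantileNormalize <- function(counts, scale = 1000) {
  if (any(counts < 0)) stop("counts must be non-negative")
  uq <- apply(counts, 2, function(x) {
    nz <- x[x > 0]
    if (length(nz) == 0L) NA_real_ else quantile(nz, 0.75, names = FALSE)
  })
  if (anyNA(uq))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[is.na(uq)], collapse = ", "))
  sweep(counts, 2, uq / scale, "/")
}

#' Per-gene z-scores across samples
#'
#' For each gene, centers by the mean and scales by the sample standard
#' deviation (n-1 denominator) across all samples. Genes with zero
#' standard deviation get z = 0.
#'
#' @param m Genes x samples matrix (normalized counts or log2(TPM+1)).
#' @return Matrix of z-scores, same dimnames.
#' @export
zscoreByGene <- function(m) {
  if (ncol(m) < 2L) stop("z-scores require >= 2 samples")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  z
}

#' Derive a signed expression signature from labelled samples
#'
#' Ranks expressed genes by the difference of group mean z-scores
#' (EBV-group mean minus non-EBV mean); the top `nUp` genes get sign +1
#' and the bottom `nDown` genes sign -1. Genes whose mean normalized
#' expression is at or below `expressionFloor` are removed before ranking
#' when a normalized matrix is supplied.
#'
#' @param z Genes x samples z-score matrix (from [zscoreByGene()]).
#' @param labels Character vector per sample; `positiveLabel` marks the
#'   EBV group.
#' @param nUp,nDown Signature sizes (defaults 24 and 24).
#' @param normalized Optional genes x samples normalized-count matrix used
#'   for the expressed-gene floor.
#' @param expressionFloor Mean normalized count a gene must exceed to be
#'   considered expressed (default 1).
#' @param positiveLabel Label of the EBV group (default `"EBV"`).
#' @return An [EbvSignature-class].
#' @export
deriveSignature <- function(z, labels, nUp = 24L, nDown = 24L,
                            normalized = NULL, expressionFloor = 1,
                            positiveLabel = "EBV") {
  stopifnot(ncol(z) == length(labels))
  pos <- labels == positiveLabel
  if (!any(pos) || all(pos))
    stop("both groups must be non-empty")
  keep <- rep(TRUE, nrow(z))
  if (!is.null(normalized)) {
    stopifnot(identical(rownames(normalized), rownames(z)))
    keep <- rowMeans(normalized) > expressionFloor
  }
  zk <- z[keep, , drop = FALSE]
  if (nrow(zk) < nUp + nDown)
    stop("fewer expressed genes than nUp + nDown")
  stat <- rowMeans(zk[, pos, drop = FALSE]) -
    rowMeans(zk[, !pos, drop = FALSE])
  ord <- order(stat, decreasing = TRUE)
  up <- rownames(zk)[ord[seq_len(nUp)]]
  down <- rownames(zk)[rev(ord)[seq_len(nDown)]]
  new("EbvSignature", genes = c(up, down),
      signs = c(rep(1L, nUp), rep(-1L, nDown)))
}

#' Score samples with a signed z-score signature
#'
#' The classifier score of a sample is the sum over signature genes of the
#' gene's sign times the sample's z-score for that gene. Samples scoring
#' strictly above `threshold` (default 3.0) are called putative
#' EBV-associated lymphomas.
#'
#' @param z Genes x samples z-score matrix containing every signature gene
#'   (missing genes are an error).
#' @param signature An [EbvSignature-class].
#' @param threshold Decision threshold (default 3.0, strict `>`).
#' @return data.frame: `sample_id`, `score`, `is_lymphoma`.
#' @export
scoreSamples <- function(z, signature, threshold = 3.0) {
  stopifnot(is(signature, "EbvSignature"))
  missing <- setdiff(signature@genes, rownames(z))
  if (length(missing))
    stop("signature gene(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  zs <- z[signature@genes, , drop = FALSE] * signature@signs
  score <- colSums(zs)
  data.frame(sample_id = colnames(z), score = unname(score),
             is_lymphoma = unname(score > threshold),
             stringsAsFactors = FALSE)
}
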