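#' KmerIndex: canonical k-mer partition of graft and host references
#'
#' Partitions the canonical k-mers (lexicographic minimum of a k-mer and its
#' reverse complement) of two reference sequence sets into graft-only,
#' host-only and shared sets, in the style of the Xenome read classifier.
#' The three sets are pairwise disjoint by construction and by validity.
#'
#' @slot k Integer k-mer length.
#' @slot graftOnly,hostOnly,shared Character vectors of canonical k-mers.
#'
#' @seealso [buildKmerIndex()], [classifyRead()]
#' @export
setClass("KmerIndex",
  representation(k = "integer", graftOnly = "character",
                 hostOnly = "character", shared = "character"))

setValidity("KmerIndex", function(object) {
  msg <- character(0)
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msg <- c(msg, "'k' must be a single positive integer")
  if (length(intersect(object@graftOnly, object@hostOnly)) ||
      length(intersect(object@graftOnly, object@shared)) ||
      length(intersect(object@hostOnly, object@shared)))
    msg <- c(msg, "graftOnly, hostOnly and shared must be pairwise disjoint")
  allk <- c(object@graftOnly, object@hostOnly, object@shared)
  if (length(allk) && any(nchar(allk) != object@k))
    msg <- c(msg, "all stored k-mers must have length k")
  if (length(msg)) msg else TRUE
})

#' @describeIn KmerIndex k-mer length of an index
#' @param x A `KmerIndex`.
#' @export
kmerLength <- function(x) {
  stopifnot(is(x, "KmerIndex"))
  x@k
}

setMethod("show", "KmerIndex", function(object) {
  cat("KmerIndex (k = ", object@k, ")\n",
      "  graft-only: ", length(object@graftOnly), " k-mers\n",
      "  host-only:  ", length(object@hostOnly), " k-mers\n",
      "  shared:     ", length(object@shared), " k-mers\n", sep = "")
})

#' GermlineResource: aggregated putative germline variants
#'
#' Union of public-database variants (dbSNP / 1000 Genomes / ExAC with
#' population MAF >= 1%) and a normal-sample compendium admitted under the
#' frequency rule of [buildGermlineResource()]. Entries are keyed at allele
#' resolution (chrom, pos, ref, alt).
#'
#' @slot entries data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sources` (comma-joined tags from dbsnp/kg1000/exac/normal_compendium)
#'   and `maf` (population minor-allele frequency, NA when unknown).
#' @slot nNormals Integer count of normal samples behind the compendium.
#'
#' @seealso [buildGermlineResource()], [flagGermline()]
#' @export
setClass("GermlineResource",
  representation(entries = "data.frame", nNormals = "integer"))

setValidity("GermlineResource", function(object) {
  need <- c("chrom", "pos", "ref", "alt", "sources", "maf")
  if (!all(need %in% names(object@entries)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  e <- object@entries
  if (anyDuplicated(variantKey(e$chrom, e$pos, e$ref, e$alt)))
    return("duplicate (chrom,pos,ref,alt) entries")
  exacOnly <- grepl("exac", e$sources) & !grepl("dbsnp|kg1000|normal", e$sources)
  if (any(exacOnly & (is.na(e$maf) | e$maf < 0.01)))
    return("ExAC-derived entries must carry MAF >= 0.01")
  TRUE
})

setMethod("show", "GermlineResource", function(object) {
  cat("GermlineResource with ", nrow(object@entries), " variants (",
      object@nNormals, " normal samples in compendium)\n", sep = "")
})

#' @describeIn GermlineResource number of variant entries
#' @param x A `GermlineResource`.
#' @export
resourceSize <- function(x) {
  stopifnot(is(x, "GermlineResource"))
  nrow(x@entries)
}

#' ClinicalKB: clinically relevant variant knowledgebase
#'
#' Curated clinically relevant variants matched either by
#' (gene, protein_change) or by genomic allele (chrom, pos, ref, alt).
#' Every entry carries at least one relevance tag out of
#' gain_or_loss_of_function, treatment_approach,
#' drug_sensitivity_resistance.
#'
#' @slot entries data.frame with columns `gene`, `protein_change`, `chrom`,
#'   `pos`, `ref`, `alt`, `tags` (comma-joined relevance tags). Genomic
#'   columns may be NA when only protein-level matching is curated, and
#'   vice versa.
#'
#' @seealso [rescueClinical()]
#' @export
setClass("ClinicalKB", representation(entries = "data.frame"))

setValidity("ClinicalKB", function(object) {
  need <- c("gene", "protein_change", "chrom", "pos", "ref", "alt", "tags")
  if (!all(need %in% names(object@entries)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  tags <- object@entries$tags
  ok <- c("gain_or_loss_of_function", "treatment_approach",
          "drug_sensitivity_resistance")
  split_tags <- strsplit(as.character(tags), ",")
  if (any(vapply(split_tags, function(t) length(t) == 0L || !all(t %in% ok),
                 logical(1))))
    return("every entry needs >= 1 recognised relevance tag")
  TRUE
})

setMethod("show", "ClinicalKB", function(object) {
  cat("ClinicalKB with", nrow(object@entries), "curated variants\n")
})

#' RecurrenceTable: cohort-wide variant position recurrence
#'
#' Per genomic position (chrom, pos), the fraction of cohort samples that
#' carry at least one quality-passing, non-germline variant at that
#' position. Used to flag systematic false positives recurring at rates no
#' plausible somatic process reaches.
#'
#' @slot table data.frame with columns `chrom`, `pos`, `n_samples`,
#'   `fraction`.
#' @slot cohortSize Integer number of samples in the cohort.
#'
#' @seealso [computeRecurrence()], [flagRecurrentFp()]
#' @export
setClass("RecurrenceTable",
  representation(table = "data.frame", cohortSize = "integer"))

setValidity("RecurrenceTable", function(object) {
  need <- c("chrom", "pos", "n_samples", "fraction")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (length(object@cohortSize) != 1L || object@cohortSize < 1L)
    return("cohortSize must be a single positive integer")
  fr <- object@table$fraction
  if (length(fr) && (any(fr < 0) || any(fr > 1)))
    return("fractions must lie in [0, 1]")
  if (nrow(object@table) &&
      !isTRUE(all.equal(fr, object@table$n_samples / object@cohortSize)))
    return("fraction must equal n_samples / cohortSize")
  TRUE
})

setMethod("show", "RecurrenceTable", function(object) {
  cat("RecurrenceTable over", object@cohortSize, "samples;",
      nrow(object@table), "positions,",
      sum(object@table$fraction >= 0.25), "at fraction >= 0.25\n")
})

#' EbvSignature: signed gene signature for the EBV-lymphoma classifier
#'
#' A set of signature genes each carrying a direction of regulation
#' (+1 up in EBV-associated lymphomas, -1 down). The published classifier
#' uses 24 up- plus 24 down-regulated genes.
#'
#' @slot genes Character vector of gene identifiers (unique).
#' @slot signs Integer vector of +1/-1, parallel to `genes`.
#'
#' @seealso [deriveSignature()], [scoreSamples()]
#' @export
setClass("EbvSignature",
  representation(genes = "character", signs = "integer"))

setValidity("EbvSignature", function(object) {
  if (length(object@genes) != length(object@signs))
    return("genes and signs must be parallel")
  if (anyDuplicated(object@genes)) return("duplicate signature genes")
  if (length(object@signs) && !all(object@signs %in% c(-1L, 1L)))
    return("signs must be +1 or -1")
  TRUE
})

setMethod("show", "EbvSignature", function(object) {
  cat("EbvSignature:", sum(object@signs == 1L), "up,",
      sum(object@signs == -1L), "down genes\n")
})

#' @describeIn EbvSignature genes of a signature, named by sign
#' @param x An `EbvSignature`.
#' @export
signatureGenes <- function(x) {
  stopifnot(is(x, "EbvSignature"))
  setNames(x@signs, x@genes)
}

#' BenchmarkResult: confusion counts and accuracy metrics
#'
#' Benchmark of a predicted variant set against a truth set over an
#' explicit universe of assessable loci, at (chrom, pos, alt) resolution.
#' `f1` is 2*(recall*precision)/(recall+precision); precision and recall
#' are 0 when their denominators are 0. `afPearson` is the Pearson
#' correlation of predicted vs true allele fractions over true positives
#' (NA with fewer than 2 true positives).
#'
#' @slot tp,fp,tn,fn Integer confusion counts.
#' @slot precision,recall,f1,afPearson Numeric metrics.
#'
#' @seealso [benchmarkCalls()]
#' @export
setClass("BenchmarkResult",
  representation(tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer", precision = "numeric", recall = "numeric",
                 f1 = "numeric", afPearson = "numeric"))

setValidity("BenchmarkResult", function(object) {
  cnt <- c(object@tp, object@fp, object@tn, object@fn)
  if (length(cnt) != 4L || any(is.na(cnt)) || any(cnt < 0L))
    return("tp/fp/tn/fn must be non-negative integers")
  TRUE
})

setMethod("show", "BenchmarkResult", function(object) {
  cat(sprintf(paste0("BenchmarkResult: TP=%d FP=%d TN=%d FN=%d\n",
                     "  precision=%.4f recall=%.4f F1=%.4f afPearson=%s\n"),
              object@tp, object@fp, object@tn, object@fn,
              object@precision, object@recall, object@f1,
              ifelse(is.na(object@afPearson), "NA",
                     sprintf("%.4f", object@afPearson))))
})

#' @describeIn BenchmarkResult metrics as a named list
#' @param x A `BenchmarkResult`.
#' @export
benchmarkMetrics <- function(x) {
  stopifnot(is(x, "BenchmarkResult"))
  list(tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn,
       precision = x@precision, recall = x@recall, f1 = x@f1,
       afPearson = x@afPearson)
}
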