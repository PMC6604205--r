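#' Configuration for the tumor-only somatic filtering pipeline
#'
#' All thresholds of the filter-and-rescue engine, defaulting to the
#' published values for targeted-panel sequencing: GATK-style hard filters
#' (SNVs: QD < 2.0, FS > 60.0, MQ < 40.0, MQRankSum < -12.5,
#' ReadPosRankSum < -8.0; indels: QD < 2.0, FS > 200.0,
#' ReadPosRankSum < -20.0), read depth >= 140, alternate allele fraction
#' >= 5%, germline allele-fraction windows 40-60% or > 90%, and a cohort
#' recurrence cutoff of 25%.
#'
#' @param minDP Minimum read depth (inclusive).
#' @param minAF Minimum alternate allele fraction (inclusive).
#' @param afWindow Closed germline heterozygous allele-fraction window.
#' @param afHigh Germline homozygous cutoff; allele fractions strictly
#'   above it are germline-compatible.
#' @param recurrenceThreshold Cohort fraction at or above which a
#'   non-germline position is a putative systematic false positive.
#' @param fpMinCohort Minimum cohort size for the recurrence filter. Below
#'   `ceiling(1/recurrenceThreshold)` samples every singleton variant
#'   would exceed the recurrence cutoff, so the filter is skipped for
#'   cohorts smaller than this (default 4).
#' @param snvHard,indelHard Named lists of hard-filter cutoffs.
#' @param rescueQualityFailed Logical; allow clinical rescue of
#'   quality-failed variants (default `FALSE`: rescue is restricted to
#'   quality-passing calls).
#' @return A list of class `SomaticFilterConfig`.
#' @export
somaticFilterConfig <- function(minDP = 140, minAF = 0.05,
                                afWindow = c(0.40, 0.60), afHigh = 0.90,
                                recurrenceThreshold = 0.25,
                                fpMinCohort = 4L,
                                snvHard = list(QD = 2.0, FS = 60.0,
                                               MQ = 40.0, MQRankSum = -12.5,
                                               ReadPosRankSum = -8.0),
                                indelHard = list(QD = 2.0, FS = 200.0,
                                                 ReadPosRankSum = -20.0),
                                rescueQualityFailed = FALSE) {
  structure(list(minDP = minDP, minAF = minAF, afWindow = afWindow,
                 afHigh = afHigh,
                 recurrenceThreshold = recurrenceThreshold,
                 fpMinCohort = as.integer(fpMinCohort),
                 snvHard = snvHard, indelHard = indelHard,
                 rescueQualityFailed = rescueQualityFailed),
            class = "SomaticFilterConfig")
}

#' Hard-filter, depth and allele-fraction quality status
#'
#' Applies, in order: GATK-style hard filters (any failing condition gives
#' `fail_hard`; missing annotations never fail, matching GATK
#' filter-expression semantics for e.g. MQRankSum at homozygous sites),
#' the depth rule (`fail_depth` when DP < 140) and the allele-fraction
#' rule (`fail_af` when ALT_AF < 5%); otherwise `pass`. SNVs and indels
#' use their respective hard-filter sets.
#'
#' @param variants data.frame of variant calls with at least `vtype`
#'   (`"snv"`/`"indel"`), `DP`, `ALT_AF` and any of `QD`, `FS`, `MQ`,
#'   `MQRankSum`, `ReadPosRankSum`.
#' @param config A [somaticFilterConfig()].
#' @return Character vector in pass/fail_hard/fail_depth/fail_af.
#' @examples
#' v <- data.frame(vtype = "snv", DP = 500, ALT_AF = 0.05, QD = 10,
#'                 FS = 1, MQ = 60, MQRankSum = 0, ReadPosRankSum = 0)
#' applyQualityFilters(v)  # "pass": both boundaries are inclusive
#' @export
applyQualityFilters <- function(variants, config = somaticFilterConfig()) {
  if (!all(variants$vtype %in% c("snv", "indel")))
    stop("unknown vtype: ", paste(setdiff(unique(variants$vtype),
                                          c("snv", "indel")), collapse = ","))
  n <- nrow(variants)
  getCol <- function(nm) {
    if (nm %in% names(variants)) variants[[nm]] else rep(NA_real_, n)
  }
  lt <- function(x, cut) !is.na(x) & x < cut   # NA never fails
  gt <- function(x, cut) !is.na(x) & x > cut
  isSnv <- variants$vtype == "snv"
  sh <- config$snvHard; ih <- config$indelHard
  hardSnv <- lt(getCol("QD"), sh$QD) | gt(getCol("FS"), sh$FS) |
    lt(getCol("MQ"), sh$MQ) | lt(getCol("MQRankSum"), sh$MQRankSum) |
    lt(getCol("ReadPosRankSum"), sh$ReadPosRankSum)
  hardIndel <- lt(getCol("QD"), ih$QD) | gt(getCol("FS"), ih$FS) |
    lt(getCol("ReadPosRankSum"), ih$ReadPosRankSum)
  hard <- ifelse(isSnv, hardSnv, hardIndel)
  status <- rep("pass", n)
  status[!hard & variants$ALT_AF < config$minAF] <- "fail_af"
  status[!hard & variants$DP < config$minDP] <- "fail_depth"
  status[hard] <- "fail_hard"
  status
}

#' Build an aggregated germline resource
#'
#' Union of public-database germline variants (dbSNP, 1000 Genomes, and
#' ExAC restricted to population MAF >= 1%) with a normal-sample
#' compendium. A compendium variant is admitted when it is seen in at
#' least `minNormals` (default 2) of the normal samples, or in at least
#' `minNormalsAlt` (default 1) normal sample and at least `minPdx`
#' (default 2) samples of the PDX cohort — the published absolute counts
#' for a 20-normal compendium. Set `proportional = TRUE` to scale the
#' count thresholds to other compendium sizes relative to 20 normals.
#'
#' @param publicSources data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `source` (one of dbsnp/kg1000/exac) and `maf` (NA when unknown).
#' @param normalCalls data.frame of per-normal-sample calls (`sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`); NULL for no compendium.
#' @param pdxCalls data.frame of per-PDX-sample calls, same columns.
#' @param nNormals Number of normal samples behind `normalCalls`.
#' @param minNormals,minNormalsAlt,minPdx Admission-count thresholds.
#' @param proportional Scale count thresholds by `nNormals / 20`.
#' @return A [GermlineResource-class].
#' @export
buildGermlineResource <- function(publicSources = NULL, normalCalls = NULL,
                                  pdxCalls = NULL, nNormals = 20L,
                                  minNormals = 2L, minNormalsAlt = 1L,
                                  minPdx = 2L, proportional = FALSE) {
  entries <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        sources = character(0), maf = numeric(0),
                        stringsAsFactors = FALSE)
  addEntries <- function(entries, df, source) {
    if (is.null(df) || nrow(df) == 0L) return(entries)
    key <- variantKey(df$chrom, df$pos, df$ref, df$alt)
    ekey <- variantKey(entries$chrom, entries$pos, entries$ref, entries$alt)
    hit <- match(key, ekey)
    newIdx <- which(is.na(hit) & !duplicated(key))
    if (length(newIdx)) {
      entries <- rbind(entries, data.frame(
        chrom = df$chrom[newIdx], pos = df$pos[newIdx],
        ref = df$ref[newIdx], alt = df$alt[newIdx],
        sources = source, maf = if ("maf" %in% names(df))
          df$maf[newIdx] else NA_real_,
        stringsAsFactors = FALSE))
    }
    old <- which(!is.na(hit))
    for (i in old) {
      j <- hit[i]
      if (!grepl(source, entries$sources[j]))
        entries$sources[j] <- paste(entries$sources[j], source, sep = ",")
    }
    entries
  }
  if (!is.null(publicSources) && nrow(publicSources)) {
    for (src in unique(publicSources$source)) {
      df <- publicSources[publicSources$source == src, , drop = FALSE]
      if (src == "exac") df <- df[!is.na(df$maf) & df$maf >= 0.01, ,
                                  drop = FALSE]
      entries <- addEntries(entries, df, src)
    }
  }
  if (!is.null(normalCalls) && nrow(normalCalls)) {
    if (nNormals < 1L)
      stop("a normal-sample compendium requires nNormals >= 1")
    scl <- if (proportional) nNormals / 20 else 1
    thrN <- ceiling(minNormals * scl)
    thrNAlt <- ceiling(minNormalsAlt * scl)
    thrP <- minPdx
    nkey <- variantKey(normalCalls$chrom, normalCalls$pos, normalCalls$ref,
                       normalCalls$alt)
    nCount <- tapply(normalCalls$sample_id, nkey,
                     function(s) length(unique(s)))
    pCount <- if (!is.null(pdxCalls) && nrow(pdxCalls)) {
      pkey <- variantKey(pdxCalls$chrom, pdxCalls$pos, pdxCalls$ref,
                         pdxCalls$alt)
      tapply(pdxCalls$sample_id, pkey, function(s) length(unique(s)))
    } else integer(0)
    pHits <- pCount[names(nCount)]
    pHits[is.na(pHits)] <- 0L
    admit <- nCount >= thrN | (nCount >= thrNAlt & pHits >= thrP)
    if (any(admit)) {
      adm <- names(nCount)[admit]
      first <- normalCalls[match(adm, nkey), , drop = FALSE]
      entries <- addEntries(entries, first, "normal_compendium")
    }
  }
  new("GermlineResource", entries = entries, nNormals = as.integer(nNormals))
}

#' Flag putative germline variants
#'
#' A call is flagged germline when its allele (chrom, pos, ref, alt) is in
#' the aggregated germline resource AND its observed allele fraction lies
#' in the heterozygous window (closed, default 40-60%) or strictly above
#' the homozygous cutoff (default 90%). Allele fractions outside both
#' windows are kept as candidate somatic even when the allele is a known
#' polymorphism, since copy-number alterations unbalance germline allele
#' fractions.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`, `ALT_AF`.
#' @param resource A [GermlineResource-class].
#' @param config A [somaticFilterConfig()] (uses `afWindow`, `afHigh`).
#' @return Logical vector.
#' @export
flagGermline <- function(variants, resource,
                         config = somaticFilterConfig()) {
  stopifnot(is(resource, "GermlineResource"))
  e <- resource@entries
  inRes <- variantKey(variants$chrom, variants$pos, variants$ref,
                      variants$alt) %in%
    variantKey(e$chrom, e$pos, e$ref, e$alt)
  af <- variants$ALT_AF
  inWindow <- (af >= config$afWindow[1] & af <= config$afWindow[2]) |
    af > config$afHigh
  inRes & inWindow
}

#' Cohort-wide position recurrence of non-germline variants
#'
#' For every position carrying any cohort variant, the fraction of cohort
#' samples with at least one non-germline-flagged variant there.
#' Recurrence is counted at (chrom, pos) resolution — systematic errors
#' recur at mutated base positions, not specific alleles — and
#' germline-flagged occurrences are excluded from the numerator, since the
#' false-positive rule applies only to variants not in the germline
#' resource.
#'
#' @param cohortCalls data.frame with `sample_id`, `chrom`, `pos` and a
#'   logical `germline_flag` column.
#' @param cohortSize Number of samples in the cohort (defaults to the
#'   distinct `sample_id` count).
#' @return A [RecurrenceTable-class] covering every observed position.
#' @export
computeRecurrence <- function(cohortCalls, cohortSize = NULL) {
  if (is.null(cohortCalls) || nrow(cohortCalls) == 0L)
    stop("empty cohort")
  if (!"germline_flag" %in% names(cohortCalls))
    stop("'cohortCalls' must carry a germline_flag column")
  if (is.null(cohortSize))
    cohortSize <- length(unique(cohortCalls$sample_id))
  pk <- positionKey(cohortCalls$chrom, cohortCalls$pos)
  nonGerm <- !cohortCalls$germline_flag
  nSamples <- tapply(ifelse(nonGerm, cohortCalls$sample_id, NA_character_),
                     pk, function(s) length(unique(s[!is.na(s)])))
  first <- !duplicated(pk)
  tab <- data.frame(chrom = cohortCalls$chrom[first],
                    pos = cohortCalls$pos[first],
                    stringsAsFactors = FALSE)
  tab$n_samples <- as.integer(nSamples[positionKey(tab$chrom, tab$pos)])
  tab$fraction <- tab$n_samples / cohortSize
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  new("RecurrenceTable", table = tab, cohortSize = as.integer(cohortSize))
}

#' Flag recurrent systematic false positives
#'
#' A variant is flagged when it is not germline-flagged and its position
#' recurs in at least `recurrenceThreshold` (default 25%) of cohort
#' samples — far above the maximum recurrence somatic mutation reaches in
#' large tumor compendia (about 6%).
#'
#' @param variants data.frame with `chrom`, `pos` and logical
#'   `germline_flag`.
#' @param recurrence A [RecurrenceTable-class] computed on the same
#'   cohort; every variant position must be present.
#' @param config A [somaticFilterConfig()].
#' @return Logical vector.
#' @export
flagRecurrentFp <- function(variants, recurrence,
                            config = somaticFilterConfig()) {
  stopifnot(is(recurrence, "RecurrenceTable"))
  tab <- recurrence@table
  idx <- match(positionKey(variants$chrom, variants$pos),
               positionKey(tab$chrom, tab$pos))
  if (anyNA(idx))
    stop("variant position(s) absent from the recurrence table: ",
         paste(head(positionKey(variants$chrom, variants$pos)[is.na(idx)]),
               collapse = ", "))
  !variants$germline_flag &
    tab$fraction[idx] >= config$recurrenceThreshold
}

## KB hit: allele match on (chrom,pos,ref,alt) where curated, else
## (gene, protein_change) match where the call carries a protein change
kbHit <- function(variants, kb) {
  if (is.null(kb)) return(rep(FALSE, nrow(variants)))
  stopifnot(is(kb, "ClinicalKB"))
  e <- kb@entries
  hit <- rep(FALSE, nrow(variants))
  gen <- !is.na(e$chrom) & !is.na(e$pos)
  if (any(gen))
    hit <- hit | variantKey(variants$chrom, variants$pos, variants$ref,
                            variants$alt) %in%
      variantKey(e$chrom[gen], e$pos[gen], e$ref[gen], e$alt[gen])
  prot <- !is.na(e$gene) & !is.na(e$protein_change)
  if (any(prot) && "protein_change" %in% names(variants)) {
    vp <- !is.na(variants$protein_change)
    hit[vp] <- hit[vp] |
      paste(variants$gene[vp], variants$protein_change[vp]) %in%
      paste(e$gene[prot], e$protein_change[prot])
  }
  hit
}

#' Run the full tumor-only somatic filter-and-rescue pipeline
#'
#' Applies, in order: hard-filter/depth/allele-fraction quality filtering,
#' germline flagging against the aggregated resource, cohort-recurrence
#' false-positive flagging, and clinical-knowledgebase rescue. Every input
#' variant receives exactly one final status:
#'
#' * `somatic_pass` — quality-passing, not germline, not recurrent
#'   (Pindel calls additionally require a knowledgebase hit to pass, since
#'   unfiltered Pindel output is false-positive-rich);
#' * `filtered_germline` / `filtered_fp` — removed by the germline or
#'   recurrence filter (Pindel calls without a knowledgebase hit are
#'   assigned `filtered_fp` when not germline-flagged);
#' * `filtered_quality` — failed a quality filter (never rescued unless
#'   `rescueQualityFailed`);
#' * `rescued_clinical` — GATK calls initially filtered as germline or
#'   recurrent, and flagged Pindel calls, reinstated by a clinical
#'   knowledgebase hit.
#'
#' Multi-allelic records (comma-separated `alt`) are decomposed to one
#' call per alternate allele before filtering. The recurrence filter is
#' computed over quality-passing calls of the whole cohort and skipped for
#' cohorts smaller than `fpMinCohort` samples.
#'
#' @param calls data.frame of cohort variant calls (columns as produced by
#'   [simulateVariantCohort()]; the cohort must include the samples to be
#'   reported).
#' @param resource A [GermlineResource-class].
#' @param kb A [ClinicalKB-class] or NULL.
#' @param config A [somaticFilterConfig()].
#' @return List with `trace` (the input calls plus `quality_status`,
#'   `germline_flag`, `recurrent_fp_flag`, `rescued`, `final`),
#'   `recurrence` (the [RecurrenceTable-class], or NULL when skipped) and
#'   `summary` (final-status counts per sample).
#' @export
runSomaticPipeline <- function(calls, resource, kb = NULL,
                               config = somaticFilterConfig()) {
  need <- c("sample_id", "chrom", "pos", "ref", "alt", "vtype", "caller",
            "DP", "ALT_AF")
  if (!all(need %in% names(calls)))
    stop("'calls' must have columns: ", paste(need, collapse = ", "))
  ## decompose multi-allelic sites
  multi <- grepl(",", calls$alt, fixed = TRUE)
  if (any(multi)) {
    alts <- strsplit(calls$alt, ",", fixed = TRUE)
    calls <- calls[rep(seq_len(nrow(calls)), lengths(alts)), , drop = FALSE]
    calls$alt <- unlist(alts)
    rownames(calls) <- NULL
  }
  trace <- calls
  trace$quality_status <- applyQualityFilters(calls, config)
  qpass <- trace$quality_status == "pass"
  trace$germline_flag <- flagGermline(calls, resource, config)

  cohortSize <- length(unique(calls$sample_id))
  recurrence <- NULL
  trace$recurrent_fp_flag <- FALSE
  if (cohortSize >= config$fpMinCohort && any(qpass)) {
    recurrence <- computeRecurrence(trace[qpass, , drop = FALSE], cohortSize)
    trace$recurrent_fp_flag[qpass] <-
      flagRecurrentFp(trace[qpass, , drop = FALSE], recurrence, config)
  }

  hit <- kbHit(calls, kb)
  rescueEligible <- if (config$rescueQualityFailed) rep(TRUE, nrow(trace))
                    else qpass
  isPindel <- calls$caller == "pindel"
  flagged <- trace$germline_flag | trace$recurrent_fp_flag

  final <- rep(NA_character_, nrow(trace))
  final[!qpass] <- "filtered_quality"
  if (config$rescueQualityFailed)
    final[!qpass & hit & (flagged | isPindel)] <- "rescued_clinical"
  ## GATK path
  g <- qpass & !isPindel
  final[g & trace$germline_flag] <- "filtered_germline"
  final[g & !trace$germline_flag & trace$recurrent_fp_flag] <- "filtered_fp"
  final[g & flagged & hit & rescueEligible] <- "rescued_clinical"
  final[g & !flagged] <- "somatic_pass"
  ## Pindel path: keep only knowledgebase-curated calls
  p <- qpass & isPindel
  final[p & hit & !flagged] <- "somatic_pass"
  final[p & hit & flagged] <- "rescued_clinical"
  final[p & !hit & trace$germline_flag] <- "filtered_germline"
  final[p & !hit & !trace$germline_flag] <- "filtered_fp"

  trace$rescued <- final == "rescued_clinical"
  trace$final <- final
  summary <- as.data.frame(table(sample_id = trace$sample_id,
                                 final = trace$final))
  names(summary)[3] <- "n"
  list(trace = trace, recurrence = recurrence, summary = summary)
}
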