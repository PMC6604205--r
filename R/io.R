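## File I/O for the package's external formats: FASTA/FASTQ (Sanger
## qualities) via Biostrings, VCF 4.2 variant tables, and headered TSVs.

#' Write a reference sequence set as FASTA
#'
#' @param seqs A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA reference
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
readFasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write read pairs as a pair of FASTQ files
#'
#' @param pairs data.frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`
#'   (Sanger/Phred+33 qualities).
#' @param path1,path2 Output FASTQ paths for mates 1 and 2.
#' @return `c(path1, path2)`, invisibly.
#' @export
writeFastqPairs <- function(pairs, path1, path2) {
  writeOne <- function(seqs, quals, ids, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
    names(x) <- ids
    Biostrings::writeQualityScaledXStringSet(x, path)
  }
  writeOne(pairs$seq1, pairs$qual1, pairs$id, path1)
  writeOne(pairs$seq2, pairs$qual2, pairs$id, path2)
  invisible(c(path1, path2))
}

#' Read paired FASTQ files into the package's pair table
#'
#' @param path1,path2 FASTQ paths for mates 1 and 2 (record-for-record
#'   aligned).
#' @return data.frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
readFastqPairs <- function(path1, path2) {
  ## Biostrings warns about dropping its own metadata columns here
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path1))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path2))
  if (length(r1) != length(r2))
    stop("mate FASTQ files have unequal record counts")
  data.frame(id = names(r1),
             seq1 = as.character(r1),
             qual1 = as.character(Biostrings::quality(r1)),
             seq2 = as.character(r2),
             qual2 = as.character(Biostrings::quality(r2)),
             stringsAsFactors = FALSE, row.names = NULL)
}

## FILTER column encoding of final pipeline status
.finalToFilter <- function(final, quality_status) {
  out <- rep(".", length(final))
  out[final %in% c("somatic_pass", "rescued_clinical")] <- "PASS"
  out[final == "filtered_germline"] <- "germline"
  out[final == "filtered_fp"] <- "recurrent_fp"
  fq <- final == "filtered_quality"
  out[fq & quality_status == "fail_hard"] <- "hard_filter"
  out[fq & quality_status == "fail_depth"] <- "low_depth"
  out[fq & quality_status == "fail_af"] <- "low_af"
  out
}

#' Write one sample's filtered variants as VCF 4.2
#'
#' Emits a sites-only VCF with the pipeline's FILTER conventions (`PASS`,
#' `germline`, `recurrent_fp`, `hard_filter`, `low_depth`, `low_af`) and
#' INFO tags `DP`, `AF`, `TRACE` (semicolon-free audit flags, comma
#' joined) and `RESCUED=1` for clinically rescued calls.
#'
#' @param trace One sample's rows of a [runSomaticPipeline()] trace.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSomaticVcf <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pdxsoma",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction\">",
    "##INFO=<ID=TRACE,Number=1,Type=String,Description=\"Audit flags: quality_status,germline_flag,recurrent_fp_flag\">",
    "##INFO=<ID=RESCUED,Number=0,Type=Flag,Description=\"Reinstated by clinical knowledgebase rescue\">",
    "##FILTER=<ID=germline,Description=\"Putative germline variant\">",
    "##FILTER=<ID=recurrent_fp,Description=\"Recurrent systematic false positive\">",
    "##FILTER=<ID=hard_filter,Description=\"Failed GATK-style hard filters\">",
    "##FILTER=<ID=low_depth,Description=\"Read depth below threshold\">",
    "##FILTER=<ID=low_af,Description=\"Alternate allele fraction below threshold\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(header, con)
  if (nrow(trace)) {
    ord <- order(trace$chrom, trace$pos)
    trace <- trace[ord, , drop = FALSE]
    info <- sprintf("DP=%d;AF=%.6g;TRACE=%s,%s,%s%s",
                    as.integer(trace$DP), trace$ALT_AF,
                    trace$quality_status,
                    ifelse(trace$germline_flag, "germline", "ok"),
                    ifelse(trace$recurrent_fp_flag, "recurrent", "ok"),
                    ifelse(trace$rescued, ";RESCUED", ""))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                       trace$chrom, trace$pos, trace$ref, trace$alt,
                       .finalToFilter(trace$final, trace$quality_status),
                       info), con)
  }
  invisible(path)
}

#' Read a variant table from a VCF written by this package
#'
#' Parses a sites-only VCF 4.2 file into the package's call-table columns.
#' Malformed records raise an error naming the offending line.
#'
#' @param path VCF file.
#' @param sample_id Sample identifier to attach.
#' @return data.frame with `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `filter`, `DP`, `ALT_AF`, `rescued`.
#' @export
readSomaticVcf <- function(path, sample_id = NA_character_) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  if (length(body) == 0L)
    return(data.frame(sample_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), filter = character(0),
                      DP = integer(0), ALT_AF = numeric(0),
                      rescued = logical(0)))
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 8L)
  if (length(bad))
    stop("malformed VCF record at line ", body[bad[1]], " of ", path)
  getInfo <- function(info, tag) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", tag, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
           character(1))
  }
  info <- vapply(fields, `[`, character(1), 8L)
  data.frame(
    sample_id = sample_id,
    chrom = vapply(fields, `[`, character(1), 1L),
    pos = as.integer(vapply(fields, `[`, character(1), 2L)),
    ref = vapply(fields, `[`, character(1), 4L),
    alt = vapply(fields, `[`, character(1), 5L),
    filter = vapply(fields, `[`, character(1), 7L),
    DP = as.integer(getInfo(info, "DP")),
    ALT_AF = as.numeric(getInfo(info, "AF")),
    rescued = grepl("(^|;)RESCUED($|;)", info),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Read/write headered TSV tables
#'
#' Thin wrappers fixing the conventions used by the package's tabular
#' formats (tab separation, header row, no quoting, no row names).
#'
#' @param df data.frame to write.
#' @param path File path.
#' @return `readPdxTsv` returns a data.frame; `writePdxTsv` returns
#'   `path` invisibly.
#' @export
writePdxTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePdxTsv
#' @export
readPdxTsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
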