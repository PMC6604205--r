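test_that("quality filters apply hard, depth and allele-fraction rules in order", {
  expect_equal(applyQualityFilters(makeCall(QD = 1.5)), "fail_hard")
  expect_equal(applyQualityFilters(makeCall(FS = 61)), "fail_hard")
  expect_equal(applyQualityFilters(makeCall(MQ = 39)), "fail_hard")
  expect_equal(applyQualityFilters(makeCall(MQRankSum = -13)), "fail_hard")
  expect_equal(applyQualityFilters(makeCall(ReadPosRankSum = -9)), "fail_hard")
  expect_equal(applyQualityFilters(makeCall(DP = 139)), "fail_depth")
  expect_equal(applyQualityFilters(makeCall(DP = 140)), "pass")
  expect_equal(applyQualityFilters(makeCall(DP = 500, ALT_AF = 0.05)), "pass")
  expect_equal(applyQualityFilters(makeCall(ALT_AF = 0.049)), "fail_af")
  ## indels use their own hard-filter set
  expect_equal(applyQualityFilters(
    makeCall(vtype = "indel", ReadPosRankSum = -25)), "fail_hard")
  expect_equal(applyQualityFilters(
    makeCall(vtype = "indel", FS = 100, ReadPosRankSum = -15)), "pass")
  ## missing annotations never fail; hard filter precedes depth
  expect_equal(applyQualityFilters(
    makeCall(QD = NA, MQRankSum = NA, ReadPosRankSum = NA)), "pass")
  expect_equal(applyQualityFilters(makeCall(QD = 1, DP = 10)), "fail_hard")
  expect_error(applyQualityFilters(makeCall(vtype = "mnv")), "vtype")
})

test_that("germline resource admits compendium variants by the frequency rule", {
  normals <- do.call(rbind, c(
    lapply(sprintf("N%02d", 1:2),
           function(s) data.frame(sample_id = s, chrom = "chr1", pos = 100L,
                                  ref = "A", alt = "T")),
    list(data.frame(sample_id = "N01", chrom = "chr1", pos = 200L,
                    ref = "C", alt = "G"),
         data.frame(sample_id = "N01", chrom = "chr1", pos = 300L,
                    ref = "G", alt = "A"))))
  pdx <- rbind(
    data.frame(sample_id = c("P1", "P2"), chrom = "chr1", pos = 200L,
               ref = "C", alt = "G"),
    data.frame(sample_id = "P1", chrom = "chr1", pos = 300L,
               ref = "G", alt = "A"))
  res <- buildGermlineResource(normalCalls = normals, pdxCalls = pdx,
                               nNormals = 20)
  keys <- with(res@entries, paste(chrom, pos))
  expect_true("chr1 100" %in% keys)   # 2/20 normals
  expect_true("chr1 200" %in% keys)   # 1/20 normals + 2/20 PDX
  expect_false("chr1 300" %in% keys)  # 1 normal + 1 PDX: not admitted
  expect_error(buildGermlineResource(normalCalls = normals, nNormals = 0),
               "nNormals")
})

test_that("public sources union respects the ExAC MAF floor", {
  pub <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                    ref = "A", alt = "T",
                    source = c("dbsnp", "exac", "exac"),
                    maf = c(NA, 0.005, 0.05))
  res <- buildGermlineResource(publicSources = pub)
  expect_equal(sort(res@entries$pos), c(10L, 30L))
  ## same allele in two sources collapses to one entry with joined tags
  pub2 <- rbind(pub, data.frame(chrom = "chr1", pos = 10L, ref = "A",
                                alt = "T", source = "kg1000", maf = NA))
  res2 <- buildGermlineResource(publicSources = pub2)
  expect_equal(resourceSize(res2), 2L)
  expect_match(res2@entries$sources[res2@entries$pos == 10L], "dbsnp")
  expect_match(res2@entries$sources[res2@entries$pos == 10L], "kg1000")
})

test_that("germline flagging requires resource membership and an AF window", {
  res <- makeResource("chr1", 100L, "A", "T")
  flag <- function(af, pos = 100L, ref = "A", alt = "T")
    flagGermline(makeCall(pos = pos, ref = ref, alt = alt, ALT_AF = af), res)
  expect_true(flag(0.50))
  expect_true(flag(0.40))   # window closed at both ends
  expect_true(flag(0.60))
  expect_false(flag(0.75))  # outside both windows
  expect_false(flag(0.90))  # ">90%" is strict
  expect_true(flag(0.95))
  expect_false(flagGermline(makeCall(pos = 999L, ALT_AF = 0.5), res))
  expect_false(flag(0.5, alt = "G"))  # allele-resolution matching
})

test_that("recurrence counts non-germline samples per position", {
  calls <- rbind(
    do.call(rbind, lapply(sprintf("S%02d", 1:5), function(s)
      makeCall(sample_id = s, pos = 100L, germline_flag = FALSE))),
    do.call(rbind, lapply(sprintf("S%02d", 1:3), function(s)
      makeCall(sample_id = s, pos = 200L, germline_flag = TRUE))),
    makeCall(sample_id = "S01", pos = 300L, germline_flag = FALSE))
  rec <- computeRecurrence(calls, cohortSize = 20)
  tab <- rec@table
  expect_equal(tab$fraction[tab$pos == 100L], 0.25)  # 5/20
  expect_equal(tab$fraction[tab$pos == 200L], 0)     # germline excluded
  expect_equal(tab$fraction[tab$pos == 300L], 0.05)  # 1/20
  expect_error(computeRecurrence(calls[0, , drop = FALSE]), "empty")

  v100 <- makeCall(pos = 100L, germline_flag = FALSE)
  expect_true(flagRecurrentFp(v100, rec))            # 0.25 inclusive
  v300 <- makeCall(pos = 300L, germline_flag = FALSE)
  expect_false(flagRecurrentFp(v300, rec))
  vg <- makeCall(pos = 100L, germline_flag = TRUE)
  expect_false(flagRecurrentFp(vg, rec))             # germline path disjoint
  vAbsent <- makeCall(pos = 999L, germline_flag = FALSE)
  expect_error(flagRecurrentFp(vAbsent, rec), "absent")
})

test_that("clinical rescue reinstates filtered GATK calls and gates Pindel", {
  res <- makeResource("chr1", 100L, "A", "T")
  kb <- makeKb(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
               gene = "BRAF", tags = "gain_or_loss_of_function")
  ## GATK call in dbSNP at het AF: germline-flagged, then rescued
  calls <- makeCall(pos = 100L, ALT_AF = 0.48)
  out <- runSomaticPipeline(calls, res, kb)
  expect_true(out$trace$germline_flag)
  expect_equal(out$trace$final, "rescued_clinical")
  ## without the KB hit it stays filtered
  out2 <- runSomaticPipeline(calls, res, kb = NULL)
  expect_equal(out2$trace$final, "filtered_germline")

  ## Pindel indel with KB hit retained; without, dropped as FP-rich
  pkb <- makeKb(chrom = "chr1", pos = 500L, ref = "A", alt = "AT",
                gene = "EGFR", tags = "drug_sensitivity_resistance")
  pin <- makeCall(pos = 500L, ref = "A", alt = "AT", vtype = "indel",
                  caller = "pindel", ALT_AF = 0.2)
  expect_equal(runSomaticPipeline(pin, emptyResource(), pkb)$trace$final,
               "somatic_pass")
  expect_equal(runSomaticPipeline(pin, emptyResource(), NULL)$trace$final,
               "filtered_fp")

  ## quality-failed variants are not rescue-eligible by default
  bad <- makeCall(pos = 100L, ALT_AF = 0.48, QD = 1.0)
  expect_equal(runSomaticPipeline(bad, res, kb)$trace$final,
               "filtered_quality")
  cfg <- somaticFilterConfig(rescueQualityFailed = TRUE)
  expect_equal(runSomaticPipeline(bad, res, kb, cfg)$trace$final,
               "rescued_clinical")

  ## protein-change matching path
  kbProt <- makeKb(gene = "KRAS", protein_change = "G12C",
                   tags = "treatment_approach")
  prot <- makeCall(pos = 100L, ALT_AF = 0.5, gene = "KRAS",
                   protein_change = "G12C")
  expect_equal(runSomaticPipeline(prot, res, kbProt)$trace$final,
               "rescued_clinical")
})

test_that("pipeline statuses partition all inputs and conserve counts", {
  cfg <- simConfig(seed = 13, nSamples = 12, nGermline = 20, nSomatic = 8,
                   nArtifact = 4, qualityFailFraction = 0.1)
  cohort <- simulateVariantCohort(cfg)
  out <- runSomaticPipeline(cohort$calls, cohort$resource)
  tr <- out$trace
  expect_equal(nrow(tr), nrow(cohort$calls))
  expect_false(anyNA(tr$final))
  expect_true(all(tr$final %in% c("somatic_pass", "filtered_germline",
                                  "filtered_fp", "filtered_quality",
                                  "rescued_clinical")))
  ## rescue containment: rescued implies flagged or pindel
  resc <- tr$rescued
  expect_true(all(!resc | tr$germline_flag | tr$recurrent_fp_flag |
                    tr$caller == "pindel"))
  ## no quality-failed variant is ever emitted
  expect_false(any(tr$quality_status != "pass" &
                     tr$final %in% c("somatic_pass", "rescued_clinical")))
})

test_that("pipeline output is order-independent and deterministic", {
  cfg <- simConfig(seed = 17, nSamples = 8, nGermline = 15, nSomatic = 6,
                   nArtifact = 3)
  cohort <- simulateVariantCohort(cfg)
  out1 <- runSomaticPipeline(cohort$calls, cohort$resource)
  set.seed(1)
  shuffled <- cohort$calls[sample(nrow(cohort$calls)), , drop = FALSE]
  out2 <- runSomaticPipeline(shuffled, cohort$resource)
  k1 <- with(out1$trace, paste(sample_id, chrom, pos, alt))
  k2 <- with(out2$trace, paste(sample_id, chrom, pos, alt))
  expect_equal(out1$trace$final, out2$trace$final[match(k1, k2)])
  out3 <- runSomaticPipeline(cohort$calls, cohort$resource)
  expect_identical(out1$trace, out3$trace)
})

test_that("multi-allelic records are decomposed before filtering", {
  calls <- makeCall(alt = "T,G", ALT_AF = 0.3)
  out <- runSomaticPipeline(calls, emptyResource())
  expect_equal(nrow(out$trace), 2)
  expect_setequal(out$trace$alt, c("T", "G"))
})

test_that("planted germline and artifacts are removed at the documented rates", {
  cfg <- simConfig(seed = 19, nSamples = 20)
  cohort <- simulateVariantCohort(cfg)
  out <- runSomaticPipeline(cohort$calls, cohort$resource)
  tr <- out$trace
  key <- paste(tr$sample_id, tr$pos)
  tkey <- paste(cohort$truth$sample_id, cohort$truth$pos)
  lab <- cohort$truth$label[match(key, tkey)]
  germFinal <- tr$final[lab == "germline"]
  expect_gte(mean(germFinal %in% c("filtered_germline", "rescued_clinical")),
             0.95)
  ## every planted artifact locus recurs above threshold: filtered in all
  expect_true(all(tr$final[lab == "artifact"] == "filtered_fp"))
})

test_that("full filter stack improves precision over quality-only filtering", {
  cfg <- simConfig(seed = 23, nSamples = 10, contaminationFraction = 0.15)
  cohort <- simulateVariantCohort(cfg)
  universe <- unique(cohort$truth[c("chrom", "pos", "alt")])
  truthSomatic <- cohort$truth[cohort$truth$label == "somatic", ]
  precFor <- function(trace) {
    keep <- trace$final %in% c("somatic_pass", "rescued_clinical")
    sapply(unique(trace$sample_id), function(s) {
      pred <- trace[keep & trace$sample_id == s, ]
      tru <- truthSomatic[truthSomatic$sample_id == s, ]
      benchmarkMetrics(benchmarkCalls(pred, tru, universe))$precision
    })
  }
  full <- runSomaticPipeline(cohort$calls, cohort$resource)
  ## germline/FP filters disabled: empty resource, recurrence skipped
  reduced <- runSomaticPipeline(cohort$calls, emptyResource(),
                                config = somaticFilterConfig(
                                  fpMinCohort = 1e6))
  expect_true(all(precFor(full$trace) >= precFor(reduced$trace)))
  expect_gt(mean(precFor(full$trace)), mean(precFor(reduced$trace)))
})
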