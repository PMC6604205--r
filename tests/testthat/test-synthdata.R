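test_that("reference pair respects divergence and determinism", {
  cfg0 <- simConfig(seed = 1, refLength = 2000, readLength = 100,
                    divergence = 0)
  refs0 <- simulateReferencePair(cfg0)
  expect_identical(as.character(refs0$graft), as.character(refs0$host))

  cfg <- simConfig(seed = 1, refLength = 10000, readLength = 100,
                   divergence = 0.15)
  refs <- simulateReferencePair(cfg)
  g <- strsplit(as.character(refs$graft[[1]]), "")[[1]]
  h <- strsplit(as.character(refs$host[[1]]), "")[[1]]
  ham <- mean(g != h)
  bound <- 3 * sqrt(0.15 * 0.85 / 10000)
  expect_lt(abs(ham - 0.15), bound)

  refs2 <- simulateReferencePair(cfg)
  expect_identical(as.character(refs$graft), as.character(refs2$graft))
  expect_identical(as.character(refs$host), as.character(refs2$host))

  expect_error(simConfig(divergence = 1.5), "divergence")
})

test_that("read set honours contamination fraction and coverage arithmetic", {
  cfg <- simConfig(seed = 3, refLength = 2000, readLength = 100,
                   coverage = 50, contaminationFraction = 0)
  refs <- simulateReferencePair(cfg)
  rs <- simulateReadSet(cfg, refs$graft, refs$host)
  expect_true(all(rs$origin == "graft"))
  ## pair count = coverage * refLength / (2 * readLength)
  expect_equal(nrow(rs$pairs), 50 * 2000 / (2 * 100))

  cfg25 <- simConfig(seed = 3, refLength = 2000, readLength = 100,
                     coverage = 125, contaminationFraction = 0.25)
  rs25 <- simulateReadSet(cfg25, refs$graft, refs$host)
  n <- nrow(rs25$pairs)
  expect_equal(n, 1250)
  hostN <- sum(rs25$origin == "host")
  ci <- qbinom(c(0.005, 0.995), n, 0.25)
  expect_gte(hostN, ci[1])
  expect_lte(hostN, ci[2])

  expect_error(simulateReadSet(
    simConfig(seed = 1, refLength = 2000, readLength = 100,
              coverage = 0.01), refs$graft, refs$host),
    "zero read pairs")
})

test_that("variant cohort conserves planted truth and admits only configured labels", {
  cfg <- simConfig(seed = 7, nSamples = 20, nGermline = 30, nSomatic = 10,
                   nArtifact = 5, fpRecurrence = 0.30)
  cohort <- simulateVariantCohort(cfg)
  truth <- cohort$truth
  ## unique (sample, chrom, pos, alt)
  expect_false(anyDuplicated(paste(truth$sample_id, truth$chrom, truth$pos,
                                   truth$alt)) > 0)
  expect_true(all(truth$true_af > 0 & truth$true_af <= 1))
  ## somatic records exactly nSamples * nSomatic
  expect_equal(sum(truth$label == "somatic"), 20 * 10)
  ## every artifact locus in >= ceiling(0.30 * 20) = 6 samples
  artCounts <- table(truth$pos[truth$label == "artifact"])
  expect_length(artCounts, 5)
  expect_true(all(artCounts >= 6))
  ## germline loci are all in the resource; artifacts and somatic are not
  e <- cohort$resource@entries
  rkey <- paste(e$chrom, e$pos, e$ref, e$alt)
  tkey <- paste(truth$chrom, truth$pos, truth$ref, truth$alt)
  expect_true(all(tkey[truth$label == "germline"] %in% rkey))
  expect_false(any(tkey[truth$label != "germline"] %in% rkey))
  ## determinism
  cohort2 <- simulateVariantCohort(cfg)
  expect_identical(cohort$calls, cohort2$calls)
  expect_identical(cohort$truth, cohort2$truth)
})

test_that("observed allele fractions are binomial around truth", {
  cfg <- simConfig(seed = 11, nSamples = 10, nGermline = 40, nSomatic = 0,
                   nArtifact = 0, coverage = 1000, germlineAfSet = 0.5,
                   germlineCarrierRate = 1)
  cohort <- simulateVariantCohort(cfg)
  dev <- abs(cohort$calls$ALT_AF - 0.5)
  ## 3-sigma binomial bound at depth ~1000 holds for 99%+ of loci
  expect_gte(mean(dev <= 3.5 * sqrt(0.25 / 1000)), 0.99)
})

test_that("cohort with only germline configured yields only germline truth", {
  cfg <- simConfig(seed = 2, nSamples = 1, nSomatic = 0, nArtifact = 0,
                   nGermline = 10)
  cohort <- simulateVariantCohort(cfg)
  expect_true(all(cohort$truth$label == "germline"))
})

test_that("expression cohort plants a directional signature", {
  expect_error(simulateExpressionCohort(nEbv = 0, nOther = 10), "nEbv")
  expect_error(simulateExpressionCohort(effect = 0), "effect")
  expect_error(simulateExpressionCohort(signatureSize = 7), "even")

  sim <- simulateExpressionCohort(nEbv = 5, nOther = 10, signatureSize = 8,
                                  effect = 2, seed = 4, nGenes = 200)
  expect_equal(dim(sim$counts), c(200L, 15L))
  ebv <- sim$labels == "EBV"
  up <- sim$signature$gene[sim$signature$sign == 1]
  down <- sim$signature$gene[sim$signature$sign == -1]
  expect_true(all(rowMeans(sim$counts[up, ebv]) >
                    rowMeans(sim$counts[up, !ebv])))
  expect_true(all(rowMeans(sim$counts[down, ebv]) <
                    rowMeans(sim$counts[down, !ebv])))
  sim2 <- simulateExpressionCohort(nEbv = 5, nOther = 10, signatureSize = 8,
                                   effect = 2, seed = 4, nGenes = 200)
  expect_identical(sim$counts, sim2$counts)
})

test_that("cn profiles tile chromosomes and match the ploidy definition", {
  genes <- data.frame(gene = sprintf("G%02d", 1:10),
                      chrom = rep(c("chr1", "chr2"), each = 5),
                      start = rep(seq(100, 8100, by = 2000), 2),
                      end = rep(seq(400, 8400, by = 2000), 2))
  prof <- simulateCnProfiles(4, genes, seed = 5)
  for (s in unique(prof$segments$sample)) {
    for (ch in unique(prof$segments$chrom)) {
      segs <- prof$segments[prof$segments$sample == s &
                              prof$segments$chrom == ch, ]
      segs <- segs[order(segs$start), ]
      expect_equal(segs$start[1], 1)
      if (nrow(segs) > 1)
        expect_equal(segs$start[-1], segs$end[-nrow(segs)] + 1)
    }
    expect_equal(prof$ploidy$ploidy[prof$ploidy$sample == s],
                 computePloidy(prof$segments[prof$segments$sample == s, ]))
  }
})

test_that("ploidy is the length-weighted mean total copy number", {
  segs <- data.frame(chrom = "chr1", start = c(1, 501), end = c(500, 1000),
                     nMajor = c(2, 1), nMinor = c(2, 1))
  expect_equal(computePloidy(segs), 3)
  diploid <- data.frame(chrom = "chr1", start = 1, end = 1000,
                        nMajor = 1, nMinor = 1)
  expect_equal(computePloidy(diploid), 2)
})

test_that("zero-noise coupled expression tracks log2(CN/ploidy) exactly", {
  genes <- data.frame(gene = sprintf("G%02d", 1:8), chrom = "chr1",
                      start = seq(100, 14100, by = 2000),
                      end = seq(300, 14300, by = 2000))
  prof <- simulateCnProfiles(6, genes, seed = 9, coupleExpression = TRUE,
                             noiseSd = 0)
  ratio <- sapply(seq_len(6), function(j) {
    s <- prof$ploidy$sample[j]
    gc <- geneCopyNumber(prof$segments[prof$segments$sample == s, ], genes,
                         prof$ploidy$ploidy[j])
    gc$log2_vs_ploidy
  })
  ## expression minus its per-gene mean equals the centered CN ratio
  centeredExpr <- prof$expression - rowMeans(prof$expression)
  centeredRatio <- ratio - rowMeans(ratio)
  expect_equal(unname(centeredExpr), unname(centeredRatio),
               tolerance = 1e-10)
})
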