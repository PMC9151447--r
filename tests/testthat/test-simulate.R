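test_that("simulation configs enforce their invariants", {
  expect_error(simConfig(fst = 1), "fst")
  expect_error(simConfig(fst = -0.1), "fst")
  expect_error(simConfig(nAfr = 0), "counts")
  expect_error(simConfig(plantedDe = data.frame(gene = "NOPE",
                                                log2fc = 1)),
               "unknown genes")
  expect_error(simConfig(plantedDmps = data.frame(cpg = "cg000001",
                                                  deltaBeta = 0.6,
                                                  direction = "hyper")),
               "outside")
  expect_error(simConfig(plantedFeedbackMtrs = "ZZZ"), "subset")
})

test_that("undiverged populations have matching allele frequencies", {
  cfg <- simConfig(seed = 1, nSnps = 20000, fst = 0)
  g <- simulateGenotypes(cfg, pops = c(A = 50L, B = 50L))
  pA <- colMeans(g$dosages[g$labels == "A", ]) / 2
  pB <- colMeans(g$dosages[g$labels == "B", ]) / 2
  expect_lt(abs(mean(pA - pB)), 0.02)
  expect_true(all(g$dosages %in% 0:2))
})

test_that("all generators are reproducible under a fixed seed", {
  cfg <- simConfig(seed = 99, nAfr = 12, nEur = 12, nGenes = 100,
                   nCpgs = 100, nSnps = 50, networkSize = 60,
                   nYesPromoters = 5, nNoPromoters = 5)
  lib <- syntheticPwmLibrary(99, n = 5)
  cfg$plantedModule <- names(lib)[1:2]
  run <- function() {
    md <- simulateMetadata(cfg)
    list(md = md,
         g = simulateGenotypes(cfg),
         ex = simulateExpression(cfg, md),
         pr = simulatePromoters(cfg, lib),
         nw = simulateNetwork(cfg))
  }
  a <- run(); b <- run()
  expect_identical(a$md, b$md)
  expect_identical(a$g$dosages, b$g$dosages)
  expect_identical(a$ex$counts, b$ex$counts)
  expect_identical(a$pr$yes, b$pr$yes)
  expect_identical(networkEdges(a$nw$network), networkEdges(b$nw$network))
  # promoter FASTA bytes are identical across runs
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  writeFastaSequences(a$pr$yes, p1)
  writeFastaSequences(b$pr$yes, p2)
  expect_identical(readLines(p1), readLines(p2))
  me1 <- simulateMethylation(cfg, a$md, a$ex$counts)
  me2 <- simulateMethylation(cfg, b$md, b$ex$counts)
  expect_identical(me1$betaTumor, me2$betaTumor)
})

test_that("near-Poisson counts without planted effects stay at baseline", {
  cfg <- simConfig(seed = 4, nAfr = 30, nEur = 30, nGenes = 300,
                   nSnps = 10, nbDispersion = 0,
                   plantedDe = data.frame(gene = character(),
                                          log2fc = numeric()),
                   immuneEffects = list(), markerGain = 0,
                   covariateEffectSd = 0)
  md <- simulateMetadata(cfg)
  ex <- simulateExpression(cfg, md)
  anc <- md$ancestry[match(colnames(ex$counts), md$sample_id)]
  overall <- rowMeans(ex$counts)
  gap <- abs(rowMeans(ex$counts[, anc == "AFR"]) -
               rowMeans(ex$counts[, anc == "EUR"])) / overall
  # Poisson noise only: typical genes sit within 2% of baseline, and even
  # the lowest-expressed genes stay within sampling error
  expect_lt(median(gap), 0.02)
  expect_lt(quantile(gap, 0.99), 0.15)
})

test_that("planted expression effects carry the configured magnitude", {
  cfg <- simConfig(seed = 7, nAfr = 50, nEur = 50, nGenes = 500,
                   nSnps = 10, nbDispersion = 0.1,
                   plantedDe = data.frame(gene = sprintf("G%05d", 1:100),
                                          log2fc = rep(1, 100)))
  md <- simulateMetadata(cfg)
  ex <- simulateExpression(cfg, md)
  anc <- md$ancestry[match(colnames(ex$counts), md$sample_id)]
  ratio <- log2(rowMeans(ex$counts[cfg$plantedDe$gene, anc == "AFR"]) /
                  rowMeans(ex$counts[cfg$plantedDe$gene, anc == "EUR"]))
  expect_gte(median(ratio), 0.8)
  expect_lte(median(ratio), 1.2)
})

test_that("a marker planted as conflicting-sign DE is rejected", {
  cfg <- simConfig(seed = 8, nGenes = 200, nAfr = 10, nEur = 10,
                   nSnps = 10)
  md <- simulateMetadata(cfg)
  # marker sets come from the tail of the gene list: plant an opposite
  # effect on one of them
  ex <- simulateExpression(cfg, md)
  marker <- ex$markerSets$cytotoxic_lymphocytes[1]
  cfg2 <- simConfig(seed = 8, nGenes = 200, nAfr = 10, nEur = 10,
                    nSnps = 10,
                    plantedDe = data.frame(gene = marker, log2fc = 2))
  expect_error(simulateExpression(cfg2, md), "conflicting sign")
})

test_that("methylation baselines are quiet without planted effects", {
  cfg <- simConfig(seed = 6, nAfr = 50, nEur = 50, nCpgs = 200,
                   nGenes = 50, nSnps = 10, normalFraction = 1,
                   plantedDmps = data.frame(cpg = character(),
                                            deltaBeta = numeric(),
                                            direction = character()),
                   plantedMsGenes = data.frame(gene = character(),
                                               cpg = character(),
                                               targetR = numeric()))
  md <- simulateMetadata(cfg)
  me <- simulateMethylation(cfg, md)
  expect_true(all(me$betaTumor > 0 & me$betaTumor < 1))
  sharedPatients <- intersect(sub("_T", "", colnames(me$betaTumor)),
                              sub("_N", "", colnames(me$betaNormal)))
  dT <- rowMeans(me$betaTumor[, paste0(sharedPatients, "_T")])
  dN <- rowMeans(me$betaNormal[, paste0(sharedPatients, "_N")])
  expect_lt(max(abs(dT - dN)), 0.075)
  expect_lt(mean(abs(dT - dN)), 0.02)
})

test_that("planted anti-correlation is realized in the tumor betas", {
  cfg <- simConfig(seed = 12, nAfr = 50, nEur = 50, nGenes = 200,
                   nCpgs = 200, nSnps = 10,
                   plantedMsGenes = data.frame(gene = "G00001",
                                               cpg = "cg000150",
                                               targetR = -0.7))
  md <- simulateMetadata(cfg)
  ex <- simulateExpression(cfg, md)
  me <- simulateMethylation(cfg, md, ex$counts)
  e <- log2(ex$counts["G00001", colnames(me$betaTumor)] + 1)
  r <- cor(me$betaTumor["cg000150", ], e)
  expect_gt(r, -0.9)
  expect_lt(r, -0.5)
})

test_that("planted promoter sites sit at their reported coordinates", {
  lib <- syntheticPwmLibrary(11, n = 20)
  cfg <- simConfig(seed = 11, plantedModule = names(lib)[1:3],
                   moduleWindow = 150, nYesPromoters = 60,
                   nNoPromoters = 60)
  pr <- simulatePromoters(cfg, lib)
  expect_equal(nrow(pr$truth), 180L)  # one site per PWM per yes promoter
  ok <- mapply(function(p, st, site)
    substr(pr$yes[[p]], st, st + nchar(site) - 1) == site,
    pr$truth$promoter, pr$truth$start, pr$truth$site)
  expect_true(all(ok))
  # all three sites fall inside one moduleWindow-wide stretch
  spans <- tapply(seq_len(nrow(pr$truth)), pr$truth$promoter, function(ix)
    max(pr$truth$start[ix] + nchar(pr$truth$site[ix]) - 1) -
      min(pr$truth$start[ix]) + 1)
  expect_true(all(spans <= cfg$moduleWindow))
  expect_error(simulatePromoters(
    simConfig(seed = 1, plantedModule = names(lib)[1:3],
              moduleWindow = 25), lib), "window smaller")
})

test_that("simulated truth files round-trip through the writer", {
  cfg <- simConfig(seed = 2, nAfr = 10, nEur = 10, nGenes = 80,
                   nCpgs = 80, nSnps = 30, networkSize = 50,
                   nYesPromoters = 4, nNoPromoters = 4)
  sim <- simulateAll(cfg)
  dir <- withr::local_tempdir()
  writeSimulation(sim, dir)
  expect_true(file.exists(file.path(dir, "genotypes.tsv")))
  truth <- read.delim(file.path(dir, "truth", "planted.tsv"))
  expect_setequal(unique(truth$category),
                  c("planted_de", "planted_dmp", "planted_ms",
                    "planted_mtr", "true_population", "planted_site"))
  counts <- readTsvMatrix(file.path(dir, "counts.tsv"))
  expect_identical(counts, sim$expression$counts)
})
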