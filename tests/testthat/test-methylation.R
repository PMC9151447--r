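test_that("probe filtering tallies removals by rule precedence", {
  withr::with_seed(1, {
    b <- matrix(runif(20), 10, 2,
                dimnames = list(sprintf("cg%02d", 1:10), c("s1", "s2")))
  })
  b["cg01", 1] <- NA
  ann <- data.frame(cpg = sprintf("cg%02d", 1:10), chrom = "chr1",
                    pos = 1:10, cross_reactive = FALSE,
                    snp_related = FALSE, multi_hit = FALSE,
                    non_cpg = FALSE, sex_chromosome = FALSE)
  ann$sex_chromosome[2:3] <- TRUE
  ann$snp_related[4] <- TRUE
  f <- filterProbes(b, ann)
  expect_equal(nrow(f$betas), 6L)
  expect_equal(unname(f$tally[c("missing_value", "sex_chromosome",
                                "snp_related")]), c(1L, 2L, 1L))
  # no flags, no missing: identity
  clean <- ann; clean$sex_chromosome <- FALSE; clean$snp_related <- FALSE
  b2 <- b; b2["cg01", 1] <- 0.5
  expect_equal(filterProbes(b2, clean)$betas, b2)
  # double-flagged probe counted once, under the first matching rule
  dual <- clean; dual$cross_reactive[5] <- TRUE; dual$multi_hit[5] <- TRUE
  f3 <- filterProbes(b2, dual)
  expect_equal(unname(f3$tally["cross_reactive"]), 1L)
  expect_equal(unname(f3$tally["multi_hit"]), 0L)
  allflag <- clean; allflag$non_cpg <- TRUE
  expect_error(filterProbes(b2, allflag), "all probes")
})

test_that("type-II normalization is a rank-preserving quantile map", {
  withr::with_seed(2, {
    n <- 50
    dt <- setNames(rep(c("I", "II"), each = n), sprintf("cg%03d", 1:(2 * n)))
    x1 <- sort(runif(n))
    x2 <- runif(n)
    b <- matrix(c(x1, x2), ncol = 1,
                dimnames = list(names(dt), "s1"))
    out <- normalizeBetas(b, dt)
    i2 <- names(dt)[dt == "II"]
    # explicit sort-and-interpolate oracle
    pr <- (rank(x2) - 1) / (n - 1)
    h <- (n - 1) * pr + 1
    lo <- floor(h)
    x1s <- sort(x1)
    oracle <- x1s[lo] + (h - lo) * (x1s[pmin(lo + 1, n)] - x1s[lo])
    expect_equal(unname(out[i2, 1]), oracle, tolerance = 1e-12)
    # monotone and in range
    ord <- order(x2)
    expect_true(all(diff(out[i2, 1][ord]) >= 0))
    expect_true(all(out >= 0 & out <= 1))
    # fixed point: type II already distributed as type I
    bEq <- matrix(c(x1, x1), ncol = 1, dimnames = list(names(dt), "s1"))
    outEq <- normalizeBetas(bEq, dt)
    expect_lt(max(abs(outEq - bEq)), 1e-6)
  })
})

test_that("normalization skips samples short on type-I probes", {
  b <- matrix(runif(10), 5, 2,
              dimnames = list(paste0("cg", 1:5), c("s1", "s2")))
  dt <- setNames(c("I", rep("II", 4)), paste0("cg", 1:5))
  expect_warning(out <- normalizeBetas(b, dt), "fewer than 10")
  expect_equal(out, b)
})

test_that("beta-to-M is the log2 logit with clipping", {
  expect_equal(betaToM(0.5), 0)
  expect_equal(betaToM(0.8), 2)
  expect_equal(betaToM(0), log2(1e-6 / (1 - 1e-6)))
  b <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(betaToM(b)) > 0))
})

test_that("planted DMPs are recovered with the right direction", {
  cfg <- simConfig(seed = 3, nAfr = 40, nEur = 40, nCpgs = 800,
                   nGenes = 50, nSnps = 10,
                   plantedMsGenes = data.frame(gene = character(),
                                               cpg = character(),
                                               targetR = numeric()))
  md <- simulateMetadata(cfg)
  me <- simulateMethylation(cfg, md)
  res <- testDmps(me$betaTumor, md)
  planted <- res[match(cfg$plantedDmps$cpg, res$cpg), ]
  expect_gte(mean(planted$q < 0.05 &
                    planted$direction == cfg$plantedDmps$direction), 0.9)
  # realized mean beta difference close to the planted delta
  isAfr <- md$ancestry[match(colnames(me$betaTumor), md$sample_id)] ==
    "AFR"
  hyper <- cfg$plantedDmps$cpg[cfg$plantedDmps$direction == "hyper"]
  diff <- rowMeans(me$betaTumor[hyper, isAfr]) -
    rowMeans(me$betaTumor[hyper, !isAfr])
  expect_lt(abs(mean(diff) - 0.25), 0.05)
  # directions always match the sign of the mean difference
  expect_equal(res$direction, ifelse(res$delta_beta >= 0, "hyper",
                                     "hypo"))
})

test_that("a location-driven CpG is not called for ancestry", {
  withr::with_seed(9, {
    n <- 60
    md <- data.frame(sample_id = paste0("s", 1:n),
                     ancestry = rep(c("AFR", "EUR"), each = n / 2),
                     age_group = rep(c("young", "old"), n / 2),
                     tumor_location = rep(c("right", "right", "left",
                                            "left"), length.out = n))
    eta <- ifelse(md$tumor_location == "right", 1, -1) + rnorm(n, 0, 0.3)
    b <- rbind(locdriven = plogis(eta), flat = plogis(rnorm(n, 0, 0.3)))
    colnames(b) <- md$sample_id
    res <- testDmps(b, md)
    expect_gt(res$p[res$cpg == "locdriven"], 0.05)
  })
})

test_that("tumor-specific candidates require a tumor/normal difference", {
  withr::with_seed(15, {
    mkMd <- function() {
      n <- 30
      tumor <- data.frame(sample_id = sprintf("t%02d", 1:n),
                          ancestry = rep(c("AFR", "EUR"), each = n / 2),
                          age_group = "old", tumor_location = "left",
                          tissue = "tumor")
      normal <- tumor
      normal$sample_id <- sprintf("n%02d", 1:n)
      normal$tissue <- "normal"
      rbind(tumor, normal)
    }
    md <- mkMd()
    isAfr <- md$ancestry == "AFR"
    isTum <- md$tissue == "tumor"
    noise <- function() rnorm(nrow(md), 0, 0.3)
    b <- rbind(
      # constitutive ancestry difference (same in tumor and normal):
      # no tumor-vs-normal signal, so never a candidate
      constitutive = plogis(ifelse(isAfr, 1.5, 0) + noise()),
      # ancestry difference in normals only: enters the candidate set
      # through the within-ancestry tumor-vs-normal test, but the
      # tumor-restricted second pass must not call it
      normonly = plogis(ifelse(isAfr & !isTum, 1.5, 0) + noise()),
      # tumor-specific and ancestry-divergent: must survive both passes
      tumorspec = plogis(ifelse(isTum, 1, 0) +
                           ifelse(isTum & isAfr, 1.2, 0) + noise()),
      flat = plogis(noise()))
    colnames(b) <- md$sample_id
    ts <- suppressMessages(tumorSpecificDmps(b, md))
    expect_false("constitutive" %in% ts$candidates)
    expect_true("tumorspec" %in% ts$candidates)
    expect_true("tumorspec" %in% ts$dmps$cpg[ts$dmps$q < 0.05])
    # the normal-only CpG is a true null in the tumor-restricted second
    # pass: its effect stays near zero, far below the planted signal
    norm2 <- ts$dmps[ts$dmps$cpg == "normonly", ]
    expect_lt(abs(norm2$delta_beta), 0.1)
    expect_gt(norm2$p, 1e-4)
    # no tumor/normal signal anywhere: empty candidates with a warning
    bNull <- rbind(flat1 = plogis(noise()), flat2 = plogis(noise()))
    colnames(bNull) <- md$sample_id
    expect_warning(ts0 <- tumorSpecificDmps(bNull, md), "no tumor")
    expect_equal(ts0$candidates, character())
  })
})

test_that("CpG feature mapping is strand-aware with promoter precedence", {
  gm <- data.frame(gene = c("plus", "minus"), chrom = "chr1",
                   strand = c("+", "-"), tss = c(10000L, 50000L),
                   tx_start = c(10000L, 47000L),
                   tx_end = c(13000L, 50000L),
                   utr5_start = c(10000L, 49800L),
                   utr5_end = c(10200L, 50000L),
                   utr3_start = c(12800L, 47000L),
                   utr3_end = c(13000L, 47200L))
  cpgs <- data.frame(cpg = c("atBoundary", "justPast", "inBody",
                             "minusUp", "minusDown", "nowhere"),
                     chrom = "chr1",
                     pos = c(10000L - 1200L,  # TSS-1200: promoter boundary
                             10201L,          # +201: past the window
                             12000L,
                             50000L + 500L,   # minus strand: offset -500
                             50000L - 500L,   # minus strand: offset +500
                             900000L))
  map <- mapCpgToFeatures(cpgs, gm)
  feat <- function(id) map$feature[map$cpg == id]
  expect_equal(feat("atBoundary"), "promoter")
  expect_false("promoter" %in% feat("justPast"))
  expect_equal(feat("inBody"), "body")
  # 500 bp upstream of a minus-strand TSS (higher coordinate) is promoter
  expect_equal(feat("minusUp"), "promoter")
  # 500 bp downstream (3') exceeds +200: inside the gene body instead
  expect_equal(feat("minusDown"), "body")
  expect_equal(feat("nowhere"), "intergenic")
  # enhancer assignment only when no gene feature matches
  enh <- data.frame(chrom = "chr1", start = 899000L, end = 901000L)
  map2 <- mapCpgToFeatures(cpgs, gm, enhancers = enh)
  expect_equal(map2$feature[map2$cpg == "nowhere"], "enhancer")
  expect_warning(mapCpgToFeatures(
    data.frame(cpg = "c", chrom = "chrUn", pos = 5L), gm), "unannotated")
})

test_that("methylation-sensitive screening keeps negative correlations", {
  withr::with_seed(25, {
    n <- 30
    md <- data.frame(sample_id = paste0("s", 1:n),
                     ancestry = rep(c("AFR", "EUR"), each = n / 2))
    expr <- rbind(anti = rnorm(n, 8), pos = rnorm(n, 8),
                  other = rnorm(n, 8))
    colnames(expr) <- md$sample_id
    betas <- rbind(cgA = plogis(-0.9 * scale(expr["anti", ])[, 1] +
                                  rnorm(n, 0, 0.2)),
                   cgB = plogis(0.9 * scale(expr["pos", ])[, 1] +
                                  rnorm(n, 0, 0.2)))
    colnames(betas) <- md$sample_id
    degs <- data.frame(gene = c("anti", "pos"), q = c(0.01, 0.01))
    dmps <- data.frame(cpg = c("cgA", "cgB"), q = c(0.001, 0.001))
    assoc <- data.frame(cpg = c("cgA", "cgB"), gene = c("anti", "pos"))
    ms <- methylationSensitiveGenes(degs, dmps, assoc, betas, expr, md)
    expect_true(ms$included[ms$gene == "anti"])
    expect_false(ms$included[ms$gene == "pos"])
    # Pearson r equals the definitional covariance ratio
    b <- betas["cgA", ]; e <- expr["anti", ]
    oracle <- mean((b - mean(b)) * (e - mean(e))) /
      (sd(b) * sd(e)) * n / (n - 1)
    expect_equal(ms$r[ms$gene == "anti"], oracle, tolerance = 1e-12)
  })
})

test_that("lowest-q CpG is selected for multi-DMP genes", {
  withr::with_seed(26, {
    n <- 20
    md <- data.frame(sample_id = paste0("s", 1:n),
                     ancestry = rep(c("AFR", "EUR"), each = n / 2))
    expr <- matrix(rnorm(n, 8), 1, n,
                   dimnames = list("g", md$sample_id))
    betas <- matrix(runif(2 * n), 2, n,
                    dimnames = list(c("cgLo", "cgHi"), md$sample_id))
    betas["cgLo", ] <- plogis(-2 * scale(expr[1, ])[, 1])
    degs <- data.frame(gene = "g", q = 0.01)
    dmps <- data.frame(cpg = c("cgLo", "cgHi"), q = c(1e-6, 0.2))
    assoc <- data.frame(cpg = c("cgLo", "cgHi"), gene = "g")
    ms <- methylationSensitiveGenes(degs, dmps, assoc, betas, expr, md)
    expect_equal(ms$cpg, "cgLo")
  })
})

test_that("TF partition by nearby methylation state is disjoint", {
  hits <- data.frame(pwm = c("TFh", "TFh", "TFl", "TFb", "TFb", "TFn"),
                     chrom = "chr1",
                     pos = c(1000L, 5000L, 3400L, 1050L, 2080L, 99000L))
  dmps <- data.frame(cpg = c("c1", "c2"), chrom = "chr1",
                     pos = c(1500L, 2500L),
                     direction = c("hyper", "hypo"),
                     gene = c("gDown", "gUp"))
  cls <- c(gDown = "down", gUp = "up")
  part <- tfbsMethylationPartition(hits, dmps, cls, window = 1000L)
  expect_equal(part$hyperOnly, "TFh")
  expect_equal(part$hypoOnly, "TFl")
  expect_equal(part$shared, "TFb")
  expect_false("TFn" %in% unlist(part))
  expect_equal(length(intersect(part$hyperOnly, part$hypoOnly)), 0L)
  # direction-class pairing matters: a hyper DMP near an up gene is inert
  dmps2 <- dmps; dmps2$gene <- c("gUp", "gDown")
  part2 <- tfbsMethylationPartition(hits, dmps2, cls, window = 1000L)
  expect_equal(unlist(part2, use.names = FALSE), character(0))
})
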