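test_that("zero-expression filter removes genes never exceeding 1", {
  m <- rbind(allzero = c(0, 0, 0), allone = c(1, 1, 0),
             withna = c(NA, 1, 0), keep2 = c(0, 0, 2),
             big = c(10, 20, 30))
  colnames(m) <- paste0("s", 1:3)
  expect_message(f <- filterZeroExpression(m), "3 gene")
  expect_equal(rownames(f), c("keep2", "big"))
  expect_error(filterZeroExpression(m[1:2, ]), "all genes removed")
})

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10, 20, 30, 40, 50,
                20, 40, 60, 80, 100,
                10, 20, 30, 40, 50,
                30, 60, 90, 120, 150), nrow = 5)
  rownames(m) <- paste0("g", 1:5); colnames(m) <- paste0("s", 1:4)
  sf <- sizeFactorsMedianOfRatios(m)
  # identical columns get equal factors; the doubled column doubles
  expect_equal(unname(sf["s2"] / sf["s1"]), 2)
  expect_equal(unname(sf["s3"]), unname(sf["s1"]))
  # definitional oracle
  geo <- apply(m, 1, function(x) exp(mean(log(x))))
  oracle <- apply(m, 2, function(col) median(col / geo))
  expect_equal(sf, oracle, tolerance = 1e-12)
  bad <- m; bad[1:5, 1] <- 0
  expect_error(sizeFactorsMedianOfRatios(bad), "all-positive")
})

test_that("vst-like transform hits its fixed points and is monotone", {
  m <- rbind(g1 = c(0, 2, 7), g2 = c(2, 5, 9))
  colnames(m) <- paste0("s", 1:3)
  sf <- c(s1 = 2, s2 = 2, s3 = 2)
  v <- vstLikeTransform(m, sf)
  expect_equal(v["g1", "s1"], 0)   # count 0 -> 0
  expect_equal(v["g1", "s2"], 1)   # count == size factor -> 1
  expect_true(all(diff(v["g2", order(m["g2", ])]) > 0))
})

test_that("planted ancestry effects are recovered and nulls stay quiet", {
  cfg <- simConfig(seed = 7, nAfr = 40, nEur = 40, nGenes = 1000,
                   nSnps = 10,
                   plantedDe = data.frame(
                     gene = sprintf("G%05d", 1:100),
                     log2fc = rep(log2(2^1.5), 100)))
  md <- simulateMetadata(cfg)
  ex <- simulateExpression(cfg, md)
  de <- differentialExpression(ex$counts, md)
  planted <- de[match(cfg$plantedDe$gene, de$gene), ]
  expect_gte(mean(planted$q < 0.05), 0.9)
  nulls <- de[!de$gene %in% cfg$plantedDe$gene, ]
  expect_lte(mean(nulls$class != "none"), 0.05)
  # planted log2 ratio of group means near the planted value
  isAfr <- md$ancestry[match(colnames(ex$counts), md$sample_id)] == "AFR"
  ratio <- log2(rowMeans(ex$counts[cfg$plantedDe$gene, isAfr]) /
                  rowMeans(ex$counts[cfg$plantedDe$gene, !isAfr]))
  expect_true(median(ratio) > 1.2 && median(ratio) < 1.8)
})

test_that("a covariate-driven gene is not called an ancestry DEG", {
  withr::with_seed(13, {
    n <- 40
    md <- data.frame(sample_id = paste0("s", 1:n),
                     ancestry = rep(c("AFR", "EUR"), each = n / 2),
                     age_group = rep(c("young", "old"), n / 2),
                     tumor_location = rep(c("right", "left"),
                                          each = n / 4, length.out = n))
    mu <- ifelse(md$age_group == "young", 800, 200)
    counts <- rbind(agegene = rpois(n, mu),
                    flat = rpois(n, 400),
                    ref = rpois(n, 500))
    colnames(counts) <- md$sample_id
    de <- differentialExpression(counts, md)
    expect_equal(de$class[de$gene == "agegene"], "none")
    expect_gt(de$p[de$gene == "agegene"], 0.01)
  })
})

test_that("differential expression is invariant to row/column order", {
  cfg <- simConfig(seed = 3, nAfr = 15, nEur = 15, nGenes = 150,
                   nSnps = 10)
  md <- simulateMetadata(cfg)
  ex <- simulateExpression(cfg, md)
  base <- differentialExpression(ex$counts, md)
  perm <- differentialExpression(
    ex$counts[sample(nrow(ex$counts)), sample(ncol(ex$counts))], md)
  perm <- perm[match(base$gene, perm$gene), ]
  expect_equal(perm$log2fc, base$log2fc, tolerance = 1e-12)
  expect_equal(perm$p, base$p, tolerance = 1e-12)
  # doubling one sample's counts is absorbed by its size factor
  doubled <- ex$counts
  doubled[, 1] <- doubled[, 1] * 2
  de2 <- differentialExpression(doubled, md)
  expect_equal(de2$log2fc, base$log2fc, tolerance = 0.02)
})

test_that("rank-deficient designs fail loudly", {
  md <- data.frame(sample_id = paste0("s", 1:12),
                   ancestry = rep(c("AFR", "EUR"), each = 6),
                   age_group = rep(c("young", "old"), each = 6),
                   tumor_location = "right")
  counts <- matrix(rpois(36, 100), 3, 12,
                   dimnames = list(paste0("g", 1:3), md$sample_id))
  expect_error(differentialExpression(counts, md,
                                      covariates = "age_group"),
               "rank deficient")
})

test_that("DEG classification applies the fold-change and q gates", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = log2(c(1.6, 1.4, 0.4, 2.0)),
                    q = c(0.01, 0.001, 0.049, 0.2))
  cls <- classifyDegs(res)$class
  expect_equal(cls, c("up", "none", "down", "none"))
  expect_error(classifyDegs(res, upFc = 0.4, downFc = 0.5), "exceed")
})

test_that("hypergeometric enrichment equals combinatorial enumeration", {
  universe <- paste0("g", 1:20)
  r <- oraEnrichment(universe[1:5], universe[1:5], universe)
  expect_equal(r$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(r$overlap, 5L)
  # zero overlap when 0 is the minimum possible -> p = 1
  r0 <- oraEnrichment(universe[1:5], universe[10:14], universe)
  expect_equal(r0$p, 1)
  # brute force over all overlaps for small universes
  withr::with_seed(17, {
    for (i in 1:20) {
      N <- sample(5:15, 1)
      u <- paste0("x", seq_len(N))
      m <- sample(1:(N - 1), 1)
      n <- sample(1:(N - 1), 1)
      set <- sample(u, m)
      query <- sample(u, n)
      k <- length(intersect(set, query))
      oracle <- sum(vapply(k:min(m, n), function(j)
        choose(m, j) * choose(N - m, n - j), numeric(1))) / choose(N, n)
      expect_equal(oraEnrichment(query, set, u)$p, oracle,
                   tolerance = 1e-12)
    }
  })
  expect_error(oraEnrichment("a", "a", character()), "empty universe")
})

test_that("enrichment tables BH-adjust across gene sets", {
  universe <- paste0("g", 1:30)
  sets <- list(hit = universe[1:5], miss = universe[21:25])
  tab <- oraEnrichmentTable(universe[1:5], sets, universe)
  expect_equal(tab$overlap, c(5L, 0L))
  expect_true(all(tab$q >= tab$p))
})
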