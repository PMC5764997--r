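test_that("expression filter applies strict count and rpkm rules", {
  m <- rbind(low = c(5, 15, 19), edge = c(5, 15, 20), ok = c(0, 0, 21))
  tce <- make_tce(m)
  expect_equal(filterExpressed(tce), "ok")   # "more than 20" is strict

  ## rpkm rescue: counts (10,10,10), length 1000 bp, library 1e6
  m2 <- rbind(target = c(10, 10, 10),
              filler = c(1e6 - 10, 1e6 - 10, 1e6 - 10))
  tce2 <- TimeCourseExperiment(m2, time_h = c(0, 6, 12), species = "t",
                               gene_length_bp = c(target = 1000,
                                                  filler = 1e6))
  ## rpkm(target) = 10 * 1e9 / (1e6 * 1000) = 10 > 1
  expect_true("target" %in% filterExpressed(tce2))
})

test_that("library size factors are column sums over their geometric mean", {
  m <- cbind(c(10, 10), c(10, 10))
  expect_equal(normalizeLibSizes(m), c(1, 1))
  m2 <- cbind(c(1e6, 0), c(2e6, 0))
  expect_equal(normalizeLibSizes(m2), c(1 / sqrt(2), sqrt(2)))
  expect_equal(normalizeLibSizes(cbind(c(3, 4))), 1)
  expect_error(normalizeLibSizes(cbind(c(1, 2), c(0, 0))), "all-zero")
})

test_that("log2 fold change uses normalized counts with a pseudocount", {
  m <- rbind(a = c(10, 40), b = c(7, 7), c = c(0, 0))
  tce <- make_tce(m, time_h = c(0, 6))
  lfc <- computeLog2FC(tce, factors = c(1, 1))
  expect_equal(lfc["a", 2], log2(40.5 / 10.5))
  expect_equal(unname(lfc[, 1]), c(0, 0, 0))   # baseline column
  expect_equal(lfc["b", 2], 0)                 # identical columns
  expect_equal(lfc["c", 2], 0)                 # 0 vs 0 under pseudocount
})

test_that("the NB exact test matches enumeration and behaves at the edges", {
  expect_equal(nbExactTest(5, 5), 1)                     # observed mode
  expect_equal(nbExactTest(0, 0), 1)
  expect_equal(nbExactTest(0, 50, dispersion = 0), 2 * 2^-50)
  expect_error(nbExactTest(1, 1, dispersion = -0.1), "dispersion")
  ## p in (0, 1]; symmetry under swapping counts at equal sizes
  set.seed(41)
  for (i in 1:25) {
    a <- rpois(1, 30); b <- rpois(1, 30)
    phi <- sample(c(0, 0.05, 0.2), 1)
    p <- nbExactTest(a, b, dispersion = phi)
    expect_gt(p, 0); expect_lte(p, 1)
    expect_equal(p, nbExactTest(b, a, dispersion = phi))
    ## independent log-gamma enumeration oracle
    expect_equal(p, oracle_exact_test(a, b, phi), tolerance = 1e-12)
  }
})

test_that("BH adjustment equals the step-up oracle and stats::p.adjust", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.5), 0.5)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhAdjust(c(0.1, NaN)), "NA")
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_equal(adj, p.adjust(p, "BH"))
    expect_gte(min(adj - p), 0)                 # p_adj >= p_raw
    expect_false(is.unsorted(adj[order(p)]))    # monotone in sorted order
  }
})

test_that("DE calls are strict at both thresholds", {
  lfc <- matrix(c(0, 2.5, 0, 2.0, 0, 3.0), nrow = 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), NULL))
  padj <- matrix(c(NA, 0.01, NA, 0.001, NA, 0.06), nrow = 3, byrow = TRUE)
  calls <- callDE(lfc, padj, deConfig())
  expect_equal(unname(calls$gene_de), c(TRUE, FALSE, FALSE))
})

test_that("the full DE chain recovers a planted gene and respects scaling", {
  set.seed(43)
  mu <- matrix(100, 50, 4)
  mu[1, 2:4] <- 800                      # planted sustained up, log2FC = 3
  m <- matrix(rnbinom(length(mu), size = 10, mu = mu), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  tce <- make_tce(m, time_h = c(0, 6, 12, 24))
  de <- runDE(tce)
  expect_true("g01" %in% deGenes(de))
  res <- deResults(de)
  expect_true(all(res$p_adj >= res$p_raw))
  ## uniform scaling of all counts preserves fold-change signs of DE calls
  de3 <- runDE(make_tce(m * 3L, time_h = c(0, 6, 12, 24)))
  common <- intersect(deGenes(de), deGenes(de3))
  expect_true("g01" %in% common)
  expect_equal(sign(de@log2fc[common, -1]), sign(de3@log2fc[common, -1]),
               tolerance = 1e-6)
})

test_that("the moment dispersion estimator is sane on null data", {
  set.seed(44)
  m <- matrix(rnbinom(500 * 5, size = 1 / 0.1, mu = 100), 500, 5)
  rownames(m) <- sprintf("g%03d", 1:500)
  phi <- estimateDispersionMoments(make_tce(m))
  expect_gt(phi, 0.02)
  expect_lt(phi, 0.3)
})
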