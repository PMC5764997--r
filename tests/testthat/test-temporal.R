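test_that("time rescaling maps any grid onto the unit interval", {
  expect_equal(rescaleTime(c(0, 6, 12, 24)), c(0, 0.25, 0.5, 1))
  expect_equal(rescaleTime(c(0, 72, 168, 336, 504)),
               c(0, 1 / 7, 1 / 3, 2 / 3, 1))
  expect_equal(rescaleTime(c(5, 10)), c(0, 1))
  ## idempotent on already-rescaled grids
  r <- rescaleTime(c(0, 0.5, 3, 6, 12, 24, 48))
  expect_equal(rescaleTime(r), r)
  expect_error(rescaleTime(c(3, 2)), "strictly increasing")
  expect_error(rescaleTime(7), "two time points")
})

test_that("phase assignment follows the two-early/two-late default rule", {
  ph <- assignPhases(c(0, 0.5, 3, 6, 12, 24, 48), "hydra")
  expect_equal(ph@early, c(2L, 3L))
  expect_equal(ph@late, c(6L, 7L))
  expect_equal(ph@recovery, 6L)          # first index at >= 24 h
  ## sparse-grid override: one early point, 14-day recovery
  aj <- assignPhases(c(0, 72, 168, 336, 504), "seacucumber",
                     early = 2L, recovery_h = 14 * 24)
  expect_equal(aj@early, 2L)
  expect_equal(aj@recovery, 4L)
  ## degenerate grid with two non-baseline points
  d <- assignPhases(c(0, 6, 12), "mini")
  expect_equal(d@early, 2L)
  expect_equal(d@late, 3L)
  expect_error(assignPhases(c(0, 6, 12, 24), "bad",
                            early = 2:3, late = 3:4), "overlap")
})

test_that("pattern classification implements the four canonical shapes", {
  ph <- assignPhases(c(0, 6, 12, 24, 36), "t")
  expect_equal(ph@early, c(2L, 3L)); expect_equal(ph@late, c(4L, 5L))
  eu <- classifyPattern(c(0, 3, 2.5, 0.2, 0.1),
                        c(FALSE, TRUE, TRUE, FALSE, FALSE), ph)
  expect_equal(as.character(eu$pattern), "EU")
  expect_equal(eu$peak_log2fc, 3)
  ld <- classifyPattern(c(0, -3, -3.2, -2.9, -3.1), c(FALSE, rep(TRUE, 4)),
                        ph)
  expect_equal(as.character(ld$pattern), "LD")
  other <- classifyPattern(c(0, 3, -3, 0.1, 0), c(FALSE, TRUE, TRUE, FALSE,
                                                  FALSE), ph)
  expect_equal(as.character(other$pattern), "OTHER")
  expect_error(classifyPattern(c(0, 1, 1, 1, 1), rep(FALSE, 5), ph),
               "not DE")
})

test_that("patterns are exclusive, exhaustive and negation-symmetric", {
  ph <- assignPhases(seq(0, 36, by = 6), "t")
  set.seed(51)
  flip <- c(EU = "ED", ED = "EU", LU = "LD", LD = "LU", OTHER = "OTHER")
  for (i in 1:200) {
    lfc <- c(0, rnorm(6, sd = 2))
    de <- c(FALSE, abs(lfc[-1]) > 2)
    if (!any(de)) next
    lab <- as.character(classifyPattern(lfc, de, ph)$pattern)
    expect_true(lab %in% c("EU", "ED", "LU", "LD", "OTHER"))
    neg <- as.character(classifyPattern(-lfc, de, ph)$pattern)
    expect_equal(neg, unname(flip[lab]))
  }
})

test_that("planted pulse shapes are recovered from noisy log2FC profiles", {
  ph <- assignPhases(seq(0, 36, by = 6), "t")
  set.seed(52)
  prof <- generatePatternProfiles(n_per_pattern = 50, effect = 3,
                                  noise_sd = 0.2, phases = ph)
  calls <- classifyPatterns(prof, ph)
  acc <- mean(as.character(calls$pattern) ==
                prof$truth[match(calls$gene_id, rownames(prof$log2fc))])
  expect_gte(acc, 0.9)
})

test_that("profile clustering groups by shape with deterministic labels", {
  set.seed(53)
  up <- c(0, 3, 3, 3); down <- -up
  m <- rbind(a = up, b = up, c = down, d = down + rnorm(4, sd = 0.01))
  cl <- clusterProfiles(m, k = 2)
  expect_equal(cl$labels[["a"]], cl$labels[["b"]])
  expect_true(cl$labels[["a"]] != cl$labels[["c"]])
  ## k = n gives singletons
  cl_n <- clusterProfiles(m, k = 4)
  expect_equal(sort(unname(cl_n$labels)), 1:4)
  ## constant profile assigned by Euclidean fallback and flagged
  m2 <- rbind(m, flat = c(0, 0, 0, 0))
  cl2 <- clusterProfiles(m2, k = 2)
  expect_true(cl2$fallback[["flat"]])
  expect_true(cl2$labels[["flat"]] %in% 1:2)
  ## planted four shapes + noise: >= 90% label purity
  ph <- assignPhases(seq(0, 36, by = 6), "t")
  prof <- generatePatternProfiles(50, 3, 0.2, ph)
  cl4 <- clusterProfiles(prof$log2fc, k = 4)
  expect_gte(permuted_accuracy(unname(cl4$labels), prof$truth), 0.9)
})
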