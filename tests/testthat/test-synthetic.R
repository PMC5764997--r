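small_cfg <- function(seed = 5, ...) {
  generatorConfig(seed = seed, n_genes = 120L, n_ortholog_groups = 20L,
                  n_common_de = 4L,
                  pattern_counts = c(EU = 8L, ED = 8L, LU = 8L, LD = 8L),
                  n_accessions = 600L, ...)
}

test_that("the reference universe has exact proportions and is seeded", {
  cfg <- generatorConfig(n_accessions = 100L,
                         taxon_props = c(human = 0.5, mouse = 0.2,
                                         other = 0.2, bacteria = 0.1))
  u <- generateReferenceUniverse(cfg)
  expect_equal(sum(u$species == "human"), 50L)
  expect_equal(generateReferenceUniverse(cfg), u)   # determinism
  cfg0 <- generatorConfig(n_accessions = 0L)
  expect_equal(nrow(generateReferenceUniverse(cfg0)), 0L)
})

test_that("hit tables plant recoverable ortholog groups and pass filters", {
  cfg <- small_cfg()
  u <- generateReferenceUniverse(cfg)
  ht <- generateHitTables(cfg, u)
  expect_equal(names(ht$hits), cfg@species)
  ## identical under the same seed
  expect_equal(generateHitTables(cfg, u)$hits$hydra, ht$hits$hydra)
  ## fixtures pass the reader/validator contract
  for (sp in cfg@species) expect_silent(validateHitTable(ht$hits[[sp]]))
  ## bacterial hits exist and are removed by the eukaryote filter
  expect_gt(sum(ht$hits$hydra$subject_taxon == "Bacteria"), 0)
  kept <- filterHits(ht$hits$hydra, 1e-15, "Eukaryota")
  expect_equal(sum(kept$subject_taxon == "Bacteria"), 0L)
  ## too many groups -> configuration error
  expect_error(
    generateHitTables(generatorConfig(n_genes = 10L,
                                      n_ortholog_groups = 20L,
                                      n_common_de = 0L,
                                      pattern_counts = c(EU = 0L, ED = 0L,
                                                         LU = 0L, LD = 0L)),
                      u),
    "ortholog")
})

test_that("planted expression pulses have the configured population shape", {
  cfg <- small_cfg()
  tc <- generateTimecourseCounts(cfg)
  expect_equal(generateTimecourseCounts(cfg)$counts$hydra,
               tc$counts$hydra)   # determinism
  m <- SummarizedExperiment::assay(tc$counts$hydra, "counts")
  lab <- tc$truth$pattern[tc$truth$species == "hydra"]
  ph <- defaultPhaseSpec("hydra", timePoints(tc$counts$hydra))
  eu <- m[lab == "EU", , drop = FALSE]
  ## EU genes: ~ 2^3-fold above baseline on early indices, recovered later
  expect_gt(mean(eu[, ph@early]) / mean(eu[, 1]), 4)
  expect_lt(abs(log2(mean(eu[, ph@recovery]) / mean(eu[, 1]))), 0.5)
  ld <- m[lab == "LD", , drop = FALSE]
  expect_lt(mean(ld[, ncol(ld)]) / mean(ld[, 1]), 0.3)
  ## fixture round-trips through the writer/reader
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCounts(tc$counts$seacucumber, f)
  back <- readCounts(f, species = "seacucumber")
  expect_equal(SummarizedExperiment::assay(back),
               SummarizedExperiment::assay(tc$counts$seacucumber))
})

test_that("signature fixtures encode their overlap truths by construction", {
  cfg <- small_cfg()
  u <- generateReferenceUniverse(cfg)
  sig <- generateSignatureFixture(cfg, u)
  expect_equal(sharedMembers(sig$source_lists, k = 3),
               sig$truth$shared_all)
  expect_setequal(sharedMembers(sig$source_lists, k = 2),
                  c(sig$truth$shared_all, sig$truth$shared_two))
  cons <- consensusSignature(sig$consensus_groups,
                             c(murine = 2, human = 3))
  expect_equal(cons@members, sig$truth$consensus)
  expect_equal(generateSignatureFixture(cfg, u)$source_lists,
               sig$source_lists)   # determinism
})

test_that("a fixture directory round-trips through readers and config", {
  cfg <- small_cfg()
  d <- withr::local_tempdir()
  fx <- generateFixture(cfg, d)
  expect_true(file.exists(fx$paths$config))
  expect_true(file.exists(fx$paths$truth))
  rc <- validateConfig(fx$paths$config)
  expect_s4_class(rc, "RunConfig")
  expect_equal(sort(names(rc@species)), sort(cfg@species))
  ## the hydra-like species carries the reduced fold-change cutoff
  expect_equal(rc@species$hydra$de@fc_threshold, 0.5)
  h <- readHitTable(fx$paths$hits_hydra)
  expect_gt(nrow(h), 0)
})
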