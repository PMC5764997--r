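test_that("hit filtering keeps at the cutoff and drops non-allowed taxa", {
  h <- make_hits(query_id = c("t1", "t1", "t1"),
                 subject_acc = c("P1", "P2", "P3"),
                 subject_taxon = c("Eukaryota", "Eukaryota", "Bacteria"),
                 sig_value = c(1e-16, 1e-14, 1e-60))
  out <- filterHits(h, 1e-15, "Eukaryota")
  expect_equal(out$subject_acc, "P1")       # 1e-16 kept (<=), 1e-14 dropped,
                                            # bacterial dropped despite sig
  expect_error(filterHits(h, 1e-15, character()), "allow-list")
  ## order preserved
  h2 <- make_hits(query_id = c("t1", "t2", "t3"),
                  subject_acc = c("Pz", "Pa", "Pm"))
  expect_equal(filterHits(h2, 1e-15)$subject_acc, c("Pz", "Pa", "Pm"))
})

test_that("greedy clustering partitions transcripts as exact-alignment says", {
  set.seed(11)
  base <- random_dna(1, 300)
  seqs <- c(A = base, B = base, C = random_dna(1, 300))
  cl <- clusterTranscripts(seqs, identity_threshold = 0.8)
  got <- lapply(cl@members, sort)
  expect_equal(sort(unname(vapply(got, paste, character(1),
                                  collapse = "+"))),
               sort(c("A+B", "C")))
  ## independent oracle: exact pairwise alignment identity via Biostrings
  pid <- function(a, b) {
    al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                        Biostrings::DNAString(b))
    Biostrings::pid(al) / 100
  }
  expect_gte(pid(seqs["A"], seqs["B"]), 0.8)
  expect_lt(pid(seqs["A"], seqs["C"]), 0.8)

  ## zero shared 8-mers -> singletons
  s2 <- c(x = strrep("A", 50), y = strrep("C", 50))
  expect_equal(length(clusterTranscripts(s2)), 2L)

  ## partition property on random input
  set.seed(12)
  rs <- random_dna(30, 120)
  names(rs) <- sprintf("t%02d", 1:30)
  cl2 <- clusterTranscripts(rs)
  expect_setequal(unlist(cl2@members), names(rs))
  expect_false(anyDuplicated(unlist(cl2@members)) > 0)
  ## representative is a member
  expect_true(all(mapply(function(m, r) r %in% m,
                         cl2@members, cl2@representatives)))

  expect_error(clusterTranscripts(c(a = "ACGTX")), "non-nucleotide")
})

test_that("per-gene hit aggregation averages over hitting members only", {
  h <- make_hits(query_id = c("t1", "t2", "t1"),
                 subject_acc = c("P1", "P1", "P2"),
                 bit_score = c(100, 200, 80),
                 sig_value = c(1e-20, 1e-30, 1e-18))
  s <- aggregateGeneHits(c("t1", "t2"), h)
  expect_equal(s$avg_score[s$subject_acc == "P1"], 150)
  ## only one of two members hits P2: average is 80, not 40
  expect_equal(s$avg_score[s$subject_acc == "P2"], 80)
  ## no hits -> empty summary
  expect_equal(nrow(aggregateGeneHits("absent", h)), 0L)
  ## invariance under duplicated hit rows
  expect_equal(aggregateGeneHits(c("t1", "t2"), rbind(h, h[1, ])), s)
})

test_that("human best match maximizes score, ties broken by significance", {
  s <- data.frame(subject_acc = c("P1", "P2", "P3"),
                  subject_species = c("human", "human", "mouse"),
                  avg_score = c(100, 90, 200),
                  avg_sig = c(1e-30, 1e-40, 1e-50))
  expect_equal(humanBestMatch(s)$acc, "P1")   # mouse P3 ignored
  expect_null(humanBestMatch(s[s$subject_species == "mouse", ]))
  s$avg_score <- c(100, 100, 200)
  expect_equal(humanBestMatch(s)$acc, "P2")   # score tie -> lower sig
  s$avg_sig <- c(1e-30, 1e-30, 1)
  expect_equal(humanBestMatch(s)$acc, "P1")   # full tie -> lexicographic
})

test_that("list-match annotation collects subjects under the strict cutoff", {
  s <- data.frame(subject_acc = c("P1", "P2", "P3"),
                  subject_species = "human",
                  avg_score = c(1, 2, 3),
                  avg_sig = c(1e-20, 1e-16, 1e-10))
  expect_equal(listMatchAnnotation(s, 1e-15), c("P1", "P2"))
  expect_equal(listMatchAnnotation(s[0, ], 1e-15), character())
  expect_equal(listMatchAnnotation(s, 1), c("P1", "P2", "P3"))
})

test_that("gene annotation combines clustering, best match and list match", {
  h <- make_hits(query_id = c("t1", "t2", "t3", "t3"),
                 subject_acc = c("HUM1", "HUM1", "EUK1", "HUM2"),
                 subject_species = c("human", "human", "other", "human"),
                 bit_score = c(100, 200, 50, 60),
                 sig_value = c(1e-30, 1e-30, 1e-20, 1e-10))
  cl <- clustersFromMap(data.frame(
    transcript_id = c("t1", "t2", "t3"),
    gene_id = c("gA", "gA", "gB")))
  ann <- annotateGenes(h, cl)
  expect_equal(ann$best_match_acc, c("HUM1", "HUM2"))
  expect_equal(ann$best_match_score, c(150, 60))
  ## gB's best match HUM2 has sig 1e-10 > 1e-15: in best match, not in list
  expect_equal(as.list(ann$list_match), list(gA = "HUM1", gB = "EUK1"))
  ## best match is in the list whenever its sig clears the list cutoff
  ok <- is.na(ann$best_match_acc) | ann$best_match_sig > 1e-15 |
    mapply(function(a, l) a %in% l, ann$best_match_acc,
           as.list(ann$list_match))
  expect_true(all(ok))
  ## identity clustering when no clusters given
  ann2 <- annotateGenes(h)
  expect_equal(ann2$gene_id, c("t1", "t2", "t3"))
  ## diagnostic
  d <- hitCountDiagnostic(ann)
  expect_equal(unname(d$per_gene), c(1L, 2L))
})
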