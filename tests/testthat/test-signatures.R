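test_that("consensus signatures honour per-group support thresholds", {
  murine <- list(m1 = c("Marco", "Sgk1"), m2 = c("Marco", "Tgfb"),
                 m3 = "Aldh6a1", m4 = "Tgfb")
  human <- list(h1 = c("MMP9", "CD14"), h2 = "MMP9", h3 = "MMP9",
                h4 = "CD14", h5 = "CALM", h6 = "X1", h7 = "X2", h8 = "X3")
  sig <- consensusSignature(list(murine = murine, human = human),
                            c(murine = 2, human = 3))
  expect_true(all(c("Marco", "Tgfb", "MMP9") %in% sig@members))
  expect_false("CD14" %in% sig@members)   # 2 of 8 human < 3
  expect_false("Sgk1" %in% sig@members)   # 1 of 4 murine < 2
  ## thresholds of 1 -> plain union
  u <- consensusSignature(list(murine = murine), c(murine = 1))
  expect_setequal(u@members, c("Marco", "Sgk1", "Tgfb", "Aldh6a1"))
  ## thresholds = group size -> intersection
  i <- consensusSignature(list(g = list(a = c("A", "B"), b = c("B", "C"))),
                          c(g = 2))
  expect_equal(i@members, "B")
  expect_error(consensusSignature(list(murine = murine), c(murine = 5)),
               "between 1 and 4")
})

test_that("shared members count lists case-insensitively", {
  lists <- list(a = c("MARCO", "MRC1"), b = c("Marco", "CSF1R"),
                c = c("marco", "MRC1"))
  expect_equal(sharedMembers(lists, k = 3), "MARCO")
  expect_setequal(sharedMembers(lists, k = 2), c("MARCO", "MRC1"))
  expect_equal(sharedMembers(lists, k = 4), character())
  expect_equal(sharedMembers(list(a = "A", b = "B", c = "C"), k = 2),
               character())
})

test_that("signature matrices flag absence, presence and DE per mode", {
  ann <- list(
    sp1 = S4Vectors::DataFrame(
      gene_id = c("g1", "g2"),
      best_match_acc = c("MARCO", NA),
      best_match_score = 100, best_match_sig = 1e-30, n_subjects = 2L,
      list_match = IRanges::CharacterList(list(c("MARCO", "MMP9"),
                                               "MMP8"))),
    sp2 = S4Vectors::DataFrame(
      gene_id = "h1", best_match_acc = "MMP9",
      best_match_score = 90, best_match_sig = 1e-20, n_subjects = 1L,
      list_match = IRanges::CharacterList(list("MMP9"))))
  de <- list(sp1 = "g1", sp2 = character())
  sig <- c("MARCO", "MMP8", "MMP9", "ABSENT1")
  best <- matchSignature(sig, ann, de, mode = "best")
  expect_equal(as.character(best$sp1),
               c("de", "absent", "absent", "absent"))
  expect_equal(as.character(best$sp2),
               c("absent", "absent", "present", "absent"))
  lst <- matchSignature(sig, ann, de, mode = "list")
  expect_equal(as.character(lst$sp1),
               c("de", "present", "de", "absent"))
  ## de implies present; best-mode presence implies list-mode presence here
  expect_true(all(lst$sp1[best$sp1 != "absent"] != "absent"))
})

test_that("reciprocal best hits require mutual top-scoring passing hits", {
  ab <- make_hits(query_id = c("a1", "a1", "a2", "a3"),
                  subject_acc = c("b1", "b2", "b2", "b3"),
                  bit_score = c(300, 200, 250, 100),
                  query_coverage = c(0.6, 0.6, 0.6, 0.2),
                  identity_frac = c(0.8, 0.8, 0.8, 0.8))
  ba <- make_hits(query_id = c("b1", "b2", "b3"),
                  subject_acc = c("a1", "a9", "a3"),
                  bit_score = c(280, 260, 90),
                  query_coverage = c(0.7, 0.7, 0.7),
                  identity_frac = c(0.9, 0.9, 0.9))
  rbh <- reciprocalOrthologs(ab, ba, 0.4, 0.6)
  ## a1<->b1 mutual top; a2->b2 but b2->a9 (one-way); a3 fails coverage
  expect_equal(rbh, data.frame(gene_a = "a1", gene_b = "b1",
                               stringsAsFactors = FALSE))
  ## symmetric under swapping the tables
  rbh_rev <- reciprocalOrthologs(ba, ab, 0.4, 0.6)
  expect_equal(rbh_rev$gene_a, rbh$gene_b)
  expect_equal(rbh_rev$gene_b, rbh$gene_a)
  ## missing coverage/identity columns -> instructive error
  expect_error(reciprocalOrthologs(make_hits("a", "b"), ba),
               "query_coverage")
})

test_that("planted reciprocal pairs are recovered exactly among decoys", {
  set.seed(61)
  n_pairs <- 40
  pa <- sprintf("pa%03d", 1:n_pairs)
  pb <- sprintf("pb%03d", 1:n_pairs)
  ab <- make_hits(query_id = pa, subject_acc = pb,
                  bit_score = runif(n_pairs, 200, 300),
                  query_coverage = runif(n_pairs, 0.5, 0.9),
                  identity_frac = runif(n_pairs, 0.7, 0.9))
  ba <- make_hits(query_id = pb, subject_acc = pa,
                  bit_score = runif(n_pairs, 200, 300),
                  query_coverage = runif(n_pairs, 0.5, 0.9),
                  identity_frac = runif(n_pairs, 0.7, 0.9))
  ## 100 one-way decoys: a-side queries whose targets never hit back
  decoys <- make_hits(query_id = sprintf("da%03d", 1:100),
                      subject_acc = sprintf("db%03d", 1:100),
                      bit_score = runif(100, 200, 300),
                      query_coverage = runif(100, 0.5, 0.9),
                      identity_frac = runif(100, 0.7, 0.9))
  rbh <- reciprocalOrthologs(rbind(ab, decoys), ba, 0.4, 0.6)
  expect_equal(nrow(rbh), n_pairs)
  expect_setequal(rbh$gene_a, pa)
  ## the threshold scan is monotone: stricter cutoffs keep no extra pairs
  scan <- rbhThresholdScan(rbind(ab, decoys), ba,
                           coverages = c(0.3, 0.5), identities = c(0.5, 0.7))
  strictest <- scan$n_pairs[scan$min_coverage == 0.5 &
                              scan$min_identity == 0.7]
  loosest <- scan$n_pairs[scan$min_coverage == 0.3 &
                            scan$min_identity == 0.5]
  expect_lte(strictest, loosest)
})
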