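## minimal best-match annotation tables
best_ann <- function(gene_ids, best) {
  S4Vectors::DataFrame(gene_id = gene_ids, best_match_acc = best,
                       best_match_score = 100, best_match_sig = 1e-30,
                       n_subjects = 1L,
                       list_match = IRanges::CharacterList(
                         lapply(best, function(b)
                           if (is.na(b)) character() else b)))
}

test_that("best-match co-annotation links genes sharing an accession", {
  ann <- list(
    hm = best_ann(c("h1", "h2"), c("CALM", NA)),
    sm = best_ann(c("s1", "s2"), c("CALM", "OTHER")),
    aj = best_ann("a1", "CALM"))
  map <- coannotateBest(ann)
  expect_equal(map@accession_species$CALM, c("hm", "sm", "aj"))
  ## h2 has no best match: no link involving it
  expect_false("h2" %in% c(map@pairs$gene_a, map@pairs$gene_b))
  ## three species pairing on CALM -> 3 pairwise links
  expect_equal(sum(map@pairs$accession == "CALM"), 3L)
  expect_error(coannotateBest(ann[1]), "two species")
})

test_that("list-match co-annotation uses strict overlap over the smaller list", {
  p <- sprintf("p%d", 1:10)
  ann_a <- make_list_annotation(c("a1", "a2", "a3"),
                                list(p[1:5], p[1:5], p[1:4]))
  ann_b <- make_list_annotation(c("b1", "b2", "b3"),
                                list(p[1:5],            # identical: 1.0
                                     c(p[1:4], p[6]),   # 4/5 = 0.8 exactly
                                     p[1:10]))          # superset of a3
  map <- coannotateList(ann_a, ann_b, 0.8)
  links <- paste(map@pairs$gene_a, map@pairs$gene_b)
  expect_true("a1 b1" %in% links)
  expect_false("a1 b2" %in% links)   # "more than 80%" is strict
  expect_true("a3 b3" %in% links)    # subset counts as full sharing
  ## symmetry: swapping inputs yields the mirrored link set
  rev_map <- coannotateList(ann_b, ann_a, 0.8)
  expect_setequal(paste(rev_map@pairs$gene_b, rev_map@pairs$gene_a), links)
})

test_that("lowering the overlap threshold never removes a list-match link", {
  set.seed(21)
  univ <- sprintf("p%02d", 1:30)
  ann_a <- make_list_annotation(sprintf("a%d", 1:15),
                                replicate(15, sample(univ, sample(3:8, 1)),
                                          simplify = FALSE))
  ann_b <- make_list_annotation(sprintf("b%d", 1:15),
                                replicate(15, sample(univ, sample(3:8, 1)),
                                          simplify = FALSE))
  prev <- NULL
  for (thr in c(0.9, 0.7, 0.5, 0.3)) {
    m <- coannotateList(ann_a, ann_b, thr)
    links <- paste(m@pairs$gene_a, m@pairs$gene_b)
    if (!is.null(prev)) expect_true(all(prev %in% links))
    prev <- links
  }
})

test_that("venn regions are disjoint, exhaustive and match brute force", {
  sets <- list(hm = c("A", "B"), sm = c("B", "C"), aj = "B")
  v <- vennCounts(sets)
  expect_equal(v$count[v$subset == "hm&sm&aj"], 1L)  # B
  expect_equal(v$count[v$subset == "hm"], 1L)        # A
  expect_equal(v$count[v$subset == "sm"], 1L)        # C
  expect_equal(sum(v$count), 3L)                     # |union|

  ## brute-force oracle over random sets
  set.seed(31)
  for (rep in 1:5) {
    rs <- list(x = sample(LETTERS, 10), y = sample(LETTERS, 8),
               z = sample(LETTERS, 12))
    v <- vennCounts(rs)
    uni <- unique(unlist(rs))
    for (i in seq_len(nrow(v))) {
      inc <- strsplit(v$subset[i], "&", fixed = TRUE)[[1]]
      exc <- setdiff(names(rs), inc)
      n <- sum(vapply(uni, function(a)
        all(vapply(rs[inc], function(s) a %in% s, logical(1))) &&
          !any(vapply(rs[exc], function(s) a %in% s, logical(1))),
        logical(1)))
      expect_equal(v$count[i], n)
    }
    expect_equal(sum(v$count), length(uni))
  }

  ## identical sets: only the all-species region
  vi <- vennCounts(list(a = c("P1", "P2"), b = c("P1", "P2"),
                        c = c("P1", "P2")))
  expect_equal(vi$count[vi$subset == "a&b&c"], 2L)
  expect_equal(sum(vi$count), 2L)
  ## disjoint sets: only singleton regions
  vd <- vennCounts(list(a = "P1", b = "P2", c = "P3"))
  expect_equal(vd$count[vd$n_species == 1], c(1L, 1L, 1L))
  expect_equal(sum(vd$count[vd$n_species > 1]), 0L)
})

test_that("co-annotated-and-DE intersection requires DE in every species", {
  ann <- list(hm = c("CALM", "CANX"), sm = c("CALM", "CANX"),
              aj = c("CALM", "CANX"))
  de2 <- list(hm = "CALM", sm = "CALM", aj = "CANX")
  expect_equal(intersectDE(ann, de2), character())   # DE in 2 of 3
  de3 <- list(hm = c("CALM", "X"), sm = "CALM", aj = "CALM")
  expect_equal(intersectDE(ann, de3), "CALM")
  expect_error(intersectDE(ann, de3[1:2]), "same species")
})
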