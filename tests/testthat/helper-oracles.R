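## Independent oracles and small fixture builders shared across test files.

## ---- NB exact-test oracle -------------------------------------------------
## Hand-coded log-gamma NB pmf (variance mu + phi mu^2), independent of
## stats::dnbinom, and a literal enumeration of the conditional two-sided
## p-value given the total.
oracle_nb_pmf <- function(k, mu, phi) {
  if (mu == 0) return(as.numeric(k == 0))
  if (phi == 0) return(exp(-mu + k * log(mu) - lfactorial(k)))
  r <- 1 / phi
  exp(lgamma(k + r) - lgamma(r) - lfactorial(k) +
        r * log(r / (r + mu)) + k * log(mu / (r + mu)))
}

oracle_exact_test <- function(a, b, phi) {
  s <- a + b
  if (s == 0) return(1)
  mu <- s / 2
  probs <- vapply(0:s, function(k)
    oracle_nb_pmf(k, mu, phi) * oracle_nb_pmf(s - k, mu, phi), numeric(1))
  obs <- probs[a + 1]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]) / sum(probs))
}

## ---- BH step-up oracle ----------------------------------------------------
## Literal min-over-j evaluation of the step-up formula.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj_sorted <- numeric(m)
  for (i in seq_len(m))
    adj_sorted[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

## ---- small fixture builders ----------------------------------------------
make_hits <- function(query_id, subject_acc,
                      subject_taxon = "Eukaryota",
                      subject_species = "human",
                      bit_score = 100, sig_value = 1e-30,
                      query_coverage = NA_real_,
                      identity_frac = NA_real_) {
  data.frame(query_id = query_id, subject_acc = subject_acc,
             subject_taxon = subject_taxon,
             subject_species = subject_species,
             bit_score = bit_score, sig_value = sig_value,
             query_coverage = query_coverage,
             identity_frac = identity_frac,
             stringsAsFactors = FALSE)
}

make_tce <- function(counts, time_h = seq(0, by = 6,
                                          length.out = ncol(counts)),
                     species = "test") {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  TimeCourseExperiment(counts, time_h = time_h, species = species)
}

## annotation table with only the fields list-match co-annotation consumes
make_list_annotation <- function(gene_ids, lists) {
  S4Vectors::DataFrame(gene_id = gene_ids,
                       best_match_acc = NA_character_,
                       best_match_score = NA_real_,
                       best_match_sig = NA_real_,
                       n_subjects = lengths(lists),
                       list_match = IRanges::CharacterList(lists))
}

## best-permutation label accuracy for unsupervised cluster labels
permuted_accuracy <- function(labels, truth) {
  truth_f <- factor(truth)
  labs <- sort(unique(labels))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- 0
  for (p in perms(levels(truth_f))) {
    mapped <- p[match(labels, labs)]
    best <- max(best, mean(mapped == truth))
  }
  best
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}
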