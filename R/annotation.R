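## Gene-level annotation from alignment hits: taxon/significance filtering,
## greedy transcript clustering (CD-HIT-like, fixture grade), per-gene hit
## aggregation, human best-match selection and list-match annotation.

#' Filter alignment hits by significance and taxon
#'
#' Drops hits to taxa outside the allow-list (e.g. non-eukaryotic sequences)
#' and hits whose significance value exceeds the cutoff. Retention is
#' inclusive at the threshold (`sig_value <= sig_threshold` is kept); input
#' order is preserved.
#'
#' @param hits a hit table (see [readHitTable()]).
#' @param sig_threshold positive significance cutoff; hits above it are
#'   discarded (default `1e-15`, the strict annotation cutoff).
#' @param taxon_allow non-empty character vector of allowed `subject_taxon`
#'   labels (default `"Eukaryota"`).
#' @return the retained rows of `hits`.
#' @examples
#' h <- data.frame(query_id = "t1", subject_acc = c("P1", "P2", "P3"),
#'                 subject_taxon = c("Eukaryota", "Eukaryota", "Bacteria"),
#'                 subject_species = "human",
#'                 bit_score = c(200, 90, 300),
#'                 sig_value = c(1e-16, 1e-14, 1e-60))
#' filterHits(h)  # keeps only P1
#' @export
filterHits <- function(hits, sig_threshold = 1e-15,
                       taxon_allow = "Eukaryota") {
  if (!length(taxon_allow))
    stop("taxon allow-list must not be empty")
  if (length(sig_threshold) != 1L || !is.finite(sig_threshold) ||
      sig_threshold <= 0)
    stop("sig_threshold must be a single positive number")
  hits <- validateHitTable(hits)
  keep <- hits$sig_value <= sig_threshold &
    hits$subject_taxon %in% taxon_allow
  hits[keep, , drop = FALSE]
}

## unique k-mers of one sequence; sequences shorter than the word are
## represented by themselves so exact short duplicates still cluster
.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(s)
  unique(substring(s, seq_len(n - k + 1L), k:n))
}

#' Greedy transcript clustering at an identity threshold
#'
#' A small, self-contained greedy longest-first clusterer in the CD-HIT
#' style, intended for collapsing near-identical transcripts to gene units
#' at fixture scale. Sequences are sorted by decreasing length (ties by id);
#' each sequence joins the first existing cluster whose representative
#' shares at least `identity_threshold` of its unique k-mers (a containment
#' estimate of identity), otherwise it founds a new cluster with itself as
#' representative. Production-scale runs should inject an external cluster
#' map instead (see [annotateGenes()]).
#'
#' @param sequences named character vector of nucleotide sequences over
#'   `A,C,G,T,N`; names are transcript ids.
#' @param identity_threshold fraction in (0, 1], default 0.8.
#' @param word_size k-mer length for the containment estimate (default 8).
#' @return a [GeneClusterSet-class]; clusters partition the input.
#' @export
clusterTranscripts <- function(sequences, identity_threshold = 0.8,
                               word_size = 8L) {
  if (!length(sequences))
    return(methods::new("GeneClusterSet", members = list(),
                        representatives = character()))
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named by transcript id")
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]")
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("non-nucleotide symbol in sequence(s): ",
         paste(utils::head(names(sequences)[bad], 5), collapse = ", "))
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  reps <- character()        # representative transcript ids
  rep_kmers <- list()        # their k-mer sets
  members <- list()
  for (i in seq_along(sequences)) {
    id <- names(sequences)[i]
    km <- .kmers(sequences[[i]], word_size)
    placed <- FALSE
    for (j in seq_along(reps)) {
      est <- sum(km %in% rep_kmers[[j]]) / max(1L, length(km))
      if (est >= identity_threshold) {
        members[[j]] <- c(members[[j]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      rep_kmers[[length(reps)]] <- km
      members[[length(reps)]] <- id
    }
  }
  names(members) <- sprintf("gene_%05d", seq_along(members))
  names(reps) <- names(members)
  methods::new("GeneClusterSet", members = members, representatives = reps)
}

#' Build a GeneClusterSet from an external transcript-to-gene map
#'
#' Injects clustering produced by an external tool. The representative of
#' each gene is its lexicographically smallest transcript.
#'
#' @param map data.frame with columns `transcript_id` and `gene_id`.
#' @return a [GeneClusterSet-class].
#' @export
clustersFromMap <- function(map) {
  stopifnot(all(c("transcript_id", "gene_id") %in% names(map)))
  if (anyDuplicated(map$transcript_id))
    stop("a transcript may belong to only one gene")
  members <- split(map$transcript_id, map$gene_id)
  members <- members[order(names(members))]
  reps <- vapply(members, function(m) sort(m)[1L], character(1))
  methods::new("GeneClusterSet", members = members, representatives = reps)
}

#' Aggregate the hits of one gene's member transcripts per subject
#'
#' For each subject accession hit by at least one member transcript, the
#' average bit score and average significance over the member transcripts
#' that hit it (members without a hit to that subject contribute nothing,
#' not zeros). Multiple hit rows of the same transcript against the same
#' subject are collapsed first (best score, lowest significance), so the
#' result is invariant under duplication of hit rows.
#'
#' @param member_ids character vector of the gene's transcript ids.
#' @param hits a filtered hit table.
#' @param mean_type `"arithmetic"` (default) or `"geometric"` averaging of
#'   significance values; scores are always averaged arithmetically.
#' @return data.frame with one row per subject: `subject_acc`,
#'   `subject_species`, `avg_score`, `avg_sig`, `n_members`.
#' @export
aggregateGeneHits <- function(member_ids, hits,
                              mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  h <- hits[hits$query_id %in% member_ids, , drop = FALSE]
  if (!nrow(h))
    return(data.frame(subject_acc = character(),
                      subject_species = character(),
                      avg_score = numeric(), avg_sig = numeric(),
                      n_members = integer(), stringsAsFactors = FALSE))
  ## collapse per (transcript, subject): keep the best hit
  key <- paste(h$query_id, h$subject_acc, sep = "\r")
  ord <- order(key, -h$bit_score, h$sig_value)
  h <- h[ord, , drop = FALSE]
  h <- h[!duplicated(key[ord]), , drop = FALSE]
  sig_mean <- if (mean_type == "arithmetic") {
    function(x) mean(x)
  } else {
    function(x) exp(mean(log(x)))
  }
  acc <- sort(unique(h$subject_acc))
  idx <- split(seq_len(nrow(h)), factor(h$subject_acc, levels = acc))
  data.frame(
    subject_acc = acc,
    subject_species = vapply(idx, function(i) h$subject_species[i[1]],
                             character(1)),
    avg_score = vapply(idx, function(i) mean(h$bit_score[i]), numeric(1)),
    avg_sig = vapply(idx, function(i) sig_mean(h$sig_value[i]), numeric(1)),
    n_members = vapply(idx, function(i) length(unique(h$query_id[i])),
                       integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the human best match from a per-subject hit summary
#'
#' Restricts the summary to subjects of the reference species and picks the
#' accession with the maximal average bit score, breaking ties by lower
#' average significance and then by lexicographically smaller accession.
#'
#' @param summary output of [aggregateGeneHits()].
#' @param human_species species tag of the reference (default `"human"`).
#' @return list with `acc`, `score`, `sig`, or `NULL` when the gene has no
#'   hit to the reference species.
#' @export
humanBestMatch <- function(summary, human_species = "human") {
  s <- summary[summary$subject_species == human_species, , drop = FALSE]
  if (!nrow(s)) return(NULL)
  ord <- order(-s$avg_score, s$avg_sig, s$subject_acc)
  best <- s[ord[1L], ]
  list(acc = best$subject_acc, score = best$avg_score, sig = best$avg_sig)
}

#' List-match annotation of a gene
#'
#' The full set of subject accessions (any species) whose average
#' significance clears the strict cutoff (`avg_sig <= sig_threshold`);
#' this broader shared annotation underlies cross-species list-match
#' co-annotation.
#'
#' @param summary output of [aggregateGeneHits()].
#' @param sig_threshold positive cutoff (default `1e-15`).
#' @return sorted character vector of accessions (possibly empty).
#' @export
listMatchAnnotation <- function(summary, sig_threshold = 1e-15) {
  if (sig_threshold <= 0) stop("sig_threshold must be positive")
  sort(summary$subject_acc[summary$avg_sig <= sig_threshold])
}

#' Annotate a species' genes from a filtered hit table
#'
#' Runs the full per-gene annotation: member hits are aggregated per subject,
#' the human best match selected, and the list-match set computed at the
#' strict significance cutoff. When no clustering is supplied every
#' transcript is its own gene.
#'
#' @param hits a hit table, already passed through [filterHits()].
#' @param clusters a [GeneClusterSet-class], or `NULL` for the identity
#'   clustering over the query ids present in `hits`.
#' @param list_sig_threshold strict cutoff for list-match membership
#'   (default `1e-15`).
#' @param human_species reference species tag (default `"human"`).
#' @param mean_type significance averaging, see [aggregateGeneHits()].
#' @return a [S4Vectors::DataFrame-class] with one row per gene:
#'   `gene_id`, `best_match_acc` (`NA` if none), `best_match_score`,
#'   `best_match_sig`, `n_subjects`, and `list_match`
#'   (an [IRanges::CharacterList-class]).
#' @export
annotateGenes <- function(hits, clusters = NULL,
                          list_sig_threshold = 1e-15,
                          human_species = "human",
                          mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  hits <- validateHitTable(hits)
  if (is.null(clusters)) {
    ids <- sort(unique(hits$query_id))
    members <- as.list(ids)
    names(members) <- ids
    clusters <- methods::new("GeneClusterSet", members = members,
                             representatives = stats::setNames(ids, ids))
  }
  stopifnot(methods::is(clusters, "GeneClusterSet"))
  gene_ids <- names(clusters@members)
  n <- length(gene_ids)
  ## assign each hit row to its gene once, instead of scanning per gene
  tx2gene <- stats::setNames(
    rep(gene_ids, lengths(clusters@members)),
    unlist(clusters@members, use.names = FALSE))
  hit_gene <- tx2gene[hits$query_id]
  row_by_gene <- split(seq_len(nrow(hits)),
                       factor(hit_gene, levels = gene_ids))
  best_acc <- rep(NA_character_, n)
  best_score <- rep(NA_real_, n)
  best_sig <- rep(NA_real_, n)
  n_subj <- integer(n)
  lm <- vector("list", n)
  for (i in seq_len(n)) {
    summ <- aggregateGeneHits(
      clusters@members[[i]],
      hits[row_by_gene[[i]], , drop = FALSE],
      mean_type = mean_type)
    n_subj[i] <- nrow(summ)
    bm <- humanBestMatch(summ, human_species = human_species)
    if (!is.null(bm)) {
      best_acc[i] <- bm$acc
      best_score[i] <- bm$score
      best_sig[i] <- bm$sig
    }
    lm[[i]] <- listMatchAnnotation(summ, sig_threshold = list_sig_threshold)
  }
  S4Vectors::DataFrame(
    gene_id = gene_ids,
    best_match_acc = best_acc,
    best_match_score = best_score,
    best_match_sig = best_sig,
    n_subjects = n_subj,
    list_match = IRanges::CharacterList(stats::setNames(lm, gene_ids)))
}

#' Hits-per-gene diagnostic
#'
#' Summary of the per-gene annotation breadth (number of distinct subjects
#' hit). Transcriptome-scale annotation typically averages around 15 subject
#' hits per gene; this diagnostic lets users compare their data, it asserts
#' nothing.
#'
#' @param annotation output of [annotateGenes()].
#' @return named list with `per_gene` (integer vector), `mean` and `median`.
#' @export
hitCountDiagnostic <- function(annotation) {
  per_gene <- stats::setNames(annotation$n_subjects, annotation$gene_id)
  list(per_gene = per_gene, mean = mean(per_gene),
       median = stats::median(per_gene))
}

#' Serialize an annotation table to a plain data.frame
#'
#' Flattens the `list_match` column to a semicolon-joined string, for TSV
#' output.
#'
#' @param annotation output of [annotateGenes()].
#' @return a base data.frame.
#' @export
annotationAsTable <- function(annotation) {
  data.frame(
    gene_id = annotation$gene_id,
    best_match_acc = annotation$best_match_acc,
    best_match_score = annotation$best_match_score,
    best_match_sig = annotation$best_match_sig,
    n_subjects = annotation$n_subjects,
    list_match = vapply(as.list(annotation$list_match),
                        paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
}
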