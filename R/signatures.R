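## Immune / EMT gene-signature handling: consensus signatures from
## per-dataset DE lists, shared members across source lists, presence/DE
## matrices against species annotations, and reciprocal-best-hit ortholog
## filtering for annotation-free correspondence.

## gene symbols mix species casing conventions (MARCO vs Mrc1); matching is
## case-insensitive after whitespace stripping
normalizeSymbol <- function(x) toupper(trimws(x))

#' SignatureSet: a named set of signature accessions with provenance
#'
#' @slot name signature name (e.g. `"EMT"`).
#' @slot members unique accessions (original casing of first occurrence).
#' @slot provenance data.frame `accession, group, support` recording, per
#'   accession, the source group and the number of source lists containing
#'   it.
#'
#' @seealso [consensusSignature()], [sharedMembers()]
#' @export
setClass("SignatureSet",
         representation(name = "character", members = "character",
                        provenance = "data.frame"))

setMethod("show", "SignatureSet", function(object) {
  cat(sprintf("SignatureSet '%s': %d members from %d source group(s)\n",
              object@name, length(object@members),
              length(unique(object@provenance$group))))
  invisible(NULL)
})

setMethod("length", "SignatureSet", function(x) length(x@members))

#' Consensus signature from grouped per-dataset DE lists
#'
#' An accession enters the signature iff the number of lists containing it
#' within its group meets that group's support threshold (e.g. DE in at
#' least 2 of 4 murine datasets OR at least 3 of 8 human datasets); the
#' union over groups is returned with provenance. Thresholds of 1
#' everywhere reduce to the plain union; thresholds equal to the group
#' sizes to the group-wise intersection.
#'
#' @param groups named list of groups; each group is a list of per-dataset
#'   accession vectors.
#' @param min_support named integer vector, one threshold per group, each
#'   between 1 and its group's list count.
#' @param name signature name.
#' @return a [SignatureSet-class].
#' @export
consensusSignature <- function(groups, min_support, name = "signature") {
  if (is.null(names(groups)) || !all(names(groups) %in% names(min_support)))
    stop("groups and min_support must be named consistently")
  prov <- list()
  for (g in names(groups)) {
    lists <- groups[[g]]
    thr <- min_support[[g]]
    if (thr < 1 || thr > length(lists))
      stop(sprintf(
        "min_support for group '%s' must be between 1 and %d (got %g)",
        g, length(lists), thr))
    norm_lists <- lapply(lists, function(l) unique(normalizeSymbol(l)))
    support <- table(unlist(norm_lists, use.names = FALSE))
    keep <- names(support)[support >= thr]
    if (length(keep)) {
      ## recover first-seen original casing
      originals <- unlist(lists, use.names = FALSE)
      first <- originals[!duplicated(normalizeSymbol(originals))]
      names(first) <- normalizeSymbol(first)
      prov[[g]] <- data.frame(accession = unname(first[keep]), group = g,
                              support = as.integer(support[keep]),
                              stringsAsFactors = FALSE)
    }
  }
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(accession = character(), group = character(),
               support = integer(), stringsAsFactors = FALSE)
  prov <- prov[order(prov$group, prov$accession), , drop = FALSE]
  rownames(prov) <- NULL
  members <- prov$accession[!duplicated(normalizeSymbol(prov$accession))]
  methods::new("SignatureSet", name = name, members = sort(members),
               provenance = prov)
}

#' Accessions shared by at least k source lists
#'
#' Case-insensitive after symbol normalization; the first-seen casing is
#' reported.
#'
#' @param lists named list of accession vectors.
#' @param k minimum number of lists an accession must appear in (>= 1).
#' @return sorted character vector.
#' @export
sharedMembers <- function(lists, k = 2L) {
  if (k < 1L) stop("k must be >= 1")
  norm_lists <- lapply(lists, function(l) unique(normalizeSymbol(l)))
  support <- table(unlist(norm_lists, use.names = FALSE))
  keep <- names(support)[support >= k]
  originals <- unlist(lists, use.names = FALSE)
  first <- originals[!duplicated(normalizeSymbol(originals))]
  names(first) <- normalizeSymbol(first)
  sort(unname(first[keep]))
}

#' Presence/DE matrix of a signature across species annotations
#'
#' For each signature accession and species, records whether the accession
#' is reachable through the species' annotation and whether any gene
#' carrying it is DE. In `best` mode an accession is present iff some
#' gene's best-match accession equals it; in `list` mode iff it occurs in
#' some gene's list-match annotation. The DE flag is set iff at least one
#' matching gene is DE (the permissive reading: any carrier suffices).
#' Matching is case-insensitive.
#'
#' @param signature a [SignatureSet-class] or character vector of
#'   accessions.
#' @param annotations named list (by species) of [annotateGenes()] outputs.
#' @param de_genes named list (by species) of DE gene-id vectors (e.g. from
#'   [deGenes()]).
#' @param mode `"best"` or `"list"`.
#' @return data.frame: `accession`, then one factor column per species with
#'   levels `absent < present < de`.
#' @export
matchSignature <- function(signature, annotations, de_genes,
                           mode = c("best", "list")) {
  mode <- match.arg(mode)
  members <- if (methods::is(signature, "SignatureSet"))
    signature@members else signature
  if (!setequal(names(annotations), names(de_genes)))
    stop("annotations and de_genes must cover the same species")
  norm_members <- normalizeSymbol(members)
  out <- data.frame(accession = members, stringsAsFactors = FALSE)
  for (sp in names(annotations)) {
    ann <- annotations[[sp]]
    de <- de_genes[[sp]]
    if (mode == "best") {
      acc <- normalizeSymbol(ann$best_match_acc)
      carriers <- lapply(norm_members, function(a)
        ann$gene_id[!is.na(acc) & acc == a])
    } else {
      lm <- lapply(as.list(ann$list_match), normalizeSymbol)
      carriers <- lapply(norm_members, function(a)
        ann$gene_id[vapply(lm, function(l) a %in% l, logical(1))])
    }
    status <- vapply(carriers, function(g) {
      if (!length(g)) "absent"
      else if (any(g %in% de)) "de"
      else "present"
    }, character(1))
    out[[sp]] <- factor(status, levels = c("absent", "present", "de"))
  }
  out
}

## top passing hit per query: highest bit score, ties by lower sig then
## lexicographic subject
.topHits <- function(hits, min_coverage, min_identity) {
  if (!all(c("query_coverage", "identity_frac") %in% names(hits)) ||
      all(is.na(hits$query_coverage)) || all(is.na(hits$identity_frac)))
    stop("reciprocal ortholog filtering needs query_coverage and ",
         "identity_frac columns; supply them in the hit tables")
  pass <- !is.na(hits$query_coverage) & !is.na(hits$identity_frac) &
    hits$query_coverage >= min_coverage & hits$identity_frac >= min_identity
  h <- hits[pass, , drop = FALSE]
  if (!nrow(h)) return(character())
  ord <- order(h$query_id, -h$bit_score, h$sig_value, h$subject_acc)
  h <- h[ord, , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  stats::setNames(h$subject_acc, h$query_id)
}

#' Reciprocal-best-hit ortholog pairs between two species
#'
#' Retains gene pairs `(g_a, g_b)` such that a hit `a -> b` and a hit
#' `b -> a` both pass the coverage and identity thresholds, and each is its
#' query's top-scoring passing hit in its direction. Used to detect
#' correspondence between transcriptomes regardless of reference-database
#' annotation. The output is symmetric under swapping the two tables (the
#' columns swap accordingly).
#'
#' @param hits_ab hit table of species A transcripts against species B
#'   (`query_id` = A gene, `subject_acc` = B gene).
#' @param hits_ba the reverse direction.
#' @param min_coverage,min_identity thresholds in (0, 1]; defaults 0.4 and
#'   0.6 (the midpoints of the ranges typically scanned, see
#'   [rbhThresholdScan()]).
#' @return data.frame `gene_a, gene_b`, sorted by `gene_a`.
#' @export
reciprocalOrthologs <- function(hits_ab, hits_ba,
                                min_coverage = 0.4, min_identity = 0.6) {
  stopifnot(min_coverage > 0, min_coverage <= 1,
            min_identity > 0, min_identity <= 1)
  top_ab <- .topHits(hits_ab, min_coverage, min_identity)
  top_ba <- .topHits(hits_ba, min_coverage, min_identity)
  ga <- names(top_ab)
  gb <- unname(top_ab)
  mutual <- !is.na(top_ba[gb]) & top_ba[gb] == ga
  mutual[is.na(mutual)] <- FALSE
  out <- data.frame(gene_a = ga[mutual], gene_b = gb[mutual],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan reciprocal-best-hit thresholds over a grid
#'
#' Reports the number of reciprocal pairs at each combination of coverage
#' and identity thresholds, as a sensitivity diagnostic over the ranges
#' commonly applied to cross-transcriptome alignment (30-50% coverage,
#' 50-70% identity).
#'
#' @param hits_ab,hits_ba see [reciprocalOrthologs()].
#' @param coverages,identities numeric grids of thresholds.
#' @return data.frame `min_coverage, min_identity, n_pairs`.
#' @export
rbhThresholdScan <- function(hits_ab, hits_ba,
                             coverages = c(0.3, 0.4, 0.5),
                             identities = c(0.5, 0.6, 0.7)) {
  grid <- expand.grid(min_coverage = coverages, min_identity = identities)
  grid$n_pairs <- vapply(seq_len(nrow(grid)), function(i)
    nrow(reciprocalOrthologs(hits_ab, hits_ba, grid$min_coverage[i],
                             grid$min_identity[i])), integer(1))
  grid
}
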