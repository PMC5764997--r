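## Cross-species gene correspondence through shared reference-database
## annotation: best-match equality, list-match overlap, multi-species
## Venn region counts, and the co-annotated-and-DE intersection.

#' CoAnnotationMap: cross-species correspondence via shared annotation
#'
#' Links between genes of different species established through shared
#' reference hits, in one of two modes: `best_match` (genes linked iff their
#' human best-match accessions are identical) or `list_match` (genes linked
#' iff their list-match annotations overlap above a threshold fraction;
#' many-to-many links are kept).
#'
#' @slot mode `"best_match"` or `"list_match"`.
#' @slot species the species tags involved.
#' @slot pairs data.frame of orientation-free links
#'   (`species_a, gene_a, species_b, gene_b`, plus `accession` in best mode
#'   and `overlap` in list mode), each link recorded once with
#'   `species_a < species_b`.
#' @slot accession_species named list: for best mode, accession ->
#'   character vector of species carrying it.
#' @slot annotated named list: per species, the set of annotated accessions
#'   (best mode) or annotated gene ids (list mode).
#'
#' @seealso [coannotateBest()], [coannotateList()], [vennCounts()]
#' @export
setClass("CoAnnotationMap",
         representation(mode = "character", species = "character",
                        pairs = "data.frame", accession_species = "list",
                        annotated = "list"))

setMethod("show", "CoAnnotationMap", function(object) {
  cat(sprintf("CoAnnotationMap (%s) over species: %s\n", object@mode,
              paste(object@species, collapse = ", ")))
  cat(sprintf("  %d cross-species links\n", nrow(object@pairs)))
  if (object@mode == "best_match") {
    k <- length(object@species)
    n_all <- sum(vapply(object@accession_species, length, integer(1)) == k)
    cat(sprintf("  %d accessions shared by all %d species\n", n_all, k))
  }
  invisible(NULL)
})

#' Co-annotate species by best-match equality
#'
#' Genes from different species are linked iff both have a human best-match
#' accession and the accessions are identical. Also exposes, per accession,
#' the tuple of species carrying it, which feeds [vennCounts()].
#'
#' @param annotations named list (by species tag) of [annotateGenes()]
#'   outputs; at least two species.
#' @return a [CoAnnotationMap-class] in `best_match` mode.
#' @export
coannotateBest <- function(annotations) {
  if (length(annotations) < 2L)
    stop("co-annotation needs at least two species")
  if (is.null(names(annotations)) || any(!nzchar(names(annotations))))
    stop("annotations must be named by species tag")
  species <- names(annotations)
  ## per species: accession -> gene ids carrying it as best match
  by_acc <- lapply(annotations, function(a) {
    keep <- !is.na(a$best_match_acc)
    split(a$gene_id[keep], a$best_match_acc[keep])
  })
  annotated <- lapply(by_acc, names)
  all_acc <- sort(unique(unlist(annotated, use.names = FALSE)))
  acc_species <- lapply(all_acc, function(acc)
    species[vapply(by_acc, function(x) acc %in% names(x), logical(1))])
  names(acc_species) <- all_acc
  pairs <- list()
  for (i in seq_along(species)) for (j in seq_along(species)) {
    if (i >= j) next
    shared <- intersect(annotated[[i]], annotated[[j]])
    for (acc in shared) {
      ga <- by_acc[[i]][[acc]]
      gb <- by_acc[[j]][[acc]]
      grid <- expand.grid(gene_a = ga, gene_b = gb,
                          stringsAsFactors = FALSE)
      if (nrow(grid))
        pairs[[length(pairs) + 1L]] <- data.frame(
          species_a = species[i], gene_a = grid$gene_a,
          species_b = species[j], gene_b = grid$gene_b,
          accession = acc, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(species_a = character(), gene_a = character(),
               species_b = character(), gene_b = character(),
               accession = character(), stringsAsFactors = FALSE)
  methods::new("CoAnnotationMap", mode = "best_match", species = species,
               pairs = pairs, accession_species = acc_species,
               annotated = annotated)
}

#' Co-annotate two species by list-match overlap
#'
#' Genes `g_a`, `g_b` (both with non-empty list-match annotation) are linked
#' iff their shared fraction exceeds the threshold strictly:
#' `|L_a n L_b| / min(|L_a|, |L_b|) > overlap_threshold` (default
#' denominator), so an overlap of exactly 0.8 at the default threshold is
#' NOT a link. With `denominator = "both"` the fraction must exceed the
#' threshold relative to each list's own size. Links are symmetric and
#' many-to-many links are kept.
#'
#' @param ann_a,ann_b [annotateGenes()] outputs for the two species.
#' @param overlap_threshold fraction in (0, 1], default 0.8.
#' @param species_a,species_b species tags for the output.
#' @param denominator `"min"` (default) or `"both"`.
#' @return a [CoAnnotationMap-class] in `list_match` mode; `pairs` carries
#'   the achieved `overlap` fraction.
#' @export
coannotateList <- function(ann_a, ann_b, overlap_threshold = 0.8,
                           species_a = "species_a", species_b = "species_b",
                           denominator = c("min", "both")) {
  denominator <- match.arg(denominator)
  if (overlap_threshold <= 0 || overlap_threshold > 1)
    stop("overlap_threshold must be in (0, 1]")
  la <- as.list(ann_a$list_match)
  lb <- as.list(ann_b$list_match)
  names(la) <- ann_a$gene_id
  names(lb) <- ann_b$gene_id
  la <- la[lengths(la) > 0L]
  lb <- lb[lengths(lb) > 0L]
  ## inverted index over species b accessions
  idx_b <- split(rep(names(lb), lengths(lb)), unlist(lb, use.names = FALSE))
  out <- list()
  for (ga in names(la)) {
    cand <- unique(unlist(idx_b[la[[ga]]], use.names = FALSE))
    for (gb in cand) {
      inter <- length(intersect(la[[ga]], lb[[gb]]))
      denom <- if (denominator == "min")
        min(length(la[[ga]]), length(lb[[gb]]))
      else max(length(la[[ga]]), length(lb[[gb]]))
      ov <- inter / denom
      if (ov > overlap_threshold)
        out[[length(out) + 1L]] <- data.frame(
          species_a = species_a, gene_a = ga,
          species_b = species_b, gene_b = gb,
          overlap = ov, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(species_a = character(), gene_a = character(),
               species_b = character(), gene_b = character(),
               overlap = numeric(), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  methods::new("CoAnnotationMap", mode = "list_match",
               species = c(species_a, species_b), pairs = pairs,
               accession_species = list(),
               annotated = stats::setNames(list(names(la), names(lb)),
                                           c(species_a, species_b)))
}

#' Venn region counts over per-species accession sets
#'
#' For every non-empty subset of species, the number of accessions carried
#' by exactly that subset. Regions are disjoint and sum to the size of the
#' union.
#'
#' @param sets named list of per-species character vectors (e.g. the
#'   `annotated` slot of a best-match [CoAnnotationMap-class]), or the map
#'   itself.
#' @return data.frame with one row per non-empty species subset: `subset`
#'   (species tags joined by `&`), `n_species`, `count`.
#' @export
vennCounts <- function(sets) {
  if (methods::is(sets, "CoAnnotationMap")) {
    if (sets@mode != "best_match")
      stop("venn counts require a best-match co-annotation map")
    sets <- sets@annotated
  }
  if (length(sets) < 2L) stop("venn counts need >= 2 species")
  species <- names(sets)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  key <- apply(membership, 1L, function(r)
    paste(species[r], collapse = "&"))
  counts <- table(key)
  ## enumerate all non-empty subsets so empty regions appear with count 0
  subsets <- unlist(lapply(seq_along(species), function(k)
    utils::combn(species, k, paste, collapse = "&", simplify = FALSE)),
    recursive = FALSE)
  data.frame(
    subset = unlist(subsets),
    n_species = vapply(strsplit(unlist(subsets), "&", fixed = TRUE),
                       length, integer(1)),
    count = as.integer(vapply(unlist(subsets), function(s)
      if (s %in% names(counts)) counts[[s]] else 0L, numeric(1))),
    stringsAsFactors = FALSE)
}

#' Accessions co-annotated and differentially expressed in every species
#'
#' @param annotated_sets named list of per-species annotated accession sets
#'   (or a best-match [CoAnnotationMap-class]).
#' @param de_sets named list of per-species DE accession sets, same species.
#' @return sorted character vector of accessions present in every species'
#'   annotation and every species' DE set.
#' @export
intersectDE <- function(annotated_sets, de_sets) {
  if (methods::is(annotated_sets, "CoAnnotationMap"))
    annotated_sets <- annotated_sets@annotated
  if (!setequal(names(annotated_sets), names(de_sets)))
    stop("annotated_sets and de_sets must cover the same species")
  sort(Reduce(intersect, c(unname(annotated_sets), unname(de_sets))))
}
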