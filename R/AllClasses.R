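#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData
#' @importFrom IRanges CharacterList
NULL

#' TimeCourseExperiment: a replicate-free regeneration time course
#'
#' A container for one species' regeneration time course: a genes x time-points
#' matrix of raw counts, the sampling times in hours post injury (the first
#' time point is the pre-/immediately-post-injury baseline), a species tag and
#' optional per-gene transcript lengths (used for rpkm-based expression
#' filtering). Extends
#' [SummarizedExperiment::SummarizedExperiment-class], so all the usual
#' subsetting and accessor machinery applies.
#'
#' Validity requires a `"counts"` assay of non-negative integer-valued counts,
#' strictly increasing `time_h` in `colData`, and unique gene identifiers.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment-class]; the
#'   time grid lives in `colData(x)$time_h` and the species tag in
#'   `metadata(x)$species`.
#'
#' @seealso [TimeCourseExperiment()], [timePoints()], [speciesTag()]
#' @export
setClass("TimeCourseExperiment", contains = "SummarizedExperiment")

setValidity("TimeCourseExperiment", function(object) {
  msg <- NULL
  if (!"counts" %in% names(SummarizedExperiment::assays(object)))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(is.na(m)))
    msg <- c(msg, "counts contain NA")
  else {
    if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(m != round(m))) msg <- c(msg, "counts must be integer-valued")
  }
  tp <- SummarizedExperiment::colData(object)$time_h
  if (is.null(tp))
    msg <- c(msg, "colData must contain a 'time_h' column")
  else {
    if (any(is.na(tp)) || is.unsorted(tp, strictly = TRUE))
      msg <- c(msg, "time_h must be strictly increasing")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers (rownames) must be present and unique")
  sp <- S4Vectors::metadata(object)$species
  if (!is.character(sp) || length(sp) != 1L)
    msg <- c(msg, "metadata$species must be a single character tag")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TimeCourseExperiment
#'
#' @param counts integer matrix, genes x time points; rownames are gene ids.
#' @param time_h numeric vector of sampling times in hours post injury,
#'   strictly increasing; the first entry is the baseline.
#' @param species single character species tag (e.g. `"hydra"`).
#' @param gene_length_bp optional numeric vector of per-gene transcript
#'   lengths in bp, used for rpkm filtering; recycled against genes by name
#'   or position.
#'
#' @return A [TimeCourseExperiment-class] object.
#' @examples
#' m <- matrix(rpois(12, 50), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), NULL))
#' tce <- TimeCourseExperiment(m, time_h = c(0, 6, 12, 24), species = "demo")
#' timePoints(tce)
#' @export
TimeCourseExperiment <- function(counts, time_h, species,
                                 gene_length_bp = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "numeric"
  if (length(time_h) != ncol(counts))
    stop("length(time_h) must equal ncol(counts)")
  cd <- S4Vectors::DataFrame(time_h = as.numeric(time_h))
  rownames(cd) <- sprintf("t%gh", time_h)
  colnames(counts) <- rownames(cd)
  rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(gene_length_bp)) {
    if (!is.null(names(gene_length_bp)))
      gene_length_bp <- gene_length_bp[rownames(counts)]
    rd$gene_length_bp <- as.numeric(gene_length_bp)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(counts = counts),
    colData = cd, rowData = rd,
    metadata = list(species = as.character(species)))
  methods::new("TimeCourseExperiment", se)
}

#' @describeIn TimeCourseExperiment sampling times in hours post injury.
#' @param x a `TimeCourseExperiment`.
#' @export
timePoints <- function(x) {
  stopifnot(methods::is(x, "TimeCourseExperiment"))
  SummarizedExperiment::colData(x)$time_h
}

#' @describeIn TimeCourseExperiment the species tag.
#' @export
speciesTag <- function(x) {
  stopifnot(methods::is(x, "TimeCourseExperiment"))
  S4Vectors::metadata(x)$species
}

#' @describeIn TimeCourseExperiment per-gene transcript lengths (bp) or NULL.
#' @export
geneLengths <- function(x) {
  stopifnot(methods::is(x, "TimeCourseExperiment"))
  SummarizedExperiment::rowData(x)$gene_length_bp
}

setMethod("show", "TimeCourseExperiment", function(object) {
  cat(sprintf("TimeCourseExperiment for species '%s'\n", speciesTag(object)))
  cat(sprintf("  %d genes x %d time points (%s h post injury)\n",
              nrow(object), ncol(object),
              paste(timePoints(object), collapse = ", ")))
  invisible(methods::callNextMethod())
})

#' GeneClusterSet: transcripts collapsed to gene units
#'
#' The partition of a species' transcript universe into gene units obtained by
#' greedy similarity clustering (or injected from an external cluster map).
#' Each cluster has a stable `gene_id`, a non-empty member set and a
#' representative member.
#'
#' @slot members named list; each element is the character vector of member
#'   transcript ids of one cluster, named by `gene_id`.
#' @slot representatives named character vector, one representative transcript
#'   per cluster, parallel to `members`.
#'
#' @seealso [clusterTranscripts()], [clusterMap()]
#' @export
setClass("GeneClusterSet",
         representation(members = "list", representatives = "character"))

setValidity("GeneClusterSet", function(object) {
  msg <- NULL
  if (length(object@members) != length(object@representatives))
    return("members and representatives lengths differ")
  if (length(object@members)) {
    if (is.null(names(object@members)) ||
        !identical(names(object@members), names(object@representatives)))
      msg <- c(msg, "members and representatives must share gene_id names")
    all_tx <- unlist(object@members, use.names = FALSE)
    if (anyDuplicated(all_tx))
      msg <- c(msg, "clusters must partition the transcripts (duplicate member)")
    ok_rep <- mapply(function(m, r) r %in% m,
                     object@members, object@representatives)
    if (!all(ok_rep))
      msg <- c(msg, "each representative must be a member of its cluster")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn GeneClusterSet a `data.frame` with columns `transcript_id`,
#'   `gene_id`, `representative_id` (one row per transcript).
#' @param x a `GeneClusterSet`.
#' @export
clusterMap <- function(x) {
  stopifnot(methods::is(x, "GeneClusterSet"))
  n <- lengths(x@members)
  data.frame(
    transcript_id = unlist(x@members, use.names = FALSE),
    gene_id = rep(names(x@members), n),
    representative_id = rep(unname(x@representatives), n),
    stringsAsFactors = FALSE)
}

setMethod("show", "GeneClusterSet", function(object) {
  n <- length(object@members)
  cat(sprintf("GeneClusterSet: %d gene clusters over %d transcripts\n",
              n, sum(lengths(object@members))))
  if (n) {
    sz <- lengths(object@members)
    cat(sprintf("  cluster sizes: min %d, median %g, max %d\n",
                min(sz), stats::median(sz), max(sz)))
  }
  invisible(NULL)
})

setMethod("length", "GeneClusterSet", function(x) length(x@members))

#' DEConfig: thresholds for replicate-free differential expression
#'
#' Bundles the tunables of the time-course differential-expression step:
#' the absolute log2 fold-change cutoff (default 2; regeneration studies of
#' species with compressed dynamic range, such as hydra, use 0.5), the
#' BH-adjusted p-value cutoff (0.05), the expression filter (a gene must
#' exceed 20 raw counts, or 1 rpkm when transcript lengths are available, in
#' at least one time point), the fixed negative-binomial dispersion phi used
#' by the exact test, and the pseudocount added to normalized counts before
#' taking log2.
#'
#' @slot fc_threshold numeric(1), strict cutoff on |log2FC|.
#' @slot alpha numeric(1), strict cutoff on the BH-adjusted p-value.
#' @slot min_count numeric(1), raw-count expression filter ("more than").
#' @slot min_rpkm numeric(1), rpkm expression filter ("more than").
#' @slot dispersion numeric(1), NB dispersion phi (variance = mu + phi mu^2).
#' @slot pseudocount numeric(1), added before log2.
#'
#' @seealso [deConfig()], [runDE()]
#' @export
setClass("DEConfig",
         representation(fc_threshold = "numeric", alpha = "numeric",
                        min_count = "numeric", min_rpkm = "numeric",
                        dispersion = "numeric", pseudocount = "numeric"),
         prototype(fc_threshold = 2, alpha = 0.05, min_count = 20,
                   min_rpkm = 1, dispersion = 0.1, pseudocount = 0.5))

setValidity("DEConfig", function(object) {
  msg <- NULL
  for (s in c("fc_threshold", "alpha", "min_count", "min_rpkm", "pseudocount"))
    if (length(methods::slot(object, s)) != 1L || methods::slot(object, s) <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", s))
  if (length(object@dispersion) != 1L || object@dispersion < 0)
    msg <- c(msg, "dispersion must be a single number >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a DEConfig
#'
#' @param fc_threshold strict |log2FC| cutoff (default 2).
#' @param alpha strict adjusted-p cutoff (default 0.05).
#' @param min_count raw-count expression filter, "more than" (default 20).
#' @param min_rpkm rpkm expression filter, "more than" (default 1).
#' @param dispersion fixed NB dispersion phi (default 0.1).
#' @param pseudocount pseudocount before log2 (default 0.5).
#' @return A [DEConfig-class] object.
#' @examples
#' deConfig()                      # defaults
#' deConfig(fc_threshold = 0.5)    # hydra-style cutoff
#' @export
deConfig <- function(fc_threshold = 2, alpha = 0.05, min_count = 20,
                     min_rpkm = 1, dispersion = 0.1, pseudocount = 0.5) {
  methods::new("DEConfig", fc_threshold = fc_threshold, alpha = alpha,
               min_count = min_count, min_rpkm = min_rpkm,
               dispersion = dispersion, pseudocount = pseudocount)
}

setMethod("show", "DEConfig", function(object) {
  cat(sprintf(paste0(
    "DEConfig: |log2FC| > %g, adjusted p < %g\n",
    "  expression filter: > %g counts or > %g rpkm in >= 1 time point\n",
    "  NB dispersion phi = %g, pseudocount = %g\n"),
    object@fc_threshold, object@alpha, object@min_count, object@min_rpkm,
    object@dispersion, object@pseudocount))
  invisible(NULL)
})

#' PhaseSpec: early/late phase and recovery time point of a time course
#'
#' Indices into the time-point vector (baseline included at index 1) marking
#' the early regeneration phase, the late phase, and the recovery time point
#' at which transiently deregulated genes must have returned near baseline.
#'
#' @slot species species tag.
#' @slot early integer indices of the early-phase time points.
#' @slot late integer indices of the late-phase time points.
#' @slot recovery integer(1), index of the recovery time point.
#'
#' @seealso [assignPhases()], [classifyPattern()]
#' @export
setClass("PhaseSpec",
         representation(species = "character", early = "integer",
                        late = "integer", recovery = "integer"))

setValidity("PhaseSpec", function(object) {
  msg <- NULL
  if (!length(object@early)) msg <- c(msg, "early phase must be non-empty")
  if (!length(object@late)) msg <- c(msg, "late phase must be non-empty")
  if (length(intersect(object@early, object@late)))
    msg <- c(msg, "early and late phases must be disjoint")
  if (length(object@recovery) != 1L)
    msg <- c(msg, "recovery must be a single index")
  else if (length(object@early) && object@recovery < max(object@early))
    msg <- c(msg, "recovery index must be >= max(early indices)")
  if (any(c(object@early, object@late) < 2L))
    msg <- c(msg, "phase indices must exclude the baseline (index 1)")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "PhaseSpec", function(object) {
  cat(sprintf(
    "PhaseSpec [%s]: early indices {%s}, late {%s}, recovery at index %d\n",
    object@species, paste(object@early, collapse = ","),
    paste(object@late, collapse = ","), object@recovery))
  invisible(NULL)
})
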