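## Configuration-driven orchestration: YAML validation into a RunConfig,
## then annotate -> DE -> temporal -> co-annotate -> signatures with
## stderr logging, TSV outputs and a JSON run manifest.

#' RunConfig: a validated pipeline configuration
#'
#' @slot seed integer-valued seed recorded in the manifest.
#' @slot base_dir directory against which relative input paths resolve.
#' @slot out_dir output directory.
#' @slot config_path the YAML file the config was read from.
#' @slot thresholds list: `permissive_sig` (1e-2), `strict_sig` (1e-15),
#'   `identity` (0.8), `overlap` (0.8).
#' @slot taxon_allow allowed subject taxa (default `"Eukaryota"`).
#' @slot species named list of per-species entries (`hits`, `counts`,
#'   `time_unit`, optional `cluster_map`, optional `de` and `phases`
#'   overrides).
#' @slot signatures named list of signature list file paths.
#'
#' @seealso [validateConfig()], [runPipeline()]
#' @export
setClass("RunConfig",
         representation(seed = "numeric", base_dir = "character",
                        out_dir = "character", config_path = "character",
                        thresholds = "list", taxon_allow = "character",
                        species = "list", signatures = "list"))

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(paste0(
    "RunConfig (seed %g): %d species [%s], %d signature list(s)\n",
    "  strict sig %g, permissive %g, identity %g, overlap %g\n",
    "  output: %s\n"),
    object@seed, length(object@species),
    paste(names(object@species), collapse = ", "),
    length(object@signatures),
    object@thresholds$strict_sig, object@thresholds$permissive_sig,
    object@thresholds$identity, object@thresholds$overlap,
    object@out_dir))
  invisible(NULL)
})

.checkKeys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")))
}

.checkRange <- function(v, lo, hi, name) {
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= lo || v > hi)
    stop(sprintf("threshold '%s' must lie in (%g, %g]; got %s",
                 name, lo, hi, paste(v, collapse = ",")))
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML run configuration, rejects unknown keys at every level,
#' range-checks thresholds, fills documented defaults (strict significance
#' 1e-15, permissive 1e-2, 80% identity and overlap, the standard DE
#' thresholds) and verifies every referenced input path exists.
#'
#' @param path path to the YAML file.
#' @return a [RunConfig-class].
#' @export
validateConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  .checkKeys(raw, c("seed", "out_dir", "thresholds", "taxon_allow",
                    "species", "signatures"), "config")
  thr <- raw$thresholds
  .checkKeys(thr, c("permissive_sig", "strict_sig", "identity", "overlap"),
             "thresholds")
  thr <- utils::modifyList(
    list(permissive_sig = 1e-2, strict_sig = 1e-15,
         identity = 0.8, overlap = 0.8),
    if (is.null(thr)) list() else thr)
  .checkRange(thr$permissive_sig, 0, 1, "permissive_sig")
  .checkRange(thr$strict_sig, 0, 1, "strict_sig")
  .checkRange(thr$identity, 0, 1, "identity")
  .checkRange(thr$overlap, 0, 1, "overlap")
  if (is.null(raw$species) || !length(raw$species))
    stop("config must declare at least one species")
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    full <- if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
    if (!file.exists(full)) stop("referenced input does not exist: ", p)
    full
  }
  species <- list()
  for (sp in names(raw$species)) {
    entry <- raw$species[[sp]]
    .checkKeys(entry, c("hits", "counts", "time_unit", "cluster_map",
                        "de", "phases"),
               sprintf("species '%s'", sp))
    if (is.null(entry$hits) || is.null(entry$counts))
      stop(sprintf("species '%s' needs both 'hits' and 'counts'", sp))
    entry$hits <- resolve(entry$hits)
    entry$counts <- resolve(entry$counts)
    if (!is.null(entry$cluster_map))
      entry$cluster_map <- resolve(entry$cluster_map)
    entry$time_unit <- if (is.null(entry$time_unit)) "hours"
    else match.arg(entry$time_unit, c("hours", "days"))
    .checkKeys(entry$de, c("fc_threshold", "alpha", "min_count", "min_rpkm",
                           "dispersion", "pseudocount"),
               sprintf("species '%s' de", sp))
    entry$de <- do.call(deConfig,
                        if (is.null(entry$de)) list() else entry$de)
    .checkKeys(entry$phases, c("early", "late", "recovery_h", "recovery"),
               sprintf("species '%s' phases", sp))
    if (is.null(entry$phases)) entry$phases <- list()
    species[[sp]] <- entry
  }
  sigs <- if (is.null(raw$signatures)) list() else
    lapply(raw$signatures, resolve)
  methods::new("RunConfig",
               seed = if (is.null(raw$seed)) 1 else as.numeric(raw$seed),
               base_dir = base_dir,
               out_dir = if (is.null(raw$out_dir)) "results" else raw$out_dir,
               config_path = normalizePath(path),
               thresholds = thr,
               taxon_allow = if (is.null(raw$taxon_allow)) "Eukaryota"
               else unlist(raw$taxon_allow),
               species = species, signatures = sigs)
}

.log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[xregen] ", fmt), ...))
}

.stage <- function(name, quiet, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  .log(quiet, "stage %-12s done in %.1fs", name,
       proc.time()[["elapsed"]] - t0)
  res
}

#' Run the full cross-species analysis pipeline
#'
#' Executes, in dependency order: per-species annotation (strict hit
#' filtering, optional external clustering, best-match and list-match
#' annotation), replicate-free DE, temporal pattern classification,
#' cross-species co-annotation (best-match groups, Venn region counts, the
#' co-annotated-and-DE intersection, and pairwise list-match links;
#' skipped with a logged notice for a single species), and signature
#' matching (presence/DE matrices in both modes over the union of the
#' configured signature lists). Every stage's table is written as TSV to
#' the output directory together with a JSON manifest (config hash, seed,
#' row counts); logs go to stderr, and a rerun on identical inputs is
#' byte-identical.
#'
#' @param config a [RunConfig-class] from [validateConfig()], or the path
#'   to a YAML configuration.
#' @param out_dir output directory override (default: the config's
#'   `out_dir`, resolved against its base directory).
#' @param quiet suppress progress logging.
#' @return (invisibly) list with `manifest`, `tables` and the intermediate
#'   objects (`annotations`, `de`, `patterns`, `coannotation`).
#' @export
runPipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- validateConfig(config)
  stopifnot(methods::is(config, "RunConfig"))
  if (is.null(out_dir))
    out_dir <- if (grepl("^(/|[A-Za-z]:)", config@out_dir)) config@out_dir
    else file.path(config@base_dir, config@out_dir)
  set.seed(config@seed)
  species <- names(config@species)
  tables <- list()
  ## --- annotation ------------------------------------------------------
  annotations <- list()
  counts <- list()
  for (sp in species) {
    entry <- config@species[[sp]]
    annotations[[sp]] <- .stage(paste0("annotate:", sp), quiet, {
      hits <- readHitTable(entry$hits)
      hits <- filterHits(hits, config@thresholds$strict_sig,
                         config@taxon_allow)
      clusters <- if (!is.null(entry$cluster_map))
        clustersFromMap(utils::read.delim(entry$cluster_map,
                                          stringsAsFactors = FALSE))
      else NULL
      annotateGenes(hits, clusters,
                    list_sig_threshold = config@thresholds$strict_sig)
    })
    counts[[sp]] <- .stage(paste0("read_counts:", sp), quiet,
                           readCounts(entry$counts, species = sp,
                                      time_unit = entry$time_unit))
    tables[[paste0("annotation_", sp)]] <-
      annotationAsTable(annotations[[sp]])
  }
  ## --- differential expression ----------------------------------------
  de <- list()
  for (sp in species) {
    de[[sp]] <- .stage(paste0("de:", sp), quiet,
                       runDE(counts[[sp]], config@species[[sp]]$de))
    tables[[paste0("de_", sp)]] <- deResults(de[[sp]])
  }
  ## --- temporal patterns ----------------------------------------------
  patterns <- list()
  for (sp in species) {
    patterns[[sp]] <- .stage(paste0("temporal:", sp), quiet, {
      ph_args <- config@species[[sp]]$phases
      phases <- do.call(assignPhases,
                        c(list(time_points_h = timePoints(counts[[sp]]),
                               species = sp), ph_args))
      classifyPatterns(de[[sp]], phases)
    })
    tables[[paste0("patterns_", sp)]] <- patterns[[sp]]
  }
  ## --- co-annotation ---------------------------------------------------
  coann <- NULL
  if (length(species) >= 2L) {
    coann <- .stage("coannotate", quiet, {
      best <- coannotateBest(annotations)
      de_acc <- lapply(species, function(sp) {
        a <- annotations[[sp]]
        unique(a$best_match_acc[!is.na(a$best_match_acc) &
                                  a$gene_id %in% deGenes(de[[sp]])])
      })
      names(de_acc) <- species
      list_pairs <- list()
      for (i in seq_along(species)) for (j in seq_along(species)) {
        if (i >= j) next
        lp <- coannotateList(annotations[[species[i]]],
                             annotations[[species[j]]],
                             overlap_threshold = config@thresholds$overlap,
                             species_a = species[i],
                             species_b = species[j])
        list_pairs[[length(list_pairs) + 1L]] <- lp@pairs
      }
      list(best = best, venn = vennCounts(best),
           common_de = intersectDE(best, de_acc),
           list_pairs = do.call(rbind, list_pairs))
    })
    tables$coannotation_best_pairs <- coann$best@pairs
    tables$venn_counts <- coann$venn
    tables$common_de <- data.frame(accession = coann$common_de,
                                   stringsAsFactors = FALSE)
    tables$coannotation_list_pairs <- coann$list_pairs
  } else {
    .log(quiet, "single species: co-annotation stage skipped")
  }
  ## --- signatures -------------------------------------------------------
  if (length(config@signatures)) {
    sig_tabs <- .stage("signatures", quiet, {
      lists <- lapply(config@signatures, readGeneList)
      members <- sort(unique(normalizeSymbol(
        unlist(lists, use.names = FALSE))))
      de_genes <- lapply(de, deGenes)
      list(best = matchSignature(members, annotations, de_genes, "best"),
           list = matchSignature(members, annotations, de_genes, "list"),
           shared = data.frame(
             accession = sharedMembers(lists, k = length(lists)),
             stringsAsFactors = FALSE))
    })
    tables$signature_matrix_best <- sig_tabs$best
    tables$signature_matrix_list <- sig_tabs$list
    tables$signature_shared_all <- sig_tabs$shared
  }
  ## --- report -----------------------------------------------------------
  tables$stage_summary <- data.frame(
    species = species,
    n_genes = vapply(counts, nrow, integer(1)),
    n_filtered = vapply(de, function(d) nrow(d@log2fc), integer(1)),
    n_de = vapply(de, function(d) length(deGenes(d)), integer(1)),
    n_patterned = vapply(patterns, nrow, integer(1)),
    stringsAsFactors = FALSE)
  manifest <- writeReport(tables, out_dir, seed = config@seed,
                          config_hash = unname(tools::md5sum(
                            config@config_path)))
  .log(quiet, "wrote %d tables to %s", length(tables), out_dir)
  invisible(list(manifest = manifest, tables = tables,
                 annotations = annotations, de = de, patterns = patterns,
                 coannotation = coann))
}
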