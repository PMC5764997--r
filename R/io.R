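## Readers/writers for the external formats the pipeline touches: tabular
## alignment-hit tables (outfmt-6 compatible via a column map), TSV count
## matrices, plain-text gene lists, and the TSV+JSON report bundle. All
## readers validate strictly and name the offending row/cell on failure.

HIT_FIELDS <- c("query_id", "subject_acc", "subject_taxon", "subject_species",
                "bit_score", "sig_value", "query_coverage", "identity_frac")
HIT_MANDATORY <- c("query_id", "subject_acc", "bit_score", "sig_value")

#' Column map for tabular alignment-hit files
#'
#' Describes how the columns of a tab-separated hit table map onto hit
#' fields. The native layout (the default) has eight columns:
#' `query_id, subject_acc, subject_taxon, subject_species, bit_score,
#' sig_value, query_coverage, identity_frac`. For 12-column BLAST
#' `outfmt 6` output use [outfmt6Dialect()].
#'
#' @param cols named integer vector mapping field names (a subset of
#'   `query_id, subject_acc, subject_taxon, subject_species, bit_score,
#'   sig_value, query_coverage, identity_frac`) to 1-based column indices.
#'   `query_id`, `subject_acc`, `bit_score` and `sig_value` are mandatory.
#' @param percent_identity logical; if `TRUE` the identity column holds
#'   percentages (0-100) and is divided by 100 on input.
#' @param taxon_default,species_default values used when the file carries no
#'   taxon / species column.
#' @return a list of class `hit_dialect`.
#' @export
hitDialect <- function(cols = c(query_id = 1, subject_acc = 2,
                                subject_taxon = 3, subject_species = 4,
                                bit_score = 5, sig_value = 6,
                                query_coverage = 7, identity_frac = 8),
                       percent_identity = FALSE,
                       taxon_default = "unknown",
                       species_default = "unknown") {
  if (is.null(names(cols)) || !all(names(cols) %in% HIT_FIELDS))
    stop("dialect columns must be named by hit fields: ",
         paste(HIT_FIELDS, collapse = ", "))
  missing <- setdiff(HIT_MANDATORY, names(cols))
  if (length(missing))
    stop("dialect is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  structure(list(cols = cols, percent_identity = percent_identity,
                 taxon_default = taxon_default,
                 species_default = species_default),
            class = "hit_dialect")
}

#' @describeIn hitDialect column map for standard 12-column BLAST outfmt 6
#'   (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'   evalue bitscore); taxon and species default to fixed labels since
#'   outfmt 6 does not carry them.
#' @export
outfmt6Dialect <- function(taxon_default = "unknown",
                           species_default = "unknown") {
  hitDialect(cols = c(query_id = 1, subject_acc = 2, identity_frac = 3,
                      sig_value = 11, bit_score = 12),
             percent_identity = TRUE,
             taxon_default = taxon_default,
             species_default = species_default)
}

#' Validate a hit table
#'
#' Checks the invariants of a hit table: mandatory columns present,
#' `bit_score >= 0`, `sig_value >= 0`, and optional `query_coverage` /
#' `identity_frac` within `[0, 1]` where not `NA`. Errors name the first
#' offending rows.
#'
#' @param hits data.frame of hits.
#' @return the validated data.frame, invisibly usable in a pipeline.
#' @export
validateHitTable <- function(hits) {
  missing <- setdiff(HIT_MANDATORY, names(hits))
  if (length(missing))
    stop("hit table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  bad_row <- function(ok, what) {
    bad <- which(!ok)
    if (length(bad))
      stop(sprintf("invalid %s at row(s) %s", what,
                   paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad_row(!is.na(hits$bit_score) & hits$bit_score >= 0,
          "bit_score (must be a number >= 0)")
  bad_row(!is.na(hits$sig_value) & hits$sig_value >= 0,
          "sig_value (must be a number >= 0)")
  for (f in c("query_coverage", "identity_frac"))
    if (f %in% names(hits))
      bad_row(is.na(hits[[f]]) | (hits[[f]] >= 0 & hits[[f]] <= 1),
              sprintf("%s (must be in [0,1] or NA)", f))
  hits
}

#' Read a tab-separated alignment-hit table
#'
#' Ingests aligner output (e.g. BLAST `outfmt 6`) through a column map and
#' returns one validated hit record per row. Line-ending convention (LF or
#' CRLF) does not affect the result.
#'
#' @param path path to a tab-separated file without header.
#' @param dialect a [hitDialect()] describing the column layout.
#' @return data.frame with columns `query_id, subject_acc, subject_taxon,
#'   subject_species, bit_score, sig_value, query_coverage, identity_frac`
#'   (optional fractions are `NA` when absent from the file).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("tx1\tP12345\tEukaryota\thuman\t210.5\t1e-30\t0.9\t0.8", tf)
#' readHitTable(tf)
#' @export
readHitTable <- function(path, dialect = hitDialect()) {
  stopifnot(inherits(dialect, "hit_dialect"))
  if (!any(nzchar(readLines(path)))) return(emptyHitTable())
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  needed <- max(dialect$cols)
  if (ncol(raw) < needed)
    stop(sprintf("hit table has %d column(s) but the dialect needs %d",
                 ncol(raw), needed))
  out <- data.frame(query_id = character(nrow(raw)),
                    stringsAsFactors = FALSE)
  for (f in HIT_FIELDS) {
    if (f %in% names(dialect$cols)) {
      v <- raw[[dialect$cols[[f]]]]
      if (f %in% c("bit_score", "sig_value", "query_coverage",
                   "identity_frac")) {
        num <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(num) & !is.na(v) & v != "" & v != "NA")
        if (length(bad))
          stop(sprintf("non-numeric %s at row(s) %s", f,
                       paste(utils::head(bad, 5), collapse = ", ")))
        out[[f]] <- num
      } else out[[f]] <- v
    } else {
      out[[f]] <- switch(f,
        subject_taxon = dialect$taxon_default,
        subject_species = dialect$species_default,
        query_coverage = NA_real_,
        identity_frac = NA_real_,
        stop("unmapped mandatory field ", f))
    }
  }
  if (isTRUE(dialect$percent_identity) && "identity_frac" %in% names(dialect$cols))
    out$identity_frac <- out$identity_frac / 100
  validateHitTable(out)
}

#' @describeIn readHitTable an empty, correctly typed hit table.
#' @export
emptyHitTable <- function() {
  data.frame(query_id = character(), subject_acc = character(),
             subject_taxon = character(), subject_species = character(),
             bit_score = numeric(), sig_value = numeric(),
             query_coverage = numeric(), identity_frac = numeric(),
             stringsAsFactors = FALSE)
}

#' Write a hit table in the native eight-column layout
#'
#' @param hits a hit table (see [readHitTable()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHitTable <- function(hits, path) {
  hits <- validateHitTable(hits)
  out <- hits[, HIT_FIELDS]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a time-course count matrix
#'
#' Reads a TSV whose header row holds the sampling times (first field a
#' gene-id column label, remaining fields numeric times) and whose rows hold
#' one gene each: gene id followed by non-negative integer raw counts.
#' Times must be strictly increasing; the first column of counts is the
#' baseline. Day-denominated series are converted to hours on input.
#'
#' @param path path to the TSV.
#' @param species species tag stored in the result.
#' @param time_unit `"hours"` (default) or `"days"`; days are multiplied
#'   by 24.
#' @param gene_length_bp optional named vector of transcript lengths (bp).
#' @return a [TimeCourseExperiment-class].
#' @export
readCounts <- function(path, species = "unknown",
                       time_unit = c("hours", "days"),
                       gene_length_bp = NULL) {
  time_unit <- match.arg(time_unit)
  lines <- readLines(path)
  if (!length(lines)) stop("empty count file: ", path)
  hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 2L) stop("count file needs a gene-id column and >= 1 time point")
  tp <- suppressWarnings(as.numeric(hdr[-1]))
  if (any(is.na(tp)))
    stop("non-numeric time point in header: ",
         paste(hdr[-1][is.na(tp)], collapse = ", "))
  if (is.unsorted(tp, strictly = TRUE))
    stop("time points in header must be strictly increasing")
  if (time_unit == "days") tp <- tp * 24
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) stop("count file has no gene rows: ", path)
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != length(hdr)))
    stop("row(s) with wrong field count: ",
         paste(utils::head(which(nfield != length(hdr)) + 1L, 5), collapse = ", "))
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate gene id(s): ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(tp),
              dimnames = list(ids, NULL))
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]][-1]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop(sprintf("invalid count at gene '%s', time point column %d (value '%s'): counts must be non-negative integers",
                   ids[i], bad[1], parts[[i]][-1][bad[1]]))
    m[i, ] <- v
  }
  TimeCourseExperiment(m, time_h = tp, species = species,
                       gene_length_bp = gene_length_bp)
}

#' Write a time-course count matrix
#'
#' Inverse of [readCounts()]: writing then reading reproduces the counts,
#' gene ids and time grid exactly.
#'
#' @param tce a [TimeCourseExperiment-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(tce, path) {
  stopifnot(methods::is(tce, "TimeCourseExperiment"))
  m <- SummarizedExperiment::assay(tce, "counts")
  hdr <- paste(c("gene_id", format(timePoints(tce), trim = TRUE,
                                   scientific = FALSE)), collapse = "\t")
  rows <- paste(rownames(m),
                apply(m, 1L, function(r)
                  paste(format(r, trim = TRUE, scientific = FALSE),
                        collapse = "\t")),
                sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a plain-text gene/accession list
#'
#' One accession per line; `#` starts a comment (whole-line or trailing);
#' surrounding whitespace is stripped; duplicates are dropped keeping first
#' occurrence; case is preserved. CRLF and LF files give identical results.
#'
#' @param path path to the list file.
#' @return character vector of unique accessions in file order (possibly
#'   empty, with a warning).
#' @export
readGeneList <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- unique(lines)
  if (!length(out))
    warning("gene list is empty after removing comments/duplicates: ", path)
  out
}

#' Write result tables and a run manifest
#'
#' Writes one TSV per named table into `out_dir` (rows sorted by the first
#' column, then remaining columns, for byte-identical reruns) plus a
#' `manifest.json` recording the files written, their row counts, the seed,
#' an optional config hash and the package version. No timestamps are
#' recorded, so a rerun on identical inputs is byte-identical.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed to record, or `NULL`.
#' @param config_hash character hash of the run configuration, or `NULL`.
#' @return the manifest, invisibly (also written as JSON).
#' @export
writeReport <- function(tables, out_dir, seed = NULL, config_hash = NULL) {
  if (length(tables) && (is.null(names(tables)) || any(!nzchar(names(tables)))))
    stop("tables must be a named list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  entries <- list()
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    if (nrow(tab) > 1L) {
      ord <- do.call(order, lapply(seq_len(ncol(tab)), function(j) tab[[j]]))
      tab <- tab[ord, , drop = FALSE]
    }
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    entries[[nm]] <- list(file = basename(f), rows = nrow(tab))
  }
  manifest <- list(
    package = "xregen",
    version = as.character(utils::packageVersion("xregen")),
    seed = seed,
    config_hash = config_hash,
    tables = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
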