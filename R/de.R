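## Replicate-free time-course differential expression: expression filtering,
## library-size normalization, log2 fold change against the baseline time
## point, a negative-binomial exact test conditioned on the pairwise count
## total, Benjamini-Hochberg correction and DE calling.

#' Expression filter for a time course
#'
#' A gene is retained iff its raw count exceeds `min_count` in at least one
#' time point (strictly: a maximum of exactly `min_count` is filtered out),
#' or, when transcript lengths are available, its rpkm exceeds `min_rpkm` in
#' at least one time point. rpkm uses
#' `count * 1e9 / (library_size * gene_length_bp)` with the column sum as
#' library size.
#'
#' @param tce a [TimeCourseExperiment-class].
#' @param config a [DEConfig-class].
#' @return character vector of retained gene ids, in input order.
#' @examples
#' m <- rbind(low = c(5, 15, 19), ok = c(0, 0, 21))
#' tce <- TimeCourseExperiment(m, c(0, 6, 12), "demo")
#' filterExpressed(tce)   # only "ok"
#' @export
filterExpressed <- function(tce, config = deConfig()) {
  stopifnot(methods::is(tce, "TimeCourseExperiment"),
            methods::is(config, "DEConfig"))
  m <- SummarizedExperiment::assay(tce, "counts")
  keep <- apply(m, 1L, max) > config@min_count
  len <- geneLengths(tce)
  if (!is.null(len)) {
    lib <- colSums(m)
    rpkm <- m * 1e9 / (rep(lib, each = nrow(m)) * len)
    keep <- keep | apply(rpkm, 1L, max) > config@min_rpkm
  }
  rownames(m)[keep]
}

#' Per-time-point library size factors
#'
#' The size factor of each column is its library size (column sum) divided
#' by the geometric mean of all library sizes, so dividing counts by their
#' column's factor puts all time points on a common scale with the overall
#' depth preserved.
#'
#' @param counts a [TimeCourseExperiment-class] or a counts matrix.
#' @return numeric vector of positive factors, one per time point.
#' @export
normalizeLibSizes <- function(counts) {
  m <- if (methods::is(counts, "TimeCourseExperiment"))
    SummarizedExperiment::assay(counts, "counts") else as.matrix(counts)
  lib <- colSums(m)
  if (any(lib <= 0))
    stop("all-zero time point column(s): ",
         paste(which(lib <= 0), collapse = ", "))
  lib / exp(mean(log(lib)))
}

#' Median-of-ratios size factors
#'
#' DESeq-style robust size factors: each gene's counts are divided by the
#' gene's geometric mean across time points, and the factor of a time
#' point is the median of those ratios over genes (renormalized to
#' geometric mean 1). Under the most-genes-null assumption this estimate
#' is insensitive to the minority of genes that are strongly
#' differentially expressed, where plain library-size scaling
#' ([normalizeLibSizes()]) is biased by the extra (or missing) read mass
#' of the deregulated genes.
#'
#' @param counts a [TimeCourseExperiment-class] or a counts matrix.
#' @return numeric vector of positive factors, one per time point.
#' @export
medianRatioFactors <- function(counts) {
  m <- if (methods::is(counts, "TimeCourseExperiment"))
    SummarizedExperiment::assay(counts, "counts") else as.matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (sum(pos) < 2L)
    stop("median-of-ratios factors need >= 2 genes expressed everywhere")
  lm <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(lm)
  f <- exp(apply(lm - ref, 2L, stats::median))
  f / exp(mean(log(f)))
}

#' Log2 fold change against the baseline time point
#'
#' `log2fc(g, t) = log2((count(g,t)/factor(t) + pc) / (count(g,1)/factor(1)
#' + pc))` with pseudocount `pc` keeping the ratio finite at zero counts.
#' The baseline column is identically zero.
#'
#' @param tce a [TimeCourseExperiment-class].
#' @param factors size factors from [normalizeLibSizes()] (recomputed when
#'   `NULL`).
#' @param config a [DEConfig-class] (supplies the pseudocount).
#' @return genes x time points matrix of log2 fold changes.
#' @export
computeLog2FC <- function(tce, factors = NULL, config = deConfig()) {
  stopifnot(methods::is(tce, "TimeCourseExperiment"))
  m <- SummarizedExperiment::assay(tce, "counts")
  if (is.null(factors)) factors <- normalizeLibSizes(m)
  stopifnot(length(factors) == ncol(m), all(factors > 0))
  norm <- sweep(m, 2L, factors, "/") + config@pseudocount
  out <- log2(norm / norm[, 1L])
  dimnames(out) <- dimnames(m)
  out
}

#' Two-sided negative-binomial exact test for a pair of counts
#'
#' Tests whether two raw counts from libraries of effective sizes
#' `size_a`, `size_b` are consistent with a common underlying expression
#' level, without replicates, under a negative-binomial model with fixed
#' dispersion `phi` (variance `mu + phi mu^2`). Conditioning on the total
#' `s = a + b`, the null means are split proportionally to the library
#' sizes, and the two-sided p-value is the total conditional probability of
#' all splits `k` whose probability does not exceed that of the observed
#' split. With `dispersion = 0` the model degenerates to Poisson and the
#' conditional distribution is binomial.
#'
#' @param count_a,count_b non-negative integer counts.
#' @param size_a,size_b positive effective library sizes (defaults 1, 1:
#'   equal libraries).
#' @param dispersion NB dispersion phi, `>= 0` (default 0.1).
#' @return p-value in (0, 1].
#' @examples
#' nbExactTest(5, 5)                      # the mode: p = 1
#' nbExactTest(0, 50, dispersion = 0)     # extreme binomial split
#' @export
nbExactTest <- function(count_a, count_b, size_a = 1, size_b = 1,
                        dispersion = 0.1) {
  if (length(dispersion) != 1L || is.na(dispersion) || dispersion < 0)
    stop("dispersion must be a single number >= 0")
  stopifnot(count_a >= 0, count_b >= 0, count_a == round(count_a),
            count_b == round(count_b), size_a > 0, size_b > 0)
  s <- count_a + count_b
  if (s == 0) return(1)
  prop_a <- size_a / (size_a + size_b)
  mu_a <- s * prop_a
  mu_b <- s * (1 - prop_a)
  k <- 0:s
  logp <- if (dispersion == 0) {
    stats::dpois(k, mu_a, log = TRUE) + stats::dpois(s - k, mu_b, log = TRUE)
  } else {
    stats::dnbinom(k, size = 1 / dispersion, mu = mu_a, log = TRUE) +
      stats::dnbinom(s - k, size = 1 / dispersion, mu = mu_b, log = TRUE)
  }
  obs <- logp[count_a + 1L]
  ## relative tolerance for probability ties, as in standard exact tests
  keep <- logp <= obs + 1e-7
  mx <- max(logp)
  p <- sum(exp(logp[keep] - mx)) / sum(exp(logp - mx))
  min(1, p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The classical step-up procedure: with p-values sorted ascending,
#' `adj_(i) = min_(j >= i) p_(j) * m / j`, capped at 1 and returned in the
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NA`/`NaN` are rejected.
#' @return adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))   # all 0.03
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(is.na(p))) stop("p-values must not contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[ord] * m / seq(m, 1L)))
  adj[order(ord)]
}

#' Moment estimator of a common NB dispersion across time points
#'
#' Treats the time points of mostly-null genes as approximate replicates:
#' per gene, `phi_g = (var - mean) / mean^2` of the normalized counts, and
#' the common dispersion is the median of the positive per-gene values
#' (0 when fewer than 10 genes yield one). A coarse, explicit fallback for
#' series without replicates; the default pipeline uses a fixed dispersion
#' instead.
#'
#' @param tce a [TimeCourseExperiment-class].
#' @return a single dispersion estimate `>= 0`.
#' @export
estimateDispersionMoments <- function(tce) {
  m <- SummarizedExperiment::assay(tce, "counts")
  norm <- sweep(m, 2L, normalizeLibSizes(m), "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1L, stats::var)
  phi <- (v - mu) / mu^2
  phi <- phi[is.finite(phi) & phi > 0]
  if (length(phi) < 10L) 0 else stats::median(phi)
}

#' DETable: differential-expression results for one species
#'
#' Holds the per-gene, per-time-point DE results of one replicate-free time
#' course, plus the matrices they derive from.
#'
#' @slot species species tag.
#' @slot results long-format data.frame: `gene_id, time_h, log2fc, p_raw,
#'   p_adj, is_de` (non-baseline time points of retained genes only).
#' @slot log2fc,p_adj,is_de retained-genes x time-points matrices (the
#'   baseline column of `p_adj` is `NA`, of `is_de` `FALSE`).
#' @slot gene_de named logical: DE at >= 1 non-baseline time point.
#' @slot config the [DEConfig-class] used.
#' @slot size_factors the library size factors used.
#'
#' @seealso [runDE()], [deResults()], [deGenes()]
#' @export
setClass("DETable",
         representation(species = "character", results = "data.frame",
                        log2fc = "matrix", p_adj = "matrix",
                        is_de = "matrix", gene_de = "logical",
                        config = "DEConfig", size_factors = "numeric"))

setMethod("show", "DETable", function(object) {
  cat(sprintf("DETable [%s]: %d retained genes x %d time points\n",
              object@species, nrow(object@log2fc), ncol(object@log2fc)))
  cat(sprintf("  %d genes DE at >= 1 time point (|log2FC| > %g, adj p < %g)\n",
              sum(object@gene_de), object@config@fc_threshold,
              object@config@alpha))
  invisible(NULL)
})

#' @describeIn DETable the long-format results data.frame.
#' @param x a `DETable`.
#' @export
deResults <- function(x) {
  stopifnot(methods::is(x, "DETable"))
  x@results
}

#' @describeIn DETable ids of genes DE at >= 1 time point.
#' @export
deGenes <- function(x) {
  stopifnot(methods::is(x, "DETable"))
  names(x@gene_de)[x@gene_de]
}

#' Call DE from log2FC and adjusted p-value matrices
#'
#' `is_de(g, t) <=> |log2fc(g, t)| > fc_threshold AND p_adj(g, t) < alpha`
#' (both strict); a gene is DE iff it is DE at any non-baseline time point.
#'
#' @param log2fc,p_adj aligned genes x time-points matrices (column 1 is
#'   the baseline; its `p_adj` entries may be `NA`).
#' @param config a [DEConfig-class].
#' @return list with `is_de` (logical matrix, baseline column `FALSE`) and
#'   `gene_de` (named logical vector).
#' @export
callDE <- function(log2fc, p_adj, config = deConfig()) {
  stopifnot(identical(dim(log2fc), dim(p_adj)))
  is_de <- abs(log2fc) > config@fc_threshold & !is.na(p_adj) &
    p_adj < config@alpha
  is_de[, 1L] <- FALSE
  list(is_de = is_de,
       gene_de = stats::setNames(apply(is_de, 1L, any), rownames(log2fc)))
}

#' Replicate-free differential expression over a time course
#'
#' The full per-species DE chain: expression filtering, geometric-mean
#' library-size normalization, log2 fold change against the baseline
#' (first) time point, a pairwise NB exact test of each non-baseline time
#' point against the baseline, BH adjustment, and strict-threshold DE
#' calling. Because a gene is reported as DE when it passes at any time
#' point, the adjustment is applied jointly across all non-baseline tests
#' by default: adjusting each contrast separately and then taking the
#' union would lose control of the false-discovery rate over the reported
#' gene set.
#'
#' @param tce a [TimeCourseExperiment-class].
#' @param config a [DEConfig-class]; use `dispersion = estimateDispersionMoments(tce)`
#'   for the moment-based alternative to the fixed default.
#' @param adjust `"global"` (default) adjusts the pooled p-vector over all
#'   genes and non-baseline time points; `"per_timepoint"` adjusts each
#'   baseline-vs-t contrast separately across genes.
#' @param normalization `"median_ratio"` (default) uses
#'   [medianRatioFactors()], robust to a minority of strongly DE genes;
#'   `"geomean"` uses plain library-size scaling
#'   ([normalizeLibSizes()]). The factors serve both as the log2FC scaling
#'   and as the effective library sizes of the exact test.
#' @return a [DETable-class].
#' @export
runDE <- function(tce, config = deConfig(),
                  adjust = c("global", "per_timepoint"),
                  normalization = c("median_ratio", "geomean")) {
  adjust <- match.arg(adjust)
  normalization <- match.arg(normalization)
  stopifnot(methods::is(tce, "TimeCourseExperiment"),
            methods::is(config, "DEConfig"))
  if (ncol(tce) < 2L)
    stop("differential expression needs a baseline plus >= 1 time point")
  keep <- filterExpressed(tce, config)
  if (!length(keep)) stop("no gene passes the expression filter")
  tce_f <- tce[keep, ]
  m <- SummarizedExperiment::assay(tce_f, "counts")
  factors <- if (normalization == "median_ratio") medianRatioFactors(m)
  else normalizeLibSizes(m)
  lfc <- computeLog2FC(tce_f, factors, config)
  nt <- ncol(m)
  p_raw <- matrix(NA_real_, nrow(m), nt, dimnames = dimnames(m))
  for (t in 2:nt)
    p_raw[, t] <- vapply(seq_len(nrow(m)), function(g)
      nbExactTest(m[g, 1L], m[g, t], factors[1L], factors[t],
                  dispersion = config@dispersion), numeric(1))
  p_adj <- p_raw
  if (adjust == "per_timepoint") {
    for (t in 2:nt) p_adj[, t] <- bhAdjust(p_raw[, t])
  } else {
    p_adj[, -1L] <- bhAdjust(as.vector(p_raw[, -1L]))
  }
  calls <- callDE(lfc, p_adj, config)
  tp <- timePoints(tce_f)
  res <- data.frame(
    gene_id = rep(rownames(m), nt - 1L),
    time_h = rep(tp[-1L], each = nrow(m)),
    log2fc = as.vector(lfc[, -1L]),
    p_raw = as.vector(p_raw[, -1L]),
    p_adj = as.vector(p_adj[, -1L]),
    is_de = as.vector(calls$is_de[, -1L]),
    stringsAsFactors = FALSE)
  res <- res[order(res$gene_id, res$time_h), ]
  rownames(res) <- NULL
  methods::new("DETable", species = speciesTag(tce), results = res,
               log2fc = lfc, p_adj = p_adj, is_de = calls$is_de,
               gene_de = calls$gene_de, config = config,
               size_factors = factors)
}
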