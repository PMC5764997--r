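## Common rescaled clock, early/late phase assignment, classification of DE
## genes into transient (EU/ED) and sustained (LU/LD) temporal patterns,
## and correlation-based clustering of expression profiles.

PATTERN_LEVELS <- c("EU", "ED", "LU", "LD", "OTHER")

#' Rescale a time grid to the unit interval
#'
#' Affine map sending the baseline to 0 and the final time point to 1, so
#' regeneration processes with different total durations can be compared on
#' a common clock.
#'
#' @param time_points_h strictly increasing numeric vector (>= 2 points).
#' @return numeric vector in `[0, 1]`; idempotent on already-rescaled grids.
#' @examples
#' rescaleTime(c(0, 6, 12, 24))
#' rescaleTime(c(0, 72, 168, 336, 504))  # 3/7/14/21 days in hours
#' @export
rescaleTime <- function(time_points_h) {
  if (length(time_points_h) < 2L)
    stop("need at least two time points")
  if (is.unsorted(time_points_h, strictly = TRUE))
    stop("time points must be strictly increasing")
  span <- time_points_h[length(time_points_h)] - time_points_h[1L]
  if (span == 0) stop("first and last time points coincide")
  (time_points_h - time_points_h[1L]) / span
}

#' Assign early/late phases and a recovery time point
#'
#' Default rule, operating on indices into the time vector (baseline at
#' index 1): the early phase is the first two non-baseline time points, the
#' late phase the last two, and the recovery time point the first index at
#' or after `recovery_h` hours (default 24 h) that is not before the end of
#' the early phase. Grids with fewer than three non-baseline points fall
#' back to early = first non-baseline point, late = last point. Species
#' with sparse early sampling (e.g. a first sample at 3 days) should
#' override `early` to the first non-baseline index only and set
#' `recovery_h` accordingly (14 days for the sea-cucumber-style grid).
#'
#' @param time_points_h strictly increasing time grid (hours), baseline
#'   first.
#' @param species species tag stored in the result.
#' @param early,late optional explicit integer index overrides (must be
#'   disjoint, baseline excluded).
#' @param recovery_h clock time (hours) of the required recovery for
#'   transient patterns (default 24).
#' @param recovery optional explicit recovery index override.
#' @return a [PhaseSpec-class].
#' @examples
#' assignPhases(c(0, 0.5, 3, 6, 12, 24, 48), "hydra")
#' assignPhases(c(0, 72, 168, 336, 504), "seacucumber",
#'              early = 2L, recovery_h = 14 * 24)
#' @export
assignPhases <- function(time_points_h, species = "unknown",
                         early = NULL, late = NULL, recovery_h = 24,
                         recovery = NULL) {
  nt <- length(time_points_h)
  if (nt < 2L) stop("need at least one non-baseline time point")
  if (is.unsorted(time_points_h, strictly = TRUE))
    stop("time points must be strictly increasing")
  nb <- 2:nt                       # non-baseline indices
  user_phase <- !is.null(early) || !is.null(late)
  if (is.null(early))
    early <- if (length(nb) >= 3L) nb[1:2] else nb[1L]
  if (is.null(late)) {
    late <- if (length(nb) >= 3L) utils::tail(nb, 2L) else nb[length(nb)]
    late <- setdiff(late, early)
    if (!length(late)) late <- nt
  }
  early <- as.integer(early); late <- as.integer(late)
  if (length(intersect(early, late)))
    stop(if (user_phase) "early/late override indices overlap"
         else "early and late phases overlap")
  if (is.null(recovery)) {
    cand <- which(time_points_h >= recovery_h)
    cand <- cand[cand >= max(early)]
    recovery <- if (length(cand)) min(cand) else nt
  }
  methods::new("PhaseSpec", species = as.character(species), early = early,
               late = late, recovery = as.integer(recovery))
}

#' Classify the temporal pattern of one DE gene
#'
#' Assigns one of the four recurrent regeneration patterns, or `OTHER`:
#' * `EU` (early up, transient): DE with positive log2FC at >= 1 early
#'   index, all early DE calls positive, and back near baseline
#'   (`|log2fc| <= recovery_tol`) at the recovery time point;
#' * `ED`: the mirror image with negative sign;
#' * `LU` (sustained up): positive log2FC at every DE time point, DE
#'   persisting at >= 1 late index, and no recovery;
#' * `LD`: the mirror image;
#' * `OTHER`: sign-mixed or fitting none of the above.
#' Negating the whole log2FC series maps EU to ED and LU to LD exactly.
#'
#' @param log2fc numeric series over all time points (baseline first).
#' @param is_de logical series, same length; must be `TRUE` somewhere.
#' @param phases a [PhaseSpec-class] for this grid.
#' @param recovery_tol tolerance on `|log2fc|` at the recovery point
#'   (default 0.5).
#' @return one-row data.frame: `pattern` (factor over EU/ED/LU/LD/OTHER),
#'   `peak_log2fc` (signed value of largest magnitude among DE points),
#'   `recovery_log2fc`.
#' @export
classifyPattern <- function(log2fc, is_de, phases, recovery_tol = 0.5) {
  stopifnot(methods::is(phases, "PhaseSpec"),
            length(log2fc) == length(is_de))
  de_idx <- which(is_de)
  de_idx <- de_idx[de_idx > 1L]
  if (!length(de_idx))
    stop("gene is not DE at any non-baseline time point")
  early_de <- intersect(de_idx, phases@early)
  late_de <- intersect(de_idx, phases@late)
  recovered <- abs(log2fc[phases@recovery]) <= recovery_tol
  pattern <- "OTHER"
  if (length(early_de) && all(log2fc[early_de] > 0) && recovered) {
    pattern <- "EU"
  } else if (length(early_de) && all(log2fc[early_de] < 0) && recovered) {
    pattern <- "ED"
  } else if (all(log2fc[de_idx] > 0) && length(late_de) && !recovered) {
    pattern <- "LU"
  } else if (all(log2fc[de_idx] < 0) && length(late_de) && !recovered) {
    pattern <- "LD"
  }
  peak <- log2fc[de_idx][which.max(abs(log2fc[de_idx]))]
  data.frame(pattern = factor(pattern, levels = PATTERN_LEVELS),
             peak_log2fc = peak,
             recovery_log2fc = log2fc[phases@recovery])
}

#' Classify the temporal patterns of all DE genes of a species
#'
#' @param de a [DETable-class], or a list with elements `log2fc` and
#'   `is_de` (aligned matrices).
#' @param phases a [PhaseSpec-class].
#' @param recovery_tol see [classifyPattern()].
#' @return data.frame with one row per DE gene: `gene_id, pattern,
#'   peak_log2fc, recovery_log2fc`.
#' @export
classifyPatterns <- function(de, phases, recovery_tol = 0.5) {
  if (methods::is(de, "DETable"))
    de <- list(log2fc = de@log2fc, is_de = de@is_de)
  genes <- rownames(de$log2fc)[apply(de$is_de[, -1L, drop = FALSE], 1L, any)]
  rows <- lapply(genes, function(g)
    cbind(gene_id = g,
          classifyPattern(de$log2fc[g, ], de$is_de[g, ], phases,
                          recovery_tol = recovery_tol)))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(),
               pattern = factor(character(), levels = PATTERN_LEVELS),
               peak_log2fc = numeric(), recovery_log2fc = numeric())
  rownames(out) <- NULL
  out
}

#' Cluster DE-gene expression profiles
#'
#' Agglomerative clustering of log2FC profiles with distance
#' `1 - Pearson correlation` and average linkage, cut at `k` clusters.
#' Constant (zero-variance) profiles have no defined correlation; they are
#' assigned to the cluster with the nearest (Euclidean) mean profile and
#' flagged.
#'
#' @param log2fc genes x time-points matrix (DE genes).
#' @param k number of clusters (default 4, the canonical pattern count).
#' @return list with `labels` (named integer), `centers` (k x time-points
#'   matrix of mean profiles) and `fallback` (named logical marking
#'   constant profiles assigned by the Euclidean fallback).
#' @export
clusterProfiles <- function(log2fc, k = 4L) {
  log2fc <- as.matrix(log2fc)
  if (is.null(rownames(log2fc)))
    rownames(log2fc) <- sprintf("g%d", seq_len(nrow(log2fc)))
  if (k < 2L) stop("k must be >= 2")
  if (nrow(log2fc) < k) stop("need at least k profiles")
  sds <- apply(log2fc, 1L, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  core <- log2fc[!const, , drop = FALSE]
  if (nrow(core) < k)
    stop("fewer than k non-constant profiles")
  d <- stats::as.dist(1 - stats::cor(t(core)))
  hc <- stats::hclust(d, method = "average")
  lab_core <- stats::cutree(hc, k = k)
  centers <- t(vapply(seq_len(k), function(cl)
    colMeans(core[lab_core == cl, , drop = FALSE]),
    numeric(ncol(core))))
  rownames(centers) <- sprintf("cluster_%d", seq_len(k))
  labels <- integer(nrow(log2fc))
  names(labels) <- rownames(log2fc)
  labels[rownames(core)] <- lab_core
  if (any(const)) {
    for (g in rownames(log2fc)[const]) {
      dist_euc <- colSums((t(centers) - log2fc[g, ])^2)
      labels[g] <- which.min(dist_euc)
    }
  }
  list(labels = labels, centers = centers,
       fallback = stats::setNames(const, rownames(log2fc)))
}
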