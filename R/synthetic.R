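## Seeded generator of multi-species fixtures with planted ground truth:
## a reference accession universe, per-species alignment-hit tables with
## planted ortholog groups, NB time-course counts with planted EU/ED/LU/LD
## pulses, signature lists with controlled overlap, and a writer that emits
## a complete fixture directory.

#' GeneratorConfig: study conditions for the synthetic fixtures
#'
#' Defaults emulate the comparative-regeneration study design: three
#' species on heterogeneous sampling grids (a hydra-like dense early grid
#' over 48 h, a planarian-like grid over 72 h, and a sea-cucumber-like
#' 3/7/14/21-day grid stored in hours), negative-binomial counts with
#' dispersion 0.1 around a baseline mean of 100, planted ortholog triplets
#' sharing their hit lists, hit lists averaging ~15 subjects per gene, a
#' small set of ortholog groups planted as DE in every species, and
#' per-species planted EU/ED/LU/LD pulses at effect size 3 (log2 units).
#'
#' @slot seed RNG seed (integer-valued).
#' @slot species species tags; must match `names(time_grids)`.
#' @slot n_genes genes per species.
#' @slot n_ortholog_groups planted cross-species ortholog groups.
#' @slot n_common_de leading ortholog groups additionally planted as
#'   sustained DE (alternating up/down) in every species (the
#'   cross-species common-DE truth).
#' @slot hit_list_size_mean mean hit-list size per gene.
#' @slot decoy_hit_rate Poisson mean of decoy hits per gene (decoys fall
#'   above the strict significance cutoff and never outscore planted hits,
#'   unless `adversarial`).
#' @slot dispersion NB dispersion phi of the counts.
#' @slot baseline_mean baseline expression mean.
#' @slot effect_size planted |log2FC| of DE pulses.
#' @slot pattern_counts named integer `c(EU=,ED=,LU=,LD=)` of species-local
#'   planted pattern genes.
#' @slot time_grids named list of strictly increasing hour vectors.
#' @slot n_accessions size of the reference accession universe.
#' @slot taxon_props named proportions over
#'   `human, mouse, other, bacteria`.
#' @slot n_signature_shared accessions planted in all signature source
#'   lists.
#' @slot adversarial allow decoys to outscore planted hits (robustness
#'   testing only).
#'
#' @seealso [generatorConfig()]
#' @export
setClass("GeneratorConfig",
         representation(seed = "numeric", species = "character",
                        n_genes = "integer", n_ortholog_groups = "integer",
                        n_common_de = "integer",
                        hit_list_size_mean = "numeric",
                        decoy_hit_rate = "numeric", dispersion = "numeric",
                        baseline_mean = "numeric", effect_size = "numeric",
                        pattern_counts = "integer", time_grids = "list",
                        n_accessions = "integer", taxon_props = "numeric",
                        n_signature_shared = "integer",
                        adversarial = "logical"))

setValidity("GeneratorConfig", function(object) {
  msg <- NULL
  if (!setequal(object@species, names(object@time_grids)))
    msg <- c(msg, "species must match names(time_grids)")
  for (g in object@time_grids)
    if (length(g) < 2L || is.unsorted(g, strictly = TRUE))
      msg <- c(msg, "each time grid must be strictly increasing, >= 2 points")
  if (object@n_ortholog_groups > object@n_genes)
    msg <- c(msg, "more ortholog groups than genes")
  if (object@n_common_de > object@n_ortholog_groups)
    msg <- c(msg, "n_common_de cannot exceed n_ortholog_groups")
  if (!setequal(names(object@pattern_counts), c("EU", "ED", "LU", "LD")))
    msg <- c(msg, "pattern_counts must be named EU, ED, LU, LD")
  if (any(object@pattern_counts < 0))
    msg <- c(msg, "pattern_counts must be >= 0")
  if (object@n_ortholog_groups + sum(object@pattern_counts) > object@n_genes)
    msg <- c(msg, "ortholog block plus planted patterns exceed n_genes")
  if (sum(object@pattern_counts) + object@n_common_de > 0 &&
      (!is.finite(object@effect_size) || object@effect_size <= 0))
    msg <- c(msg, "planted patterns require a positive finite effect_size")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (any(object@taxon_props < 0) ||
      abs(sum(object@taxon_props) - 1) > 1e-8 ||
      !setequal(names(object@taxon_props),
                c("human", "mouse", "other", "bacteria")))
    msg <- c(msg, "taxon_props must be proportions over human/mouse/other/bacteria summing to 1")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GeneratorConfig
#'
#' @param seed RNG seed.
#' @param species species tags (default hydra-, planarian- and
#'   sea-cucumber-like).
#' @param n_genes genes per species (default 2000).
#' @param n_ortholog_groups planted ortholog triplets (default 100).
#' @param n_common_de ortholog groups planted DE in every species
#'   (default 18).
#' @param hit_list_size_mean mean hit-list size (default 15).
#' @param decoy_hit_rate Poisson mean of decoy hits per gene (default 3).
#' @param dispersion NB dispersion (default 0.1).
#' @param baseline_mean baseline count mean (default 100).
#' @param effect_size planted |log2FC| (default 3).
#' @param pattern_counts species-local planted pattern genes (default 50
#'   each of EU/ED/LU/LD).
#' @param time_grids named list of hour grids (defaults above).
#' @param n_accessions reference universe size (default 3000).
#' @param taxon_props proportions of human/mouse/other-eukaryote/bacteria
#'   accessions (default 0.4/0.2/0.3/0.1: about half human or murine).
#' @param n_signature_shared accessions shared by all signature lists
#'   (default 5).
#' @param adversarial see [GeneratorConfig-class] (default `FALSE`).
#' @return a [GeneratorConfig-class].
#' @export
generatorConfig <- function(seed = 1,
                            species = c("hydra", "planaria", "seacucumber"),
                            n_genes = 2000L, n_ortholog_groups = 100L,
                            n_common_de = 18L, hit_list_size_mean = 15,
                            decoy_hit_rate = 3, dispersion = 0.1,
                            baseline_mean = 100, effect_size = 3,
                            pattern_counts = c(EU = 50L, ED = 50L,
                                               LU = 50L, LD = 50L),
                            time_grids = list(
                              hydra = c(0, 0.5, 3, 6, 12, 24, 48),
                              planaria = c(0, 6, 12, 24, 36, 48, 72),
                              seacucumber = c(0, 72, 168, 336, 504)),
                            n_accessions = 3000L,
                            taxon_props = c(human = 0.4, mouse = 0.2,
                                            other = 0.3, bacteria = 0.1),
                            n_signature_shared = 5L,
                            adversarial = FALSE) {
  pc <- pattern_counts
  storage.mode(pc) <- "integer"
  methods::new("GeneratorConfig", seed = seed, species = species,
               n_genes = as.integer(n_genes),
               n_ortholog_groups = as.integer(n_ortholog_groups),
               n_common_de = as.integer(n_common_de),
               hit_list_size_mean = hit_list_size_mean,
               decoy_hit_rate = decoy_hit_rate, dispersion = dispersion,
               baseline_mean = baseline_mean, effect_size = effect_size,
               pattern_counts = pc, time_grids = time_grids,
               n_accessions = as.integer(n_accessions),
               taxon_props = taxon_props,
               n_signature_shared = as.integer(n_signature_shared),
               adversarial = adversarial)
}

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(paste0(
    "GeneratorConfig (seed %g): %d species x %d genes\n",
    "  %d ortholog groups (%d common-DE), patterns %s at effect %g\n",
    "  NB(mean %g, phi %g); universe %d accessions\n"),
    object@seed, length(object@species), object@n_genes,
    object@n_ortholog_groups, object@n_common_de,
    paste(sprintf("%s=%d", names(object@pattern_counts),
                  object@pattern_counts), collapse = "/"),
    object@effect_size, object@baseline_mean, object@dispersion,
    object@n_accessions))
  invisible(NULL)
})

## deterministic largest-block allocation of n items to proportions
.allocate <- function(n, props) {
  cuts <- floor(cumsum(props) * n + 1e-9)
  diff(c(0L, cuts))
}

#' Generate the reference accession universe
#'
#' Accessions tagged human / mouse / other-eukaryote / bacteria in the
#' configured proportions (deterministic allocation, so a 50% share of 100
#' accessions is exactly 50). Stands in for a curated reference protein
#' database.
#'
#' @param config a [GeneratorConfig-class].
#' @return data.frame `accession, species, taxon`.
#' @export
generateReferenceUniverse <- function(config) {
  methods::validObject(config)
  n <- config@n_accessions
  if (n == 0L)
    return(data.frame(accession = character(), species = character(),
                      taxon = character(), stringsAsFactors = FALSE))
  sizes <- .allocate(n, config@taxon_props)
  groups <- names(config@taxon_props)
  prefix <- c(human = "HSA", mouse = "MMU", other = "EUK", bacteria = "BAC")
  acc <- unlist(lapply(seq_along(groups), function(i)
    if (sizes[i]) sprintf("%s%05d", prefix[[groups[i]]], seq_len(sizes[i]))
    else character()))
  data.frame(
    accession = acc,
    species = rep(c("human", "mouse", "other_eukaryote", "bacteria"), sizes),
    taxon = rep(c("Eukaryota", "Eukaryota", "Eukaryota", "Bacteria"), sizes),
    stringsAsFactors = FALSE)
}

.geneIds <- function(sp, n) sprintf("%s_g%05d", sp, seq_len(n))

#' Generate per-species hit tables with planted ortholog truth
#'
#' Each planted ortholog group assigns one gene per species the same human
#' accession as top-scoring hit (significance around the 1e-30 scale),
#' plus a shared list of lower-scoring eukaryotic hits below the strict
#' cutoff, so best-match and list-match co-annotation both recover the
#' group. Non-planted genes draw hits from species-disjoint accession
#' slices (no spurious cross-species links). Decoy hits (Poisson rate)
#' carry significance above the strict cutoff, and a fraction of genes get
#' a bacterial hit, exercising the filters without perturbing the truth;
#' in `adversarial` mode decoys may outscore planted hits.
#'
#' @param config a [GeneratorConfig-class].
#' @param universe output of [generateReferenceUniverse()].
#' @return list with `hits` (named list of per-species hit tables) and
#'   `truth` (data.frame `group, accession, species, gene_id`).
#' @export
generateHitTables <- function(config, universe) {
  methods::validObject(config)
  if (!nrow(universe)) stop("universe must be non-empty")
  G <- config@n_ortholog_groups
  human_acc <- universe$accession[universe$species == "human"]
  euk_acc <- universe$accession[universe$taxon == "Eukaryota"]
  bac_acc <- universe$accession[universe$taxon == "Bacteria"]
  if (length(human_acc) < G)
    stop("universe has fewer human accessions than ortholog groups")
  set.seed(config@seed)
  planted_acc <- human_acc[seq_len(G)]
  ## shared list-match extras per group (identical across species)
  extra_pool <- setdiff(euk_acc, planted_acc)
  list_sizes <- pmax(2L, stats::rpois(G, config@hit_list_size_mean))
  extras <- lapply(list_sizes, function(L)
    sample(extra_pool, min(L - 1L, length(extra_pool))))
  ## species-disjoint slices for non-planted genes
  free_acc <- setdiff(euk_acc,
                      union(planted_acc, human_acc))  # never human
  slice <- split(free_acc,
                 rep_len(seq_along(config@species), length(free_acc)))
  hits <- list()
  truth <- list()
  for (si in seq_along(config@species)) {
    sp <- config@species[si]
    ids <- .geneIds(sp, config@n_genes)
    ## accumulate column chunks and bind once (fast at fixture scale)
    chunks <- list()
    add <- function(qid, acc, taxon, spp, bit, sig, cov, idf) {
      chunks[[length(chunks) + 1L]] <<- list(
        query_id = rep_len(qid, length(acc)), subject_acc = acc,
        subject_taxon = rep_len(taxon, length(acc)),
        subject_species = spp, bit_score = bit, sig_value = sig,
        query_coverage = cov, identity_frac = idf)
    }
    for (g in seq_len(config@n_genes)) {
      qid <- ids[g]
      if (g <= G) {
        main_score <- stats::runif(1, 250, 350)
        add(qid, planted_acc[g], "Eukaryota", "human", main_score,
            10^-stats::runif(1, 25, 35), stats::runif(1, 0.7, 1),
            stats::runif(1, 0.7, 0.95))
        ex <- extras[[g]]
        if (length(ex)) {
          nx <- length(ex)
          add(qid, ex, "Eukaryota",
              universe$species[match(ex, universe$accession)],
              stats::runif(nx, 50, main_score - 10),
              10^-stats::runif(nx, 16, 25),
              stats::runif(nx, 0.3, 0.9), stats::runif(nx, 0.4, 0.8))
        }
      } else {
        L <- max(1L, stats::rpois(1, config@hit_list_size_mean))
        own <- sample(slice[[si]], min(L, length(slice[[si]])))
        no <- length(own)
        add(qid, own, "Eukaryota",
            universe$species[match(own, universe$accession)],
            stats::runif(no, 50, 200), 10^-stats::runif(no, 16, 30),
            stats::runif(no, 0.3, 0.9), stats::runif(no, 0.4, 0.8))
      }
      n_decoy <- stats::rpois(1, config@decoy_hit_rate)
      if (n_decoy > 0) {
        dec <- sample(euk_acc, n_decoy)
        top <- if (config@adversarial) 400 else 45
        add(qid, dec, "Eukaryota",
            universe$species[match(dec, universe$accession)],
            stats::runif(n_decoy, 25, top),
            10^-stats::runif(n_decoy, 3, 14.9),
            stats::runif(n_decoy, 0.05, 0.5),
            stats::runif(n_decoy, 0.2, 0.6))
      }
      if (length(bac_acc) && stats::runif(1) < 0.1) {
        add(qid, sample(bac_acc, 1), "Bacteria", "bacteria",
            stats::runif(1, 50, 150), 10^-stats::runif(1, 16, 40),
            stats::runif(1, 0.2, 0.8), stats::runif(1, 0.3, 0.7))
      }
    }
    hits[[sp]] <- data.frame(
      lapply(stats::setNames(nm = names(chunks[[1]])), function(f)
        unlist(lapply(chunks, `[[`, f), use.names = FALSE)),
      stringsAsFactors = FALSE)
    if (G)
      truth[[sp]] <- data.frame(group = seq_len(G),
                                accession = planted_acc,
                                species = sp,
                                gene_id = ids[seq_len(G)],
                                stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(group = integer(), accession = character(),
               species = character(), gene_id = character())
  rownames(truth) <- NULL
  list(hits = hits, truth = truth)
}

## per-species planted pattern labels: common-DE groups are sustained
## (alternating up/down, keeping the count composition balanced so
## total-count size factors stay valid) in every species; species-local
## patterns occupy genes after the ortholog block
.plantPatterns <- function(config) {
  labels <- rep("NULL", config@n_genes)
  if (config@n_common_de)
    labels[seq_len(config@n_common_de)] <-
      rep_len(c("LU", "LD"), config@n_common_de)
  start <- config@n_ortholog_groups
  for (p in c("EU", "ED", "LU", "LD")) {
    k <- config@pattern_counts[[p]]
    if (k) {
      labels[start + seq_len(k)] <- p
      start <- start + k
    }
  }
  labels
}

#' Generate per-species NB time-course counts with planted pulses
#'
#' Null genes are NB(`baseline_mean`, `dispersion`) at every time point.
#' EU/ED genes have their mean multiplied by `2^(+-effect_size)` on the
#' early-phase indices only (baseline elsewhere, hence recovered at the
#' recovery time point); LU/LD genes sustain the multiplier from the first
#' non-baseline point onward. The first `n_common_de` genes (the leading
#' ortholog groups) are sustained DE, alternating up/down, in every
#' species.
#'
#' @param config a [GeneratorConfig-class].
#' @return list with `counts` (named list of [TimeCourseExperiment-class]),
#'   `truth` (data.frame `species, gene_id, pattern`) and `de_truth`
#'   (named list of logical genes x time matrices marking planted DE
#'   cells).
#' @export
generateTimecourseCounts <- function(config) {
  methods::validObject(config)
  set.seed(config@seed + 1)
  counts <- list()
  truth <- list()
  de_truth <- list()
  labels <- .plantPatterns(config)
  for (sp in config@species) {
    tp <- config@time_grids[[sp]]
    nt <- length(tp)
    ## phases are needed only to place transient pulses; sustained-only
    ## configurations work on grids too short for a phase assignment
    phases <- if (any(labels %in% c("EU", "ED")))
      defaultPhaseSpec(sp, tp) else NULL
    mult <- matrix(1, config@n_genes, nt)
    for (g in which(labels != "NULL")) {
      lab <- labels[g]
      eff <- 2^(config@effect_size * if (lab %in% c("EU", "LU")) 1 else -1)
      idx <- if (lab %in% c("EU", "ED")) phases@early else 2:nt
      mult[g, idx] <- eff
    }
    mu <- config@baseline_mean * mult
    m <- matrix(if (config@dispersion == 0)
      stats::rpois(length(mu), lambda = mu)
      else stats::rnbinom(length(mu), size = 1 / config@dispersion,
                          mu = mu),
      nrow = config@n_genes)
    rownames(m) <- .geneIds(sp, config@n_genes)
    counts[[sp]] <- TimeCourseExperiment(m, time_h = tp, species = sp)
    truth[[sp]] <- data.frame(species = sp, gene_id = rownames(m),
                              pattern = labels, stringsAsFactors = FALSE)
    de <- mult != 1
    dimnames(de) <- list(rownames(m), NULL)
    de_truth[[sp]] <- de
  }
  list(counts = counts, truth = do.call(rbind, truth), de_truth = de_truth)
}

#' Default phase specification for a generated species
#'
#' The sea-cucumber-like sparse grid uses a single early time point and a
#' 14-day recovery; dense grids use the default two-early/two-late rule
#' with 24 h recovery.
#'
#' @param species species tag.
#' @param time_points_h its time grid.
#' @return a [PhaseSpec-class].
#' @export
defaultPhaseSpec <- function(species, time_points_h) {
  if (species == "seacucumber" ||
      (length(time_points_h) >= 2 && time_points_h[2] >= 48))
    assignPhases(time_points_h, species, early = 2L, recovery_h = 14 * 24)
  else
    assignPhases(time_points_h, species)
}

#' Generate noisy log2FC profiles with planted pattern labels
#'
#' Profiles on the four canonical pulse shapes: transient pulses of
#' `+-effect` on the early indices (recovering to 0), sustained ramps of
#' `+-effect` from the first non-baseline point, plus Gaussian noise on the
#' non-baseline entries. DE flags mark the planted (noise-free) DE
#' positions.
#'
#' @param n_per_pattern genes per pattern (default 50).
#' @param effect planted |log2FC| (default 3).
#' @param noise_sd Gaussian noise sd on log2FC (default 0.2).
#' @param phases a [PhaseSpec-class]; its grid length sets the profile
#'   length.
#' @param n_timepoints number of time points (used only when `phases` is
#'   `NULL`; default 7, with default phases).
#' @return list with `log2fc` (matrix), `is_de` (logical matrix), `truth`
#'   (character vector of planted labels).
#' @export
generatePatternProfiles <- function(n_per_pattern = 50L, effect = 3,
                                    noise_sd = 0.2, phases = NULL,
                                    n_timepoints = 7L) {
  if (is.null(phases))
    phases <- assignPhases(seq(0, by = 6, length.out = n_timepoints),
                           "profiles")
  nt <- max(c(phases@late, phases@recovery))
  labels <- rep(c("EU", "ED", "LU", "LD"), each = n_per_pattern)
  n <- length(labels)
  lfc <- matrix(0, n, nt)
  de <- matrix(FALSE, n, nt)
  for (i in seq_len(n)) {
    sgn <- if (labels[i] %in% c("EU", "LU")) 1 else -1
    idx <- if (labels[i] %in% c("EU", "ED")) phases@early else 2:nt
    lfc[i, idx] <- sgn * effect
    de[i, idx] <- TRUE
  }
  noise <- matrix(stats::rnorm(n * (nt - 1L), sd = noise_sd), n, nt - 1L)
  lfc[, -1L] <- lfc[, -1L] + noise
  rownames(lfc) <- rownames(de) <- sprintf("p_%s_%03d", labels,
                                           stats::ave(seq_len(n),
                                                      labels,
                                                      FUN = seq_along))
  list(log2fc = lfc, is_de = de, truth = labels)
}

#' Generate signature lists with controlled overlap
#'
#' Emits three macrophage-style source lists sharing exactly
#' `n_signature_shared` accessions (plus a block shared by exactly two
#' lists and per-list unique members), and grouped per-dataset DE lists
#' (four murine-style, eight human-style) with planted consensus members,
#' so the shared-members and consensus-signature truths are known by
#' construction.
#'
#' @param config a [GeneratorConfig-class].
#' @param universe output of [generateReferenceUniverse()].
#' @return list with `source_lists` (3 named lists), `consensus_groups`
#'   (named list of grouped per-dataset lists), and `truth` (list with
#'   `shared_all`, `shared_two`, `consensus`).
#' @export
generateSignatureFixture <- function(config, universe) {
  methods::validObject(config)
  set.seed(config@seed + 2)
  human_acc <- universe$accession[universe$species == "human"]
  k <- config@n_signature_shared
  need <- k + 6L + 3L * 4L + 6L + 10L
  if (length(human_acc) < need)
    stop("universe holds too few human accessions for the signature fixture")
  pool <- rev(human_acc)  # keep clear of the planted ortholog accessions
  shared_all <- pool[seq_len(k)]
  shared_two <- pool[k + seq_len(6L)]
  uniq <- split(pool[k + 6L + seq_len(12L)], rep(1:3, each = 4L))
  ## each shared_two member sits in exactly two of the three lists:
  ## 1:2 in A&B, 3:4 in A&C, 5:6 in B&C
  source_lists <- list(
    groupA = c(shared_all, shared_two[1:4], uniq[[1]]),
    groupB = c(shared_all, shared_two[c(1, 2, 5, 6)], uniq[[2]]),
    groupC = c(shared_all, shared_two[3:6], uniq[[3]]))
  cons_pool <- pool[k + 18L + seq_len(16L)]
  cons_murine <- cons_pool[1:4]    # planted in >= 2 of 4 murine lists
  cons_human <- cons_pool[5:8]     # planted in >= 3 of 8 human lists
  weak <- cons_pool[9:16]          # below both thresholds
  murine <- lapply(1:4, function(i)
    c(cons_murine[(i %% 2) + c(1, 3)], weak[i]))
  human <- lapply(1:8, function(i)
    c(cons_human[((i + 0:2) %% 4) + 1], weak[((i + 3) %% 8) + 1]))
  names(murine) <- sprintf("murine_ds%d", 1:4)
  names(human) <- sprintf("human_ds%d", 1:8)
  list(source_lists = source_lists,
       consensus_groups = list(murine = murine, human = human),
       truth = list(shared_all = sort(shared_all),
                    shared_two = sort(shared_two),
                    consensus = sort(c(cons_murine, cons_human))))
}

#' Write a complete synthetic fixture directory
#'
#' Emits per-species hit tables and count matrices, signature list files,
#' a ground-truth JSON, and a ready-to-run pipeline configuration YAML
#' (hydra-like species gets the reduced |log2FC| cutoff of 0.5; the
#' sparse-grid species the single-early-point phase override).
#'
#' @param config a [GeneratorConfig-class].
#' @param out_dir directory to create/populate.
#' @return (invisibly) list with the written `paths`, the `truth` tables
#'   and the in-memory objects.
#' @export
generateFixture <- function(config, out_dir) {
  methods::validObject(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  universe <- generateReferenceUniverse(config)
  ht <- generateHitTables(config, universe)
  tc <- generateTimecourseCounts(config)
  sig <- generateSignatureFixture(config, universe)
  paths <- list()
  species_cfg <- list()
  for (sp in config@species) {
    hp <- file.path(out_dir, sprintf("hits_%s.tsv", sp))
    cp <- file.path(out_dir, sprintf("counts_%s.tsv", sp))
    writeHitTable(ht$hits[[sp]], hp)
    writeCounts(tc$counts[[sp]], cp)
    paths[[sprintf("hits_%s", sp)]] <- hp
    paths[[sprintf("counts_%s", sp)]] <- cp
    sp_cfg <- list(hits = basename(hp), counts = basename(cp))
    if (sp == "hydra") sp_cfg$de <- list(fc_threshold = 0.5)
    if (sp == "seacucumber")
      sp_cfg$phases <- list(early = 2L, recovery_h = 336)
    species_cfg[[sp]] <- sp_cfg
  }
  sig_paths <- list()
  for (nm in names(sig$source_lists)) {
    p <- file.path(out_dir, sprintf("signature_%s.txt", nm))
    writeLines(c(sprintf("# synthetic signature source list %s", nm),
                 sig$source_lists[[nm]]), p)
    sig_paths[[nm]] <- basename(p)
    paths[[sprintf("signature_%s", nm)]] <- p
  }
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(ortholog_groups = ht$truth, patterns = tc$truth,
         signature = sig$truth),
    truth_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths$truth <- truth_path
  cfg_yaml <- list(seed = config@seed, out_dir = "results",
                   thresholds = list(permissive_sig = 1e-2,
                                     strict_sig = 1e-15,
                                     identity = 0.8, overlap = 0.8),
                   taxon_allow = list("Eukaryota"),
                   species = species_cfg,
                   signatures = sig_paths)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg_yaml, cfg_path)
  paths$config <- cfg_path
  invisible(list(paths = paths, universe = universe, hits = ht$hits,
                 counts = tc$counts, signature = sig,
                 truth = list(orthologs = ht$truth, patterns = tc$truth,
                              de = tc$de_truth, signature = sig$truth)))
}
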