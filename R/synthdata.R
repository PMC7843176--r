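# Synthetic cohort generator. Emulates the statistical structure the
# REO-based pipeline assumes: a normal compendium with strong reproducible
# between-gene orderings plus inter-individual noise; tumor samples in
# which chosen genes are shifted up/down in a chosen fraction of samples;
# monotone-distorted "platform" views; and paired methylation with planted
# hypermethylation. All generation happens on the log2 scale with additive
# Gaussian noise.

# One global seed is expanded into independent per-stream seeds by a fixed
# affine-mod scheme so the streams (baselines, normal noise, tumor noise,
# plant draws, ...) are reproducible yet decoupled.
stream_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 131071 + as.double(stream) * 524287) %% 2147483629)
}

default_gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Describe a synthetic cohort
#'
#' Fixes the generative model: per-gene baselines are drawn once from
#' `Normal(8, baseline_spread)` (log2 scale) and every sample value is
#' baseline plus `Normal(0, noise_sd)` noise. Planted genes are shifted by
#' `+effect` (up) or `-effect` (down) in an independently Bernoulli-chosen
#' fraction of tumor samples.
#'
#' @param n_genes Number of genes.
#' @param n_normal Number of normal samples.
#' @param n_tumor Number of tumor samples (or tumor-normal pairs).
#' @param planted_up,planted_down Data frames with columns `gene`
#'   (ID or index), `frequency` (in `[0,1]`) and `effect` (log2 units), or
#'   `NULL`.
#' @param noise_sd Per-sample Gaussian noise SD, log2 units.
#' @param baseline_spread SD of the per-gene baseline draw, log2 units.
#' @param seed Integer seed; every generator is a pure function of
#'   (design, seed).
#' @param baseline_seed Seed of the per-gene baseline draw (defaults to
#'   `seed`). Cohorts describing the same biological system - e.g. a normal
#'   compendium, tumors, and a validation cohort - must share it so their
#'   genes have identical baselines.
#' @return Object of class `CohortDesign`.
#' @export
cohort_design <- function(n_genes, n_normal, n_tumor,
                          planted_up = NULL, planted_down = NULL,
                          noise_sd = 0.5, baseline_spread = 2.0,
                          seed = 1L, baseline_seed = seed) {
  norm_plant <- function(p) {
    if (is.null(p) || NROW(p) == 0L)
      return(data.frame(gene = character(0L), frequency = numeric(0L),
                        effect = numeric(0L), stringsAsFactors = FALSE))
    p <- as.data.frame(p, stringsAsFactors = FALSE)
    stopifnot(all(c("gene", "frequency", "effect") %in% names(p)))
    if (is.numeric(p$gene)) {
      if (any(p$gene < 1 | p$gene > n_genes))
        stop("planted gene index out of range")
      p$gene <- default_gene_ids(n_genes)[p$gene]
    }
    if (any(p$frequency < 0 | p$frequency > 1))
      stop("planted frequencies must lie in [0, 1]")
    if (any(p$frequency > 0 & p$effect == 0))
      stop("a gene planted with frequency > 0 must have a nonzero effect")
    p
  }
  up <- norm_plant(planted_up)
  dn <- norm_plant(planted_down)
  if (length(intersect(up$gene, dn$gene)))
    stop("a gene cannot be planted both up and down")
  if (noise_sd < 0 || baseline_spread < 0)
    stop("noise_sd and baseline_spread must be non-negative")
  structure(list(n_genes = as.integer(n_genes), n_normal = as.integer(n_normal),
                 n_tumor = as.integer(n_tumor), planted_up = up,
                 planted_down = dn, noise_sd = noise_sd,
                 baseline_spread = baseline_spread, seed = as.integer(seed),
                 baseline_seed = as.integer(baseline_seed),
                 gene_ids = default_gene_ids(n_genes)),
            class = "CohortDesign")
}

design_baselines <- function(design) {
  set.seed(stream_seed(design$baseline_seed, 1L))
  setNames(rnorm(design$n_genes, mean = 8, sd = design$baseline_spread),
           design$gene_ids)
}

noise_matrix <- function(n_genes, n_samples, sd) {
  if (sd == 0) matrix(0, n_genes, n_samples)
  else matrix(rnorm(n_genes * n_samples, sd = sd), n_genes, n_samples)
}

#' Generate a normal-tissue reference compendium
#'
#' @param design A `CohortDesign`; needs `n_normal >= 2` because stable-REO
#'   testing requires at least two samples.
#' @return A log2-scale `ExpressionMatrix` (platform `"synthetic"`).
#' @export
generate_normal_cohort <- function(design) {
  stopifnot(inherits(design, "CohortDesign"))
  if (design$n_normal < 2L) stop("need n_normal >= 2")
  mu <- design_baselines(design)
  set.seed(stream_seed(design$seed, 2L))
  vals <- mu + noise_matrix(design$n_genes, design$n_normal, design$noise_sd)
  dimnames(vals) <- list(design$gene_ids, sprintf("n%03d", seq_len(design$n_normal)))
  expression_matrix(vals, platform = "synthetic", log_scale = TRUE)
}

# Plant per-sample effects into a tumor matrix; returns list(values, status).
plant_effects <- function(vals, design) {
  status <- matrix("NONE", nrow(vals), ncol(vals), dimnames = dimnames(vals))
  apply_plant <- function(p, sign, label) {
    for (r in seq_len(NROW(p))) {
      g <- p$gene[r]
      hit <- runif(ncol(vals)) < p$frequency[r]
      vals[g, hit] <<- vals[g, hit] + sign * abs(p$effect[r])
      status[g, hit] <<- label
    }
  }
  apply_plant(design$planted_up, +1, "UP")
  apply_plant(design$planted_down, -1, "DOWN")
  list(values = vals, status = status)
}

synthetic_truth <- function(status) {
  structure(list(status = status,
                 frequency = rowSums(status != "NONE") / ncol(status)),
            class = "SyntheticTruth")
}

#' Generate a paired tumor-normal cohort with recorded truth
#'
#' Each of the `n_tumor` patients contributes a normal column (baseline +
#' noise) and a tumor column (same per-gene baseline + fresh noise + the
#' planted effect, applied independently per sample at the planted
#' frequency). The realized per-sample truth and its exact per-gene
#' frequency are returned alongside the cohort.
#'
#' @param design A `CohortDesign`.
#' @return List with elements `cohort` (a `PairedCohort`) and `truth`
#'   (a `SyntheticTruth`: status matrix over UP/DOWN/NONE plus realized
#'   per-gene frequency).
#' @export
generate_paired_cohort <- function(design) {
  stopifnot(inherits(design, "CohortDesign"))
  if (design$n_tumor < 1L) stop("need n_tumor >= 1")
  mu <- design_baselines(design)
  n <- design$n_tumor
  set.seed(stream_seed(design$seed, 3L))
  nv <- mu + noise_matrix(design$n_genes, n, design$noise_sd)
  set.seed(stream_seed(design$seed, 4L))
  tv <- mu + noise_matrix(design$n_genes, n, design$noise_sd)
  dimnames(nv) <- list(design$gene_ids, sprintf("pn%03d", seq_len(n)))
  dimnames(tv) <- list(design$gene_ids, sprintf("pt%03d", seq_len(n)))
  set.seed(stream_seed(design$seed, 5L))
  planted <- plant_effects(tv, design)
  cohort <- paired_cohort(
    tumor = expression_matrix(planted$values, "synthetic", TRUE),
    normal = expression_matrix(nv, "synthetic", TRUE),
    pairing = data.frame(tumor = colnames(tv), normal = colnames(nv),
                         stringsAsFactors = FALSE))
  list(cohort = cohort, truth = synthetic_truth(planted$status))
}

#' Generate an unpaired tumor cohort with recorded truth
#'
#' Same tumor generative model as [generate_paired_cohort()] but without
#' matched normals; used to emulate the large unpaired cohort that the
#' REO-based individual-level caller is applied to.
#'
#' @param design A `CohortDesign`.
#' @return List with elements `tumor` (an `ExpressionMatrix`) and `truth`.
#' @export
generate_tumor_cohort <- function(design) {
  stopifnot(inherits(design, "CohortDesign"))
  if (design$n_tumor < 1L) stop("need n_tumor >= 1")
  mu <- design_baselines(design)
  set.seed(stream_seed(design$seed, 6L))
  tv <- mu + noise_matrix(design$n_genes, design$n_tumor, design$noise_sd)
  dimnames(tv) <- list(design$gene_ids, sprintf("t%04d", seq_len(design$n_tumor)))
  set.seed(stream_seed(design$seed, 7L))
  planted <- plant_effects(tv, design)
  list(tumor = expression_matrix(planted$values, "synthetic", TRUE),
       truth = synthetic_truth(planted$status))
}

#' Distorted platform view of a cohort
#'
#' Applies a strictly monotone increasing map to every value (so all
#' within-sample orderings are preserved when `extra_noise_sd = 0`) plus
#' fresh Gaussian noise, emulating a second measurement platform.
#'
#' @param matrix An `ExpressionMatrix`.
#' @param distortion_id One of `"affine"`, `"cube"`, `"exp"`; becomes the
#'   output platform label.
#' @param extra_noise_sd SD of platform-specific noise added after the map.
#' @param seed Integer seed for the noise.
#' @param a,b Slope (`a > 0`) and intercept of the affine map.
#' @return An `ExpressionMatrix` with platform set to `distortion_id`.
#' @export
generate_platform_view <- function(matrix, distortion_id = c("affine", "cube", "exp"),
                                   extra_noise_sd = 0, seed = 1L, a = 1, b = 0) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  distortion_id <- match.arg(distortion_id)
  if (distortion_id == "affine" && a <= 0) stop("affine slope must be positive")
  v <- matrix$values
  v <- switch(distortion_id,
              affine = a * v + b,
              cube = sign(v - 8) * abs(v - 8)^3 + 8,
              exp = 2^(v / 4))
  set.seed(stream_seed(seed, 11L))
  v <- v + noise_matrix(nrow(v), ncol(v), extra_noise_sd)
  expression_matrix(v, platform = distortion_id, log_scale = matrix$log_scale)
}

#' Generate a paired methylation cohort with planted hypermethylation
#'
#' Beta values in `[0,1]`. For each planted gene exactly
#' `round(frequency * n_pairs)` pairs are raised (tumor beta strictly above
#' the paired normal beta) and the remaining pairs lowered, so the
#' hypermethylation frequency is exact by construction. Unplanted genes
#' receive symmetric tumor-normal perturbations (frequency near 0.5).
#'
#' @param n_genes,n_pairs Dimensions.
#' @param planted_hyper Named numeric vector: gene ID -> planted frequency.
#' @param seed Integer seed.
#' @param effect Size of the planted beta shift.
#' @param noise_sd SD of the symmetric tumor-normal perturbation.
#' @return A `PairedCohort` of beta values (`log_scale = FALSE`, platform
#'   `"methylation"`), with the planted frequency table in
#'   `attr(, "truth")`.
#' @export
generate_methylation_cohort <- function(n_genes, n_pairs, planted_hyper = NULL,
                                        seed = 1L, effect = 0.15, noise_sd = 0.03) {
  genes <- default_gene_ids(n_genes)
  set.seed(stream_seed(seed, 21L))
  nv <- matrix(rbeta(n_genes * n_pairs, 2, 5) * 0.7 + 0.1, n_genes, n_pairs)
  set.seed(stream_seed(seed, 22L))
  delta <- matrix(rnorm(n_genes * n_pairs, sd = noise_sd), n_genes, n_pairs)
  tv <- nv + delta
  truth <- setNames(numeric(0L), character(0L))
  if (!is.null(planted_hyper) && length(planted_hyper)) {
    stopifnot(!is.null(names(planted_hyper)),
              all(names(planted_hyper) %in% genes),
              all(planted_hyper >= 0 & planted_hyper <= 1))
    set.seed(stream_seed(seed, 23L))
    for (g in names(planted_hyper)) {
      gi <- match(g, genes)
      n_raised <- as.integer(round(planted_hyper[[g]] * n_pairs))
      raised <- sample.int(n_pairs, n_raised)
      tv[gi, ] <- pmax(0, nv[gi, ] - abs(delta[gi, ]) - effect)
      tv[gi, raised] <- pmin(1, nv[gi, raised] + abs(delta[gi, raised]) + effect)
      truth[g] <- n_raised / n_pairs
    }
  }
  tv <- pmin(pmax(tv, 0), 1)
  dimnames(nv) <- list(genes, sprintf("mn%03d", seq_len(n_pairs)))
  dimnames(tv) <- list(genes, sprintf("mt%03d", seq_len(n_pairs)))
  out <- paired_cohort(
    tumor = expression_matrix(tv, "methylation", FALSE),
    normal = expression_matrix(nv, "methylation", FALSE),
    pairing = data.frame(tumor = colnames(tv), normal = colnames(nv),
                         stringsAsFactors = FALSE))
  attr(out, "truth") <- truth
  out
}

#' Generate toy knowledgebases (gene sets, PPI network, cancer genes)
#'
#' Uniform random draws over a gene universe, deterministic given the seed.
#' Optionally plants chosen genes into one dedicated gene set so enrichment
#' recovery can be tested.
#'
#' @param genes Gene universe: either a character vector of IDs or an
#'   integer count (IDs are then auto-generated).
#' @param n_sets Number of random gene sets.
#' @param set_size_range Length-2 integer range of set sizes.
#' @param n_edges Number of random undirected edges.
#' @param n_cancer_genes Number of genes sampled as the cancer-gene list.
#' @param seed Integer seed.
#' @param plant Optional list with elements `genes` (IDs to plant) and
#'   `size` (total size of the planted set, filled with random genes);
#'   the planted set is named `"planted_set"`.
#' @return List with elements `collection` (a `GeneSetCollection`),
#'   `network` (a `PpiNetwork`) and `cancer_genes` (character vector).
#' @export
generate_toy_knowledge <- function(genes, n_sets = 20L, set_size_range = c(5L, 20L),
                                   n_edges = 200L, n_cancer_genes = 30L,
                                   seed = 1L, plant = NULL) {
  if (is.numeric(genes) && length(genes) == 1L) genes <- default_gene_ids(genes)
  genes <- as.character(genes)
  n <- length(genes)
  set.seed(stream_seed(seed, 31L))
  sizes <- sample(set_size_range[1L]:set_size_range[2L], n_sets, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(genes, min(k, n)))
  names(sets) <- sprintf("set%03d", seq_len(n_sets))
  if (!is.null(plant)) {
    stopifnot(all(plant$genes %in% genes))
    size <- max(length(plant$genes), plant$size %||% length(plant$genes))
    filler <- sample(setdiff(genes, plant$genes), size - length(plant$genes))
    sets[["planted_set"]] <- c(plant$genes, filler)
  }
  set.seed(stream_seed(seed, 32L))
  edges <- NULL
  if (n_edges > 0L) {
    from <- sample(genes, 4L * n_edges, replace = TRUE)
    to <- sample(genes, 4L * n_edges, replace = TRUE)
    ok <- from != to
    edges <- cbind(from[ok], to[ok])
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges <- edges[seq_len(min(n_edges, nrow(edges))), , drop = FALSE]
  }
  network <- if (is.null(edges) || nrow(edges) == 0L) {
    structure(list(nodes = character(0L),
                   edges = data.frame(from = character(0L), to = character(0L),
                                      stringsAsFactors = FALSE)),
              class = "PpiNetwork")
  } else suppressMessages(ppi_network(edges))
  set.seed(stream_seed(seed, 33L))
  cancer <- sample(genes, min(n_cancer_genes, n))
  list(collection = gene_set_collection(sets),
       network = network, cancer_genes = cancer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
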