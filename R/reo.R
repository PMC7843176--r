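# Stable relative expression orderings (REOs). For every gene pair (a, b)
# the orientation a > b is counted across a normal compendium; a pair is
# significantly stable when the majority orientation beats a Binomial(n,
# 0.5) null (two-sided exact test by doubled smaller tail, ties excluded
# from n) after BH FDR control across all tested pairs. Stable REO sets
# from two platforms are intersected, keeping only orientation-consistent
# pairs.

# All unordered pairs (i < j) over G genes, without materializing a G x G
# matrix: pairs are stored as packed integer index vectors so memory is
# O(#pairs).
pair_indices <- function(G) {
  stopifnot(G >= 2L)
  list(i = sequence(seq_len(G - 1L)),
       j = rep.int(2:G, seq_len(G - 1L)))
}

#' Orientation counts for every gene pair
#'
#' For each unordered pair of genes (a, b), counts the samples in which
#' a > b, a < b and a = b. Counts always sum to the number of samples.
#'
#' @param matrix An `ExpressionMatrix` with at least 2 genes.
#' @param chunk_size Pairs processed per block (memory knob).
#' @return Data frame with columns `i`, `j` (row indices into the gene
#'   universe, `i < j`), `k_gt` (samples with gene i > gene j), `k_lt`,
#'   `k_tie`.
#' @export
pair_orientation_counts <- function(matrix, chunk_size = 2e6) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  v <- matrix$values
  G <- nrow(v)
  idx <- pair_indices(G)
  np <- length(idx$i)
  k_gt <- integer(np); k_lt <- integer(np)
  starts <- seq(1L, np, by = as.integer(chunk_size))
  for (s in starts) {
    e <- min(np, s + as.integer(chunk_size) - 1L)
    vi <- v[idx$i[s:e], , drop = FALSE]
    vj <- v[idx$j[s:e], , drop = FALSE]
    k_gt[s:e] <- rowSums(vi > vj)
    k_lt[s:e] <- rowSums(vi < vj)
  }
  data.frame(i = idx$i, j = idx$j, k_gt = k_gt, k_lt = k_lt,
             k_tie = ncol(v) - k_gt - k_lt)
}

# Two-sided exact binomial p against p = 0.5: doubled smaller tail, capped
# at 1. Vectorized; n = 0 gives p = 1.
binom_reo_p <- function(k_major, n) {
  k_minor <- n - k_major
  p <- pmin(1, 2 * stats::pbinom(pmin(k_major, k_minor), n, 0.5))
  p[n == 0L] <- 1
  p
}

#' Significantly stable REOs of a normal compendium
#'
#' Per pair, a two-sided exact binomial test of the majority orientation
#' count against `Binomial(n_eff, 0.5)`, where `n_eff` excludes tied
#' samples; BH FDR across all tested pairs jointly. Significant pairs are
#' stored in their majority orientation `a > b`.
#'
#' @param matrix An `ExpressionMatrix` with `>= 2` samples.
#' @param alpha_fdr FDR threshold.
#' @return Object of class `StableReoSet`: `gene_universe` (the matrix's
#'   gene IDs, in order), `pairs` (data frame `a`, `b`, `k`, `n`: integer
#'   indices into the universe with gene a stably above gene b, supported by
#'   `k` of `n` untied samples), `platform`, `n_samples`, `alpha_fdr`.
#' @export
stable_reos <- function(matrix, alpha_fdr = 0.05) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (ncol(matrix$values) < 2L) stop("stable-REO testing needs >= 2 samples")
  counts <- pair_orientation_counts(matrix)
  n_eff <- counts$k_gt + counts$k_lt
  k_major <- pmax(counts$k_gt, counts$k_lt)
  tested <- n_eff > 0L
  p <- binom_reo_p(k_major[tested], n_eff[tested])
  q <- bh_fdr(p)
  sig <- q < alpha_fdr
  ct <- counts[tested, , drop = FALSE][sig, , drop = FALSE]
  fwd <- ct$k_gt >= ct$k_lt   # significance forces k_gt != k_lt
  pairs <- data.frame(a = ifelse(fwd, ct$i, ct$j),
                      b = ifelse(fwd, ct$j, ct$i),
                      k = pmax(ct$k_gt, ct$k_lt),
                      n = ct$k_gt + ct$k_lt)
  structure(list(gene_universe = gene_ids(matrix), pairs = pairs,
                 platform = matrix$platform, n_samples = ncol(matrix$values),
                 alpha_fdr = alpha_fdr),
            class = "StableReoSet")
}

#' @export
print.StableReoSet <- function(x, ...) {
  cat(sprintf("StableReoSet: %d stable pairs over %d genes (platform '%s', n = %d)\n",
              nrow(x$pairs), length(x$gene_universe), x$platform, x$n_samples))
  invisible(x)
}

#' Intersect two stable REO sets across platforms
#'
#' The gene universe becomes the intersection of the two universes; the
#' retained pairs are those present in both sets with the same orientation.
#' Overlapping pairs with conflicting orientation are dropped, counted and
#' reported via `attr(, "n_conflicts")`. Support columns from both cohorts
#' are carried (`k_a`, `n_a`, `k_b`, `n_b`).
#'
#' @param set_a,set_b `StableReoSet` objects.
#' @return A `StableReoSet` on the common universe with both cohorts'
#'   support; also carries `attr(, "n_overlap")`.
#' @export
intersect_stable_reos <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "StableReoSet"), inherits(set_b, "StableReoSet"))
  universe <- intersect(set_a$gene_universe, set_b$gene_universe)
  to_names <- function(s) {
    ga <- s$gene_universe[s$pairs$a]
    gb <- s$gene_universe[s$pairs$b]
    keep <- ga %in% universe & gb %in% universe
    data.frame(ga = ga[keep], gb = gb[keep],
               k = s$pairs$k[keep], n = s$pairs$n[keep],
               stringsAsFactors = FALSE)
  }
  pa <- to_names(set_a)
  pb <- to_names(set_b)
  key <- function(x, y) paste(x, y, sep = "\r")
  m_same <- match(key(pa$ga, pa$gb), key(pb$ga, pb$gb))
  m_flip <- match(key(pa$ga, pa$gb), key(pb$gb, pb$ga))
  same <- !is.na(m_same)
  n_conflicts <- sum(!is.na(m_flip) & !same)
  if (n_conflicts > 0L)
    message("intersect_stable_reos: dropped ", n_conflicts,
            " orientation-conflicting pair(s)")
  sel <- which(same)
  pairs <- data.frame(a = match(pa$ga[sel], universe),
                      b = match(pa$gb[sel], universe),
                      k = pa$k[sel] + pb$k[m_same[sel]],
                      n = pa$n[sel] + pb$n[m_same[sel]],
                      k_a = pa$k[sel], n_a = pa$n[sel],
                      k_b = pb$k[m_same[sel]], n_b = pb$n[m_same[sel]])
  out <- structure(list(gene_universe = universe, pairs = pairs,
                        platform = paste(set_a$platform, set_b$platform, sep = "+"),
                        n_samples = set_a$n_samples + set_b$n_samples,
                        alpha_fdr = max(set_a$alpha_fdr, set_b$alpha_fdr)),
                   class = "StableReoSet")
  attr(out, "n_conflicts") <- n_conflicts
  attr(out, "n_overlap") <- length(sel) + n_conflicts
  out
}

#' Write a stable REO set to a versioned text file
#'
#' Header lines (`#reo_set v1`, platform, n_samples, gene universe) followed
#' by one `a b k n` record per pair, indices referring to the universe line.
#'
#' @param reos A `StableReoSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reo_set <- function(reos, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("#reo_set v1",
               paste0("#platform\t", reos$platform),
               paste0("#n_samples\t", reos$n_samples),
               paste0("#genes\t", paste(reos$gene_universe, collapse = "\t"))), con)
  writeLines(sprintf("%d\t%d\t%d\t%d", reos$pairs$a, reos$pairs$b,
                     reos$pairs$k, reos$pairs$n), con)
  invisible(path)
}

#' Read a stable REO set written by [write_reo_set()]
#' @param path File path.
#' @return A `StableReoSet`.
#' @export
read_reo_set <- function(path) {
  lines <- readLines(path)
  if (lines[[1L]] != "#reo_set v1") stop("not a v1 REO set file: ", path)
  header <- strsplit(lines[2:4], "\t", fixed = TRUE)
  platform <- header[[1L]][2L]
  n_samples <- as.integer(header[[2L]][2L])
  universe <- header[[3L]][-1L]
  body <- lines[-(1:4)]
  if (length(body)) {
    rec <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE), as.integer))
    pairs <- data.frame(a = rec[, 1L], b = rec[, 2L], k = rec[, 3L], n = rec[, 4L])
  } else {
    pairs <- data.frame(a = integer(0L), b = integer(0L),
                        k = integer(0L), n = integer(0L))
  }
  structure(list(gene_universe = universe, pairs = pairs, platform = platform,
                 n_samples = n_samples, alpha_fdr = NA_real_),
            class = "StableReoSet")
}
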