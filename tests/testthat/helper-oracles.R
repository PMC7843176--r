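# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (explicit loops, stats:: reference functions) and
# share no code with the package implementation.

make_em <- function(vals, genes = NULL, samples = NULL, platform = "test",
                    log_scale = TRUE) {
  vals <- as.matrix(vals)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(vals)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(vals)))
  dimnames(vals) <- list(genes, samples)
  expression_matrix(vals, platform = platform, log_scale = log_scale)
}

make_paired <- function(tumor_vals, normal_vals, genes = NULL) {
  tum <- make_em(tumor_vals, genes = genes,
                 samples = sprintf("T%02d", seq_len(ncol(as.matrix(tumor_vals)))))
  nor <- make_em(normal_vals, genes = genes,
                 samples = sprintf("N%02d", seq_len(ncol(as.matrix(normal_vals)))))
  paired_cohort(tum, nor, data.frame(tumor = sample_ids(tum),
                                     normal = sample_ids(nor),
                                     stringsAsFactors = FALSE))
}

# Hand-build a StableReoSet (a is stably above b).
make_reos <- function(universe, a, b, k = NULL, n = 10L) {
  if (is.null(k)) k <- rep(n, length(a))
  structure(list(gene_universe = universe,
                 pairs = data.frame(a = match(a, universe), b = match(b, universe),
                                    k = k, n = n),
                 platform = "test", n_samples = n, alpha_fdr = 0.05),
            class = "StableReoSet")
}

# Naive per-pair orientation counting by a double loop.
oracle_pair_counts <- function(vals) {
  G <- nrow(vals)
  out <- NULL
  for (i in seq_len(G - 1L)) for (j in (i + 1L):G) {
    gt <- sum(vals[i, ] > vals[j, ])
    lt <- sum(vals[i, ] < vals[j, ])
    out <- rbind(out, data.frame(i = i, j = j, k_gt = gt, k_lt = lt,
                                 k_tie = ncol(vals) - gt - lt))
  }
  out
}

# Independent stable-REO caller: binom.test per pair (two-sided exact test
# against 0.5 is the doubled-tail value at this symmetric null), BH by
# explicit step-up, majority orientation.
oracle_stable_reos <- function(vals, alpha = 0.05) {
  cnt <- oracle_pair_counts(vals)
  tested <- cnt[cnt$k_gt + cnt$k_lt > 0, , drop = FALSE]
  if (nrow(tested) == 0L) return(tested[, c("i", "j")])
  p <- vapply(seq_len(nrow(tested)), function(r)
    stats::binom.test(max(tested$k_gt[r], tested$k_lt[r]),
                      tested$k_gt[r] + tested$k_lt[r], 0.5)$p.value,
    numeric(1L))
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q <- numeric(m); q[ord] <- pmin(1, q_sorted)
  sig <- tested[q < alpha, , drop = FALSE]
  data.frame(a = ifelse(sig$k_gt >= sig$k_lt, sig$i, sig$j),
             b = ifelse(sig$k_gt >= sig$k_lt, sig$j, sig$i))
}

# Upper-tail hypergeometric by direct enumeration of choose() terms.
oracle_hyper_tail <- function(k, K, n, N) {
  xs <- k:min(K, n)
  xs <- xs[xs >= max(0, n - (N - K))]
  if (length(xs) == 0L) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Naive neighbor scan over an edge data frame.
oracle_neighbors <- function(edges, seeds) {
  nb <- character(0L)
  deg <- setNames(rep(0L, length(seeds)), seeds)
  for (r in seq_len(nrow(edges))) {
    f <- edges$from[r]; t <- edges$to[r]
    if (f %in% seeds) { nb <- c(nb, t); deg[f] <- deg[f] + 1L }
    if (t %in% seeds) { nb <- c(nb, f); deg[t] <- deg[t] + 1L }
  }
  list(neighbors = sort(setdiff(unique(nb), seeds)), degrees = deg)
}

# Independent single-sample RankComp: explicit loops, stats::fisher.test,
# stats::p.adjust, per-gene-view partner exclusion, fixed-point iteration.
oracle_call_sample <- function(sample, reos, alpha = 0.05, max_iter = 10L) {
  universe <- reos$gene_universe
  G <- length(universe)
  pr <- reos$pairs
  s <- sample[universe]
  status <- rep("NONE", G)
  for (it in 0:max_iter) {
    p <- rep(NA_real_, G)
    dir <- rep("NONE", G)
    for (g in seq_len(G)) {
      ngN <- nlN <- ngS <- nlS <- 0L
      for (r in seq_len(nrow(pr))) {
        if (pr$a[r] == g && status[pr$b[r]] == "NONE") {
          ngN <- ngN + 1L
          if (s[g] >= s[pr$b[r]]) ngS <- ngS + 1L else nlS <- nlS + 1L
        } else if (pr$b[r] == g && status[pr$a[r]] == "NONE") {
          nlN <- nlN + 1L
          if (s[g] > s[pr$a[r]]) ngS <- ngS + 1L else nlS <- nlS + 1L
        }
      }
      tot <- ngN + nlN
      if (tot == 0L) next
      p[g] <- stats::fisher.test(matrix(c(ngN, nlN, ngS, nlS), 2, byrow = TRUE))$p.value
      if (ngS / tot > ngN / tot) dir[g] <- "UP"
      if (ngS / tot < ngN / tot) dir[g] <- "DOWN"
    }
    q <- rep(NA_real_, G)
    q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
    new_status <- ifelse(!is.na(q) & q < alpha & dir != "NONE", dir, "NONE")
    if (identical(new_status, status)) break
    status <- new_status
  }
  status
}
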