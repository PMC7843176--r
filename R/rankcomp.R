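# RankComp-style individual-level DEG calling. For one cancer sample and a
# stable-REO reference built from normal tissues, each gene g is tested by
# a 2x2 Fisher exact table
#
#     [ n_greater_normal  n_less_normal  ]   <- stable partner orientations
#     [ n_greater_sample  n_less_sample  ]   <- same pairs, re-evaluated
#
# (rows: normal reference, sample; columns: g greater, g less). Genes with
# disproportionately reversed orientations get small p; after BH control a
# significant gene is UP when its in-sample "greater" proportion exceeds
# the normal one, DOWN otherwise. Calling then iterates: pairs whose
# partner gene was called in the previous round are excluded from each
# gene's table, and the procedure repeats to a fixed point.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability rule: the p-value is the sum of hypergeometric
#' probabilities of all tables (with the observed margins) no more likely
#' than the observed one.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `[[a, b], [c, d]]`.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  m <- a + b; n2 <- c + d; k <- a + c
  if (m + n2 == 0L) return(1)
  lo <- max(0L, k - n2); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Vectorized over rows of an integer matrix cbind(a, b, c, d).
fisher_exact_rows <- function(tab) {
  vapply(seq_len(nrow(tab)), function(r)
    fisher_exact_2x2(tab[r, 1L], tab[r, 2L], tab[r, 3L], tab[r, 4L]),
    numeric(1L))
}

#' Call individual-level DEGs for one sample against stable REOs
#'
#' Implements the iterative rank-comparison procedure described above.
#' Ties between the sample value and a partner are assigned to the pair's
#' normal orientation (not counted as reversals). Genes with no stable
#' partner are flagged `unsupported` and never called.
#'
#' @param sample Named numeric vector of the sample's expression values;
#'   must cover the REO set's gene universe.
#' @param reos A `StableReoSet`.
#' @param alpha_fdr Per-iteration BH FDR threshold.
#' @param max_iter Maximum refinement iterations.
#' @return Data frame (one row per universe gene): `gene`,
#'   `n_greater_normal`, `n_less_normal`, `n_greater_sample`,
#'   `n_less_sample`, `p`, `q`, `status` (`UP`/`DOWN`/`NONE`),
#'   `iteration_of_call`, `unsupported`. Attributes: `iterations`,
#'   `converged`.
#' @export
call_sample_degs <- function(sample, reos, alpha_fdr = 0.05, max_iter = 10L) {
  stopifnot(inherits(reos, "StableReoSet"), !is.null(names(sample)))
  universe <- reos$gene_universe
  missing <- setdiff(universe, names(sample))
  if (length(missing))
    stop("sample lacks universe gene(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  s <- sample[universe]
  G <- length(universe)
  pa <- reos$pairs$a
  pb <- reos$pairs$b
  # Normal orientation is a > b; in the sample, a counts as greater when
  # s[a] >= s[b] (ties keep the normal orientation).
  a_greater <- s[pa] >= s[pb]

  called <- rep(FALSE, G)
  status <- rep("NONE", G)
  iter_of_call <- rep(NA_integer_, G)
  tabs <- NULL; p <- q <- rep(NA_real_, G)
  converged <- FALSE
  iterations <- 0L
  for (it in 0:max_iter) {
    use_a <- !called[pb]   # pair usable in gene-a's table: partner b not called
    use_b <- !called[pa]
    ngN <- tabulate(pa[use_a], G) + 0L
    nlN <- tabulate(pb[use_b], G)
    ngS <- tabulate(pa[use_a & a_greater], G) + tabulate(pb[use_b & !a_greater], G)
    tot <- ngN + nlN
    nlS <- tot - ngS
    tabs <- cbind(ngN, nlN, ngS, nlS)
    p <- rep(NA_real_, G)
    testable <- tot > 0L
    p[testable] <- fisher_exact_rows(tabs[testable, , drop = FALSE])
    q <- rep(NA_real_, G)
    q[testable] <- bh_fdr(p[testable])
    new_called <- !is.na(q) & q < alpha_fdr
    prop_n <- ngN / tot
    prop_s <- ngS / tot
    new_status <- rep("NONE", G)
    new_status[new_called & prop_s > prop_n] <- "UP"
    new_status[new_called & prop_s < prop_n] <- "DOWN"
    # equal proportions with q < alpha is unreachable for a 2x2 table;
    # such a gene would stay NONE by construction
    new_called <- new_status != "NONE"
    changed <- which(new_status != status | (new_called & is.na(iter_of_call)))
    iter_of_call[changed] <- it
    iterations <- it
    if (identical(new_called, called) && identical(new_status, status)) {
      converged <- TRUE
      break
    }
    called <- new_called
    status <- new_status
  }
  if (!converged)
    warning("call_sample_degs did not converge within ", max_iter,
            " iterations; reporting the last iteration")
  unsupported <- tabulate(pa, G) + tabulate(pb, G) == 0L
  out <- data.frame(gene = universe,
                    n_greater_normal = tabs[, 1L], n_less_normal = tabs[, 2L],
                    n_greater_sample = tabs[, 3L], n_less_sample = tabs[, 4L],
                    p = p, q = q, status = status,
                    iteration_of_call = iter_of_call,
                    unsupported = unsupported,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "iterations") <- iterations
  attr(out, "converged") <- converged
  out
}

#' RankComp calls for every sample of a tumor matrix
#'
#' Applies [call_sample_degs()] to each column and assembles a call matrix.
#'
#' @param tumor An `ExpressionMatrix` whose genes cover the REO universe.
#' @param reos A `StableReoSet`.
#' @param alpha_fdr,max_iter Passed to [call_sample_degs()].
#' @return A `DegCallMatrix` (see [deg_call_matrix()]) with provenance
#'   `"rankcomp"`, genes = REO universe, samples = tumor columns.
#' @export
rankcomp_calls <- function(tumor, reos, alpha_fdr = 0.05, max_iter = 10L) {
  stopifnot(inherits(tumor, "ExpressionMatrix"))
  universe <- reos$gene_universe
  status <- matrix("NONE", length(universe), ncol(tumor$values),
                   dimnames = list(universe, sample_ids(tumor)))
  for (sid in sample_ids(tumor)) {
    res <- call_sample_degs(setNames(tumor$values[, sid], gene_ids(tumor)),
                            reos, alpha_fdr = alpha_fdr, max_iter = max_iter)
    status[, sid] <- res$status
  }
  deg_call_matrix(status, provenance = "rankcomp")
}

#' Naive mean-reference comparator
#'
#' Calls a gene UP when its value in the sample exceeds the mean of the
#' normal cohort and DOWN otherwise (strict `>`). Provided to demonstrate
#' the pitfall of comparing one tumor against an average normal profile
#' rather than against the patient's own normal state: a gene can sit below
#' its paired normal yet above the cohort mean.
#'
#' @param sample Named numeric vector.
#' @param normal_matrix An `ExpressionMatrix` of normal samples sharing the
#'   gene universe.
#' @return Named character vector over the normal matrix's genes, values
#'   `UP`/`DOWN`.
#' @export
call_vs_mean_reference <- function(sample, normal_matrix) {
  stopifnot(inherits(normal_matrix, "ExpressionMatrix"))
  genes <- gene_ids(normal_matrix)
  missing <- setdiff(genes, names(sample))
  if (length(missing))
    stop("sample lacks gene(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  m <- rowMeans(normal_matrix$values)
  setNames(ifelse(sample[genes] > m, "UP", "DOWN"), genes)
}
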