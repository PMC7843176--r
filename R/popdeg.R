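# Population-level DEG identification on paired cohorts and cross-dataset
# concordance. Genes are tested with a two-sided paired t-test on the
# tumor-normal differences, FDR-adjusted by Benjamini-Hochberg; two
# datasets' DEG lists are compared by direction agreement on their overlap
# under a cumulative binomial null of random agreement (p = 0.5).

#' Benjamini-Hochberg q-values
#'
#' Thin wrapper over the standard step-up adjustment, kept as a named
#' operation because every module of the pipeline FDR-controls through it.
#'
#' @param pvalues Numeric vector of p-values in `[0,1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0L))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Population-level DEGs by paired t-test
#'
#' Per gene, a two-sided paired t-test on the tumor-normal differences with
#' BH adjustment across all tested genes. The direction is the sign of the
#' mean paired difference. Genes whose differences have zero variance are
#' degenerate: their p is set to 1 and they are flagged, never significant.
#'
#' @param cohort A `PairedCohort`.
#' @param alpha_fdr FDR threshold for the `significant` flag.
#' @param method `"paired"` (default) or `"welch"` for an unpaired fallback
#'   comparing the tumor and normal groups.
#' @return Data frame (one row per gene): `gene`, `t`, `p`, `q`,
#'   `direction` (`UP`/`DOWN`/`NA`), `significant`, `degenerate`.
#' @export
paired_t_degs <- function(cohort, alpha_fdr = 0.05, method = c("paired", "welch")) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "PairedCohort"))
  if (nrow(cohort$pairing) < 2L) stop("need at least 2 pairs")
  if (method == "paired") {
    d <- paired_differences(cohort)
    n <- ncol(d)
    m <- rowMeans(d)
    s <- sqrt(rowSums((d - m)^2) / (n - 1L))
    degen <- s == 0
    tstat <- ifelse(degen, NA_real_, m / (s / sqrt(n)))
    p <- ifelse(degen, 1, 2 * stats::pt(-abs(tstat), df = n - 1L))
    dir_mean <- m
  } else {
    tv <- cohort$tumor$values[, cohort$pairing$tumor, drop = FALSE]
    nv <- cohort$normal$values[, cohort$pairing$normal, drop = FALSE]
    n1 <- ncol(tv); n2 <- ncol(nv)
    m1 <- rowMeans(tv); m2 <- rowMeans(nv)
    v1 <- rowSums((tv - m1)^2) / (n1 - 1L)
    v2 <- rowSums((nv - m2)^2) / (n2 - 1L)
    se2 <- v1 / n1 + v2 / n2
    degen <- se2 == 0
    tstat <- ifelse(degen, NA_real_, (m1 - m2) / sqrt(se2))
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
    p <- ifelse(degen, 1, 2 * stats::pt(-abs(tstat), df = df))
    dir_mean <- m1 - m2
  }
  q <- bh_fdr(p)
  direction <- ifelse(dir_mean > 0, "UP", ifelse(dir_mean < 0, "DOWN", NA_character_))
  out <- data.frame(gene = gene_ids(cohort$tumor), t = tstat, p = p, q = q,
                    direction = direction,
                    significant = q < alpha_fdr & !degen,
                    degenerate = degen,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "alpha_fdr") <- alpha_fdr
  class(out) <- c("PopulationDegTable", class(out))
  out
}

#' Concordance of two DEG lists from overlap counts
#'
#' Cumulative binomial concordance score: with `n_overlap` genes
#' significant in both datasets and `n_same` of them agreeing in direction,
#' the p-value is the upper-tail probability `P(X >= n_same)` for
#' `X ~ Binomial(n_overlap, 0.5)` (null of random direction agreement).
#'
#' @param n_overlap Number of genes significant in both lists.
#' @param n_same Number of overlap genes with equal direction.
#' @return Object of class `ConcordanceResult`: list with `n_overlap`,
#'   `n_same_direction`, `percent_same` (`100 * n_same / n_overlap`, `NA`
#'   when the overlap is empty), `p_value`, and `log10_p` (computed in log
#'   space, finite even when `p_value` underflows).
#' @export
concordance_counts <- function(n_overlap, n_same) {
  stopifnot(n_same >= 0, n_overlap >= n_same)
  if (n_overlap == 0L) {
    res <- list(n_overlap = 0L, n_same_direction = 0L,
                percent_same = NA_real_, p_value = 1, log10_p = 0)
  } else {
    log_p <- stats::pbinom(n_same - 1L, n_overlap, 0.5,
                           lower.tail = FALSE, log.p = TRUE)
    res <- list(n_overlap = as.integer(n_overlap),
                n_same_direction = as.integer(n_same),
                percent_same = 100 * n_same / n_overlap,
                p_value = exp(log_p),
                log10_p = log_p / log(10))
  }
  structure(res, class = "ConcordanceResult")
}

#' Concordance of two population-level DEG tables
#'
#' The overlap is the set of genes significant in both tables; direction
#' agreement is counted on the overlap and scored by
#' [concordance_counts()]. Symmetric in its arguments.
#'
#' @param table_a,table_b `PopulationDegTable` objects from
#'   [paired_t_degs()].
#' @return A `ConcordanceResult`.
#' @export
concordance <- function(table_a, table_b) {
  stopifnot(nrow(table_a) > 0L, nrow(table_b) > 0L)
  sig_a <- table_a[table_a$significant, c("gene", "direction")]
  sig_b <- table_b[table_b$significant, c("gene", "direction")]
  common <- intersect(sig_a$gene, sig_b$gene)
  same <- sum(sig_a$direction[match(common, sig_a$gene)] ==
                sig_b$direction[match(common, sig_b$gene)])
  concordance_counts(length(common), same)
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  p_txt <- if (x$p_value == 0) sprintf("10^%.1f", x$log10_p)
           else sprintf("%.3g", x$p_value)
  cat(sprintf("Concordance: %d/%d same direction (%s), binomial p = %s\n",
              x$n_same_direction, x$n_overlap,
              if (is.na(x$percent_same)) "NA" else sprintf("%.2f%%", x$percent_same),
              p_txt))
  invisible(x)
}

#' Reproducible DEGs across two datasets
#'
#' Genes significant in both tables with matching direction; these are the
#' population-level DEG candidates fed to the universality filter.
#'
#' @param table_a,table_b `PopulationDegTable` objects.
#' @return Data frame with columns `gene` and `direction`.
#' @export
reproducible_degs <- function(table_a, table_b) {
  sig_a <- table_a[table_a$significant, c("gene", "direction")]
  sig_b <- table_b[table_b$significant, c("gene", "direction")]
  common <- intersect(sig_a$gene, sig_b$gene)
  da <- sig_a$direction[match(common, sig_a$gene)]
  db <- sig_b$direction[match(common, sig_b$gene)]
  keep <- !is.na(da) & da == db
  data.frame(gene = common[keep], direction = da[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}
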