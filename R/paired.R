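# Individual-level DEG calls from paired tumor-normal samples, and
# per-gene dysregulation frequencies with exact 95% binomial confidence
# intervals. A gene is UP in a patient when its tumor value strictly
# exceeds the paired normal value, DOWN when strictly below, NONE on ties.

#' Construct a per-gene per-sample call matrix
#'
#' @param status Character matrix over `{"UP", "DOWN", "NONE"}` with gene
#'   rownames and sample colnames.
#' @param provenance `"rankcomp"` or `"paired"`.
#' @return Object of class `DegCallMatrix`.
#' @export
deg_call_matrix <- function(status, provenance = c("rankcomp", "paired")) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(status), is.character(status),
            !is.null(rownames(status)), !is.null(colnames(status)))
  bad <- setdiff(unique(as.vector(status)), c("UP", "DOWN", "NONE"))
  if (length(bad)) stop("invalid call value(s): ", paste(bad, collapse = ", "))
  structure(list(status = status, provenance = provenance),
            class = "DegCallMatrix")
}

#' @export
print.DegCallMatrix <- function(x, ...) {
  cat(sprintf("DegCallMatrix (%s): %d genes x %d samples; %d UP, %d DOWN calls\n",
              x$provenance, nrow(x$status), ncol(x$status),
              sum(x$status == "UP"), sum(x$status == "DOWN")))
  invisible(x)
}

#' Individual-level DEG calls by paired comparison
#'
#' A gene is upregulated in a patient when its expression in the cancer
#' tissue is strictly higher than in the paired normal tissue, and
#' downregulated when strictly lower; exact ties give NONE (counted in a
#' message).
#'
#' @param cohort A `PairedCohort`.
#' @return A `DegCallMatrix` with provenance `"paired"`; columns are the
#'   tumor sample IDs in pairing order.
#' @export
paired_calls <- function(cohort) {
  d <- paired_differences(cohort)
  status <- matrix("NONE", nrow(d), ncol(d), dimnames = dimnames(d))
  status[d > 0] <- "UP"
  status[d < 0] <- "DOWN"
  n_ties <- sum(d == 0)
  if (n_ties > 0L)
    message("paired_calls: ", n_ties, " exact tie(s) recorded as NONE")
  deg_call_matrix(status, provenance = "paired")
}

#' Exact binomial confidence interval for a proportion
#'
#' Clopper-Pearson by default: the interval endpoints invert the binomial
#' tails (computed via beta quantiles), with `lo = 0` when `k = 0` and
#' `hi = 1` when `k = n`. The Wilson score interval is available as an
#' alternative.
#'
#' @param k Number of successes (vectorized).
#' @param n Number of trials.
#' @param conf Confidence level.
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @return Two-column matrix `lo`, `hi`, one row per element of `k`.
#' @export
binomial_ci <- function(k, n, conf = 0.95, method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  stopifnot(all(k >= 0), all(k <= n), all(n >= 1), conf > 0, conf < 1)
  alpha <- 1 - conf
  if (method == "clopper-pearson") {
    lo <- ifelse(k == 0, 0, stats::qbeta(alpha / 2, k, n - k + 1))
    hi <- ifelse(k == n, 1, stats::qbeta(1 - alpha / 2, k + 1, n - k))
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    ph <- k / n
    den <- 1 + z^2 / n
    ctr <- (ph + z^2 / (2 * n)) / den
    hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
    lo <- pmax(0, ctr - hw)
    hi <- pmin(1, ctr + hw)
  }
  cbind(lo = lo, hi = hi)
}

#' Per-gene dysregulation frequencies with 95% CIs
#'
#' Frequencies use all samples of the call matrix as the denominator (NONE
#' calls included), matching a per-cohort "fraction of tumors dysregulated"
#' reading; exact binomial CIs are attached for both directions.
#'
#' @param calls A `DegCallMatrix`.
#' @param conf Confidence level for the binomial CIs.
#' @param ci_method Passed to [binomial_ci()].
#' @return Data frame (one row per gene): `gene`, `n`, `n_up`, `n_down`,
#'   `freq_up`, `ci_up_lo`, `ci_up_hi`, `freq_down`, `ci_down_lo`,
#'   `ci_down_hi`.
#' @export
dysregulation_frequency <- function(calls, conf = 0.95,
                                    ci_method = "clopper-pearson") {
  stopifnot(inherits(calls, "DegCallMatrix"))
  st <- calls$status
  if (nrow(st) == 0L || ncol(st) == 0L) stop("empty call matrix")
  n <- ncol(st)
  n_up <- rowSums(st == "UP")
  n_down <- rowSums(st == "DOWN")
  ci_up <- binomial_ci(n_up, n, conf = conf, method = ci_method)
  ci_down <- binomial_ci(n_down, n, conf = conf, method = ci_method)
  data.frame(gene = rownames(st), n = n, n_up = n_up, n_down = n_down,
             freq_up = n_up / n,
             ci_up_lo = ci_up[, "lo"], ci_up_hi = ci_up[, "hi"],
             freq_down = n_down / n,
             ci_down_lo = ci_down[, "lo"], ci_down_hi = ci_down[, "hi"],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Integer percentage, rounded half-up, matching display style "88% (21) of
# the 24".
percent_display <- function(x) as.integer(floor(100 * x + 0.5))
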