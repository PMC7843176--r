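# The universality filter: a population-level DEG candidate qualifies as a
# universal DEG when it is dysregulated in its candidate direction in at
# least `threshold` (default 90%) of tumors in BOTH the unpaired
# (REO-called) cohort and the paired cohort. A held-out paired cohort can
# then be used for validation.

#' Select universal DEGs by the dual-cohort frequency threshold
#'
#' Each candidate gene's direction is fixed by the population-level map;
#' its dysregulation frequency in that direction is looked up in both
#' cohorts' frequency tables (a gene missing from a table counts as
#' frequency 0 and is reported in a message). The gene qualifies iff both
#' frequencies are `>= threshold`.
#'
#' @param freq_unpaired,freq_paired Frequency tables from
#'   [dysregulation_frequency()] for the unpaired (REO-called) and paired
#'   cohorts.
#' @param candidate_genes Data frame with columns `gene` and `direction`
#'   (`UP`/`DOWN`), e.g. from [reproducible_degs()].
#' @param threshold Universality threshold (comparison is `>=`).
#' @return Object of class `UniversalDegList`: a data frame with `gene`,
#'   `direction`, `freq_unpaired`, `ci_unpaired_lo`, `ci_unpaired_hi`,
#'   `freq_paired`, `ci_paired_lo`, `ci_paired_hi`, `qualifying`.
#' @export
select_universal <- function(freq_unpaired, freq_paired, candidate_genes,
                             threshold = 0.90) {
  candidate_genes <- as.data.frame(candidate_genes, stringsAsFactors = FALSE)
  if (nrow(candidate_genes) == 0L) stop("empty candidate map")
  stopifnot(all(c("gene", "direction") %in% names(candidate_genes)),
            all(candidate_genes$direction %in% c("UP", "DOWN")),
            threshold > 0, threshold <= 1)
  lookup <- function(tab, genes, dirs) {
    m <- match(genes, tab$gene)
    up <- dirs == "UP"
    freq <- ifelse(up, tab$freq_up[m], tab$freq_down[m])
    lo <- ifelse(up, tab$ci_up_lo[m], tab$ci_down_lo[m])
    hi <- ifelse(up, tab$ci_up_hi[m], tab$ci_down_hi[m])
    n_missing <- sum(is.na(m))
    if (n_missing > 0L)
      message("select_universal: ", n_missing,
              " candidate(s) missing from a frequency table; treated as frequency 0")
    freq[is.na(m)] <- 0; lo[is.na(m)] <- 0; hi[is.na(m)] <- 0
    data.frame(freq = freq, lo = lo, hi = hi)
  }
  fu <- lookup(freq_unpaired, candidate_genes$gene, candidate_genes$direction)
  fp <- lookup(freq_paired, candidate_genes$gene, candidate_genes$direction)
  out <- data.frame(gene = candidate_genes$gene,
                    direction = candidate_genes$direction,
                    freq_unpaired = fu$freq,
                    ci_unpaired_lo = fu$lo, ci_unpaired_hi = fu$hi,
                    freq_paired = fp$freq,
                    ci_paired_lo = fp$lo, ci_paired_hi = fp$hi,
                    qualifying = fu$freq >= threshold & fp$freq >= threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "threshold") <- threshold
  class(out) <- c("UniversalDegList", class(out))
  out
}

#' Validate universal DEGs on a held-out paired cohort
#'
#' Re-runs the paired per-sample caller and the frequency computation on
#' the validation cohort, restricted to the qualifying universal genes, and
#' reports each gene's validation frequency with a pass/fail at a
#' configurable threshold. Near-threshold misses (within 5 percentage
#' points) are flagged rather than silently failed; genes absent from the
#' validation matrix are flagged `unmeasured` and excluded from pass/fail.
#'
#' @param universal A `UniversalDegList`.
#' @param validation A `PairedCohort` measured independently.
#' @param threshold Validation frequency threshold.
#' @return Data frame: `gene`, `direction`, `n`, `n_called`, `frequency`,
#'   `percent_display` (integer percent, rounded half-up), `pass`,
#'   `near_threshold`, `unmeasured`.
#' @export
validate_on_cohort <- function(universal, validation, threshold = 0.90) {
  stopifnot(inherits(universal, "UniversalDegList"),
            inherits(validation, "PairedCohort"))
  genes <- universal$gene[universal$qualifying]
  dirs <- universal$direction[universal$qualifying]
  if (length(genes) == 0L) stop("no qualifying universal genes to validate")
  measured <- genes %in% gene_ids(validation$tumor)
  n_pairs <- nrow(validation$pairing)
  n_called <- rep(NA_integer_, length(genes))
  if (any(measured)) {
    calls <- paired_calls(validation)
    st <- calls$status[genes[measured], , drop = FALSE]
    n_called[measured] <- vapply(seq_len(nrow(st)), function(r)
      sum(st[r, ] == dirs[measured][r]), integer(1L))
  }
  frequency <- n_called / n_pairs
  out <- data.frame(gene = genes, direction = dirs, n = n_pairs,
                    n_called = n_called, frequency = frequency,
                    percent_display = ifelse(is.na(frequency), NA_integer_,
                                             percent_display(frequency)),
                    pass = frequency >= threshold,
                    near_threshold = !is.na(frequency) & frequency < threshold &
                      frequency >= threshold - 0.05,
                    unmeasured = !measured,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(!measured))
    message("validate_on_cohort: ", sum(!measured), " gene(s) unmeasured in the validation cohort")
  attr(out, "threshold") <- threshold
  out
}
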