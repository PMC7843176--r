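# Readers/writers for the external representations the pipeline consumes:
# expression/methylation matrices (TSV), GMT gene-set collections,
# two-column PPI edge lists and one-ID-per-line gene lists, plus
# probe-to-gene collapsing.

#' Construct a validated expression matrix
#'
#' The universal substrate of the pipeline: a genes-by-samples real matrix
#' with a platform label and a flag declaring whether values are on the
#' log2 scale. Gene and sample identifiers must be unique; all values must
#' be finite.
#'
#' @param values Numeric matrix with row names (gene IDs) and column names
#'   (sample IDs).
#' @param platform Character label of the measuring platform.
#' @param log_scale Logical; `TRUE` when values are log2-transformed.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `platform` and `log_scale`.
#' @export
expression_matrix <- function(values, platform = "unknown", log_scale = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene IDs as rownames and sample IDs as colnames")
  if (nrow(values) < 2L) stop("an ExpressionMatrix needs at least 2 genes")
  if (ncol(values) < 1L) stop("an ExpressionMatrix needs at least 1 sample")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene ID(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample ID(s): ", paste(dup_s, collapse = ", "))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  structure(list(values = values, platform = as.character(platform)[1L],
                 log_scale = isTRUE(log_scale)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (platform '%s', %s scale)\n",
              nrow(x$values), ncol(x$values), x$platform,
              if (x$log_scale) "log2" else "linear"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of gene IDs, in storage order.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Sample identifiers of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of sample IDs, in storage order.
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of sample IDs whose first field is the gene-ID
#' column name (canonically `gene_id`), then one row per gene: gene ID
#' followed by one numeric value per sample. Duplicate gene or sample IDs
#' and non-numeric cells are load errors naming the offending row/column.
#'
#' @param path Path to a TSV file.
#' @param platform Platform label to attach.
#' @param log_scale Whether the stored values are log2-scaled.
#' @return An `ExpressionMatrix`.
#' @export
read_expression_matrix <- function(path, platform = "unknown", log_scale = TRUE) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("malformed expression file '", path, "': need a header plus >= 1 gene row")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    stop("malformed header in '", path, "': expected gene-ID column plus >= 1 sample")
  samples <- header[-1L]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  genes <- vapply(rows, `[[`, character(1L), 1L)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(samples))
  for (r in seq_along(rows)) {
    fields <- rows[[r]][-1L]
    if (length(fields) != length(samples))
      stop(sprintf("row %d (gene '%s') has %d values; expected %d",
                   r, genes[r], length(fields), length(samples)))
    num <- suppressWarnings(as.numeric(fields))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad))
      stop(sprintf("non-numeric or missing cell at gene '%s', sample '%s' (value '%s')",
                   genes[r], samples[bad[1L]], fields[bad[1L]]))
    vals[r, ] <- num
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene ID(s) in '", path, "': ", paste(dup, collapse = ", "))
  rownames(vals) <- genes
  colnames(vals) <- samples
  expression_matrix(vals, platform = platform, log_scale = log_scale)
}

#' Write an expression matrix as canonical TSV
#'
#' The canonical dialect: tab separators, header first field literally
#' `gene_id`, decimal point, no thousands separators. Reading a canonical
#' file and writing it back reproduces it byte-identically.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x$values)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x$values)), function(r) {
    paste(c(rownames(x$values)[r], as.character(x$values[r, ])), collapse = "\t")
  }, character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Collapse a probe-level matrix to gene level
#'
#' When a gene is measured by several probes its expression is the
#' arithmetic mean of those probes, per sample, on the scale the matrix was
#' loaded in. Probes without a mapping are dropped. Output rows are in
#' lexicographic gene order.
#'
#' @param probe_matrix `ExpressionMatrix` keyed by probe IDs.
#' @param probe_to_gene Named character vector: names are probe IDs, values
#'   gene IDs. Every mapped probe must exist in the matrix.
#' @return Gene-level `ExpressionMatrix`.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene) {
  stopifnot(inherits(probe_matrix, "ExpressionMatrix"))
  if (length(probe_to_gene) == 0L) stop("empty probe-to-gene mapping")
  if (is.null(names(probe_to_gene)))
    stop("`probe_to_gene` must be named by probe ID")
  missing <- setdiff(names(probe_to_gene), gene_ids(probe_matrix))
  if (length(missing))
    stop("mapped probe(s) absent from matrix: ", paste(missing, collapse = ", "))
  keep <- intersect(gene_ids(probe_matrix), names(probe_to_gene))
  sub <- probe_matrix$values[keep, , drop = FALSE]
  grp <- as.character(probe_to_gene[keep])
  sums <- rowsum(sub, grp)
  counts <- as.vector(table(grp)[rownames(sums)])
  means <- sums / counts
  means <- means[order(rownames(means)), , drop = FALSE]
  if (nrow(means) < 2L)
    stop("probe collapsing left fewer than 2 genes")
  expression_matrix(means, platform = probe_matrix$platform,
                    log_scale = probe_matrix$log_scale)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (set members).
#' @param descriptions Optional named character vector of set descriptions.
#' @param background Optional explicit gene universe.
#' @return Object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, background = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions,
                 background = background),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, %d unique members\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Members are de-duplicated within each set; a line with
#' fewer than three fields is an error naming the line number.
#'
#' @param path GMT file path.
#' @return A `GeneSetCollection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", short[1L]))
  nm <- vapply(fields, `[[`, character(1L), 1L)
  desc <- vapply(fields, `[[`, character(1L), 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  n_dups <- sum(vapply(members, function(m) length(m) - length(unique(m)), integer(1L)))
  if (n_dups > 0L)
    message("read_gmt: removed ", n_dups, " duplicated member entr",
            if (n_dups == 1L) "y" else "ies")
  gene_set_collection(setNames(members, nm), descriptions = setNames(desc, nm))
}

#' Construct an undirected PPI network
#'
#' Edges are canonicalized as sorted ID pairs; self-loops and duplicate
#' edges (in either orientation) are dropped with a message.
#'
#' @param edges Two-column character matrix or data frame of edge endpoints.
#' @param nodes Optional extra node IDs (isolated nodes).
#' @return Object of class `PpiNetwork` with elements `nodes` and `edges`
#'   (data frame with columns `from`, `to`, `from < to` lexicographically).
#' @export
ppi_network <- function(edges, nodes = NULL) {
  if (is.null(dim(edges))) edges <- matrix(as.character(edges), ncol = 2L)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)[, 1:2]
  names(edges) <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  n_loops <- sum(edges$from == edges$to)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  n_dup <- sum(duplicated(key))
  keep <- !duplicated(key)
  edges <- data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE)
  if (n_loops || n_dup)
    message(sprintf("ppi_network: dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_loops, n_dup))
  nodes <- sort(unique(c(edges$from, edges$to, as.character(nodes))))
  structure(list(nodes = nodes, edges = edges), class = "PpiNetwork")
}

#' @export
print.PpiNetwork <- function(x, ...) {
  cat(sprintf("PpiNetwork: %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a PPI network from a two-column edge list
#'
#' @param path Tab-separated file, two columns per line (extra columns
#'   ignored), no header. An empty file yields an empty network with a
#'   warning.
#' @return A `PpiNetwork`.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty edge list '", path, "': returning empty network")
    return(structure(list(nodes = character(0L),
                          edges = data.frame(from = character(0L), to = character(0L),
                                             stringsAsFactors = FALSE)),
                     class = "PpiNetwork"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short))
    stop(sprintf("edge-list line %d has fewer than 2 fields", short[1L]))
  ppi_network(cbind(vapply(fields, `[[`, character(1L), 1L),
                    vapply(fields, `[[`, character(1L), 2L)))
}

#' Read a one-ID-per-line gene list
#'
#' @param path Text file, one gene ID per line; blank lines skipped.
#' @return Character vector of unique gene IDs.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Construct a paired tumor-normal cohort
#'
#' Both matrices must share an identical, identically ordered gene
#' universe; every pairing entry must reference existing samples and no
#' sample may appear in more than one pair.
#'
#' @param tumor,normal `ExpressionMatrix` objects.
#' @param pairing Data frame with columns `tumor` and `normal` holding
#'   sample IDs.
#' @return Object of class `PairedCohort`.
#' @export
paired_cohort <- function(tumor, normal, pairing) {
  stopifnot(inherits(tumor, "ExpressionMatrix"), inherits(normal, "ExpressionMatrix"))
  if (!identical(gene_ids(tumor), gene_ids(normal)))
    stop("tumor and normal matrices must share identical, ordered gene IDs")
  pairing <- as.data.frame(pairing, stringsAsFactors = FALSE)
  if (!all(c("tumor", "normal") %in% names(pairing)))
    stop("`pairing` needs columns 'tumor' and 'normal'")
  if (nrow(pairing) < 1L) stop("empty pairing")
  bad_t <- setdiff(pairing$tumor, sample_ids(tumor))
  if (length(bad_t)) stop("pairing references unknown tumor sample(s): ",
                          paste(bad_t, collapse = ", "))
  bad_n <- setdiff(pairing$normal, sample_ids(normal))
  if (length(bad_n)) stop("pairing references unknown normal sample(s): ",
                          paste(bad_n, collapse = ", "))
  if (anyDuplicated(pairing$tumor) || anyDuplicated(pairing$normal))
    stop("a sample appears in more than one pair")
  structure(list(tumor = tumor, normal = normal, pairing = pairing),
            class = "PairedCohort")
}

#' @export
print.PairedCohort <- function(x, ...) {
  cat(sprintf("PairedCohort: %d genes, %d pairs\n",
              nrow(x$tumor$values), nrow(x$pairing)))
  invisible(x)
}

# Aligned difference matrix (tumor - normal), genes x pairs.
paired_differences <- function(cohort) {
  stopifnot(inherits(cohort, "PairedCohort"))
  tv <- cohort$tumor$values[, cohort$pairing$tumor, drop = FALSE]
  nv <- cohort$normal$values[, cohort$pairing$normal, drop = FALSE]
  d <- tv - nv
  colnames(d) <- cohort$pairing$tumor
  d
}
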