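# Downstream characterization of a gene list: hypergeometric gene-set and
# cancer-gene enrichment, direct-neighbor subnetworks with full-network
# degrees, and the paired-methylation hypermethylation-frequency rule.

hypergeom_upper <- function(k, K, n, N) {
  # P(X >= k) for X ~ Hypergeometric(N population, K successes, n draws)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric gene-set enrichment
#'
#' For each set, the upper-tail hypergeometric probability of drawing at
#' least the observed overlap between the query and the set within the
#' declared background, BH-adjusted across the collection. The background
#' defaults to the union of all collection members; query genes outside the
#' background are dropped (reported via a message).
#'
#' @param query Character vector of genes of interest.
#' @param collection A `GeneSetCollection`.
#' @param background Optional explicit gene universe.
#' @param alpha_fdr FDR threshold for the `significant` flag.
#' @return Data frame sorted by `q` then `p`: `set_name`, `set_size`,
#'   `query_size`, `overlap`, `background_size`, `p`, `q`, `significant`.
#' @export
hypergeom_enrichment <- function(query, collection, background = NULL,
                                 alpha_fdr = 0.05) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (is.null(background)) background <- collection$background
  if (is.null(background)) background <- unique(unlist(collection$sets))
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("empty background universe")
  query <- unique(as.character(query))
  dropped <- setdiff(query, background)
  if (length(dropped))
    message("hypergeom_enrichment: ", length(dropped),
            " query gene(s) outside the background were dropped")
  query <- intersect(query, background)
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], background)
    K <- length(members)
    k <- length(intersect(query, members))
    data.frame(set_name = nm, set_size = K, query_size = n, overlap = k,
               background_size = N, p = hypergeom_upper(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < alpha_fdr
  out <- out[order(out$q, out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cancer-gene enrichment of a gene list
#'
#' Single upper-tail hypergeometric test of the overlap between a gene list
#' and a cancer-gene catalogue within a background universe (by convention
#' the PPI network's nodes).
#'
#' @param genes Query gene list.
#' @param cancer_genes Cancer-gene catalogue.
#' @param background Gene universe.
#' @return One-row data frame: `set_name` (`"cancer_genes"`), `set_size`,
#'   `query_size`, `overlap`, `background_size`, `p`.
#' @export
cancer_gene_enrichment <- function(genes, cancer_genes, background) {
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("empty background universe")
  K <- length(intersect(cancer_genes, background))
  if (K == 0L) stop("no cancer genes in the background universe")
  query <- intersect(unique(as.character(genes)), background)
  k <- length(intersect(query, cancer_genes))
  data.frame(set_name = "cancer_genes", set_size = K, query_size = length(query),
             overlap = k, background_size = length(background),
             p = hypergeom_upper(k, K, length(query), length(background)),
             stringsAsFactors = FALSE)
}

#' Direct-neighbor subnetwork of seed genes
#'
#' Collects every node adjacent to at least one seed (seeds themselves
#' excluded from the neighbor set), the edges induced among seeds and
#' neighbors, and each seed's degree in the full network. Seeds absent from
#' the network get degree 0 and are reported via a message.
#'
#' @param network A `PpiNetwork`.
#' @param seeds Character vector of seed genes.
#' @return Object of class `NeighborSubnetwork`: list with `seeds`,
#'   `neighbors`, `edges` (induced edge data frame), `seed_degrees`
#'   (named integer vector over all seeds).
#' @export
direct_neighbors <- function(network, seeds) {
  stopifnot(inherits(network, "PpiNetwork"))
  seeds <- unique(as.character(seeds))
  absent <- setdiff(seeds, network$nodes)
  if (length(absent))
    message("direct_neighbors: ", length(absent), " seed(s) absent from the network")
  degrees <- setNames(rep(0L, length(seeds)), seeds)
  neighbors <- character(0L)
  edges <- network$edges[0, , drop = FALSE]
  present <- intersect(seeds, network$nodes)
  if (length(present) && nrow(network$edges)) {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = network$nodes)
    degrees[present] <- as.integer(igraph::degree(g)[present])
    nb <- unique(unlist(lapply(igraph::adjacent_vertices(g, present),
                               igraph::as_ids)))
    neighbors <- sort(setdiff(nb, seeds))
    sub <- igraph::induced_subgraph(g, intersect(c(seeds, neighbors),
                                                 network$nodes))
    edges <- igraph::as_data_frame(sub, what = "edges")[, c("from", "to")]
    rownames(edges) <- NULL
  }
  structure(list(seeds = seeds, neighbors = neighbors, edges = edges,
                 seed_degrees = degrees),
            class = "NeighborSubnetwork")
}

#' @export
print.NeighborSubnetwork <- function(x, ...) {
  cat(sprintf("NeighborSubnetwork: %d seeds, %d direct neighbors, %d induced edges\n",
              length(x$seeds), length(x$neighbors), nrow(x$edges)))
  invisible(x)
}

#' Hypermethylation frequency rule on paired methylation data
#'
#' Per gene, the fraction of pairs in which the tumor beta value is
#' strictly higher than the paired normal beta. A gene is flagged
#' hypermethylated when this frequency strictly exceeds the threshold
#' ("more than 50%" under the default).
#'
#' @param methyl A `PairedCohort` of beta values in `[0, 1]`.
#' @param genes Optional gene subset to report (default: all genes).
#' @param freq_threshold Strict threshold for the flag.
#' @return Data frame: `gene`, `n_pairs`, `n_higher`, `frequency`,
#'   `hypermethylated`.
#' @export
hypermethylation_frequency <- function(methyl, genes = NULL, freq_threshold = 0.50) {
  stopifnot(inherits(methyl, "PairedCohort"))
  rng <- range(methyl$tumor$values, methyl$normal$values)
  if (rng[1L] < 0 || rng[2L] > 1)
    stop("methylation beta values must lie in [0, 1]")
  d <- paired_differences(methyl)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(d))
    if (length(missing))
      message("hypermethylation_frequency: ", length(missing),
              " gene(s) without methylation data skipped")
    d <- d[intersect(genes, rownames(d)), , drop = FALSE]
  }
  n_pairs <- ncol(d)
  n_higher <- rowSums(d > 0)
  data.frame(gene = rownames(d), n_pairs = n_pairs, n_higher = n_higher,
             frequency = n_higher / n_pairs,
             hypermethylated = n_higher / n_pairs > freq_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}
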