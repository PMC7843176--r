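test_that("hypergeometric enrichment reproduces analytic corners", {
  coll <- gene_set_collection(list(full = sprintf("g%02d", 1:5),
                                   none = sprintf("g%02d", 6:8)))
  bg <- sprintf("g%02d", 1:20)
  enr <- hypergeom_enrichment(sprintf("g%02d", 1:5), coll, background = bg)
  expect_equal(enr$p[enr$set_name == "full"], 1 / choose(20, 5))
  expect_equal(enr$p[enr$set_name == "none"], 1.0)   # k = 0
  expect_equal(enr$q, p.adjust(enr$p, "BH"))
  expect_error(hypergeom_enrichment("g01", coll, background = character(0)),
               "empty background")
})

test_that("hypergeometric tails match brute-force enumeration", {
  # worked instance N=100, K=10, n=10, k=3
  expect_equal(unideg:::hypergeom_upper(3, 10, 10, 100),
               oracle_hyper_tail(3, 10, 10, 100))
  set.seed(19)
  for (rep in 1:200) {
    N <- sample(5:30, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(unideg:::hypergeom_upper(k, K, n, N),
                 oracle_hyper_tail(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("shrinking the background to query and set members never lowers overlap", {
  set.seed(29)
  bg <- sprintf("g%03d", 1:200)
  sets <- list(s1 = sample(bg, 30), s2 = sample(bg, 15))
  coll <- gene_set_collection(sets)
  query <- sample(bg, 25)
  full <- hypergeom_enrichment(query, coll, background = bg)
  small_bg <- union(query, unlist(sets))
  small <- hypergeom_enrichment(query, coll, background = small_bg)
  m <- match(full$set_name, small$set_name)
  expect_true(all(small$overlap[m] >= full$overlap))
})

test_that("cancer-gene enrichment handles worked example and degenerate cases", {
  bg <- sprintf("g%02d", 1:10)
  cg <- sprintf("g%02d", 1:5)
  row <- cancer_gene_enrichment(c("g01", "g02"), cg, bg)
  expect_equal(row$p, choose(5, 2) / choose(10, 2))   # 10/45
  expect_equal(cancer_gene_enrichment(bg, cg, bg)$p, 1.0)
  expect_error(cancer_gene_enrichment("g01", "zz", bg), "no cancer genes")
})

test_that("direct neighbors handle stars, shared neighbors and absent seeds", {
  star <- ppi_network(cbind("hub", sprintf("leaf%d", 1:5)))
  sub <- direct_neighbors(star, "hub")
  expect_length(sub$neighbors, 5L)
  expect_equal(unname(sub$seed_degrees["hub"]), 5L)

  tri <- ppi_network(rbind(c("s1", "n"), c("s2", "n")))
  sub2 <- direct_neighbors(tri, c("s1", "s2"))
  expect_equal(sub2$neighbors, "n")   # shared neighbor counted once

  sub3 <- suppressMessages(direct_neighbors(star, c("hub", "ghost")))
  expect_equal(unname(sub3$seed_degrees["ghost"]), 0L)
  expect_false("ghost" %in% sub3$neighbors)
})

test_that("neighbor sets and degrees match a naive adjacency scan", {
  set.seed(37)
  for (rep in 1:10) {
    nodes <- sprintf("n%02d", 1:50)
    edges <- unique(t(apply(cbind(sample(nodes, 120, TRUE),
                                  sample(nodes, 120, TRUE)), 1, sort)))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    net <- ppi_network(edges)
    seeds <- sample(nodes, 4)
    got <- suppressMessages(direct_neighbors(net, seeds))
    ref <- oracle_neighbors(net$edges, seeds)
    expect_identical(got$neighbors, ref$neighbors)
    expect_identical(got$seed_degrees[seeds], ref$degrees[seeds])
    # induced edges are a subset of the full network's edges
    key <- function(df) paste(pmin(df$from, df$to), pmax(df$from, df$to))
    expect_true(all(key(got$edges) %in% key(net$edges)))
  }
})

test_that("the hypermethylation rule is a strict majority over pairs", {
  n <- 115L
  nor <- matrix(0.4, 3, n)
  tum <- matrix(0.4, 3, n)
  tum[1, 1:58] <- 0.6; tum[1, 59:n] <- 0.2    # 58/115 higher
  tum[2, 1:57] <- 0.6; tum[2, 58:n] <- 0.2    # 57 < 57.5: under the rule
  tum[3, ] <- 0.2
  cohort <- make_paired(tum, nor, genes = c("over", "half", "never"))
  cohort$tumor$log_scale <- FALSE
  cohort$normal$log_scale <- FALSE
  hm <- hypermethylation_frequency(cohort)
  expect_true(hm$hypermethylated[hm$gene == "over"])
  expect_equal(hm$n_higher[hm$gene == "half"], 57L)
  expect_false(hm$hypermethylated[hm$gene == "half"])
  expect_equal(hm$frequency[hm$gene == "never"], 0)
  # exactly 50% is not hypermethylated
  nor2 <- matrix(0.5, 2, 4); tum2 <- matrix(c(0.6, 0.6, 0.4, 0.4), 2, 4, byrow = TRUE)
  tum2[2, ] <- c(0.6, 0.6, 0.6, 0.4)
  cohort2 <- make_paired(tum2, nor2, genes = c("exact", "overx"))
  hm2 <- hypermethylation_frequency(cohort2)
  expect_false(hm2$hypermethylated[hm2$gene == "exact"])
  expect_true(hm2$hypermethylated[hm2$gene == "overx"])
  expect_error(hypermethylation_frequency(
    make_paired(matrix(2, 2, 2), matrix(0.5, 2, 2))), "beta")
})

test_that("planted enrichment signal is recovered as the top hit", {
  set.seed(71)
  universe <- sprintf("g%04d", 1:1000)
  query <- sprintf("g%04d", 1:10)
  know <- generate_toy_knowledge(universe, n_sets = 15, set_size_range = c(10L, 30L),
                                 n_edges = 0, seed = 8,
                                 plant = list(genes = query, size = 20))
  enr <- hypergeom_enrichment(query, know$collection, background = universe)
  expect_equal(enr$set_name[1], "planted_set")
  expect_true(enr$significant[1])
})
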