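test_that("Fisher exact p matches enumeration corners and fisher.test", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1.0)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10))
  expect_equal(fisher_exact_2x2(0, 5, 5, 0), 2 / choose(10, 5))
  set.seed(13)
  for (rep in 1:200) {
    cells <- as.integer(rpois(4, lambda = sample(c(2, 5, 15), 1)))
    got <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    ref <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(got, ref, tolerance = 1e-10)
  }
  expect_error(fisher_exact_2x2(-1, 0, 0, 0), "non-negative")
})

test_that("a sample matching the normal consensus yields zero calls", {
  d <- cohort_design(20, 10, 1, noise_sd = 0.3, baseline_spread = 1.5, seed = 44)
  nc <- generate_normal_cohort(d)
  reos <- stable_reos(nc)
  consensus <- setNames(rowMeans(nc$values), gene_ids(nc))
  res <- call_sample_degs(consensus, reos)
  expect_true(all(res$status == "NONE"))
  expect_true(attr(res, "converged"))
})

test_that("a gene falling below most stable partners is called DOWN", {
  u <- c("g", sprintf("p%02d", 1:20))
  reos <- make_reos(u, a = rep("g", 20), b = sprintf("p%02d", 1:20), n = 10)
  s <- setNames(numeric(21), u)
  s["g"] <- 5
  s[sprintf("p%02d", 1:5)] <- 4      # g still above 5 partners
  s[sprintf("p%02d", 6:20)] <- 6     # g fell below 15 partners
  res <- call_sample_degs(s, reos)
  row <- res[res$gene == "g", ]
  expect_equal(unlist(row[c("n_greater_normal", "n_less_normal",
                            "n_greater_sample", "n_less_sample")],
                      use.names = FALSE), c(20L, 0L, 5L, 15L))
  expect_equal(row$p, fisher_exact_2x2(20, 0, 5, 15))
  expect_lt(row$p, 1e-4)
  expect_equal(row$status, "DOWN")
  # iteration 1 removes the called gene from the partners' single-pair
  # tables, leaving them unsupported but uncalled
  expect_true(all(res$status[res$gene != "g"] == "NONE"))
})

test_that("genes without stable partners are flagged unsupported", {
  u <- c("a", "b", "c")
  reos <- make_reos(u, a = "a", b = "b", n = 10)
  res <- call_sample_degs(setNames(c(1, 2, 3), u), reos)
  expect_true(res$unsupported[res$gene == "c"])
  expect_equal(res$status[res$gene == "c"], "NONE")
})

test_that("calls are invariant under monotone transforms of the sample", {
  d <- cohort_design(40, 20, 1,
                     planted_up = data.frame(gene = 5, frequency = 1, effect = 2),
                     noise_sd = 0.4, baseline_spread = 1, seed = 3)
  nc <- generate_normal_cohort(d)
  reos <- stable_reos(nc)
  tum <- generate_tumor_cohort(d)
  s <- setNames(tum$tumor$values[, 1], gene_ids(tum$tumor))
  base <- call_sample_degs(s, reos)
  for (f in list(function(x) x^3, function(x) 2^x, function(x) 10 * x + 3)) {
    res <- call_sample_degs(f(s), reos)
    expect_identical(res$status, base$status)
  }
})

test_that("the returned call set is a fixed point of one further iteration", {
  d <- cohort_design(60, 25, 1,
                     planted_up = data.frame(gene = 1:4, frequency = 1, effect = 2),
                     planted_down = data.frame(gene = 5:8, frequency = 1, effect = 2),
                     noise_sd = 0.5, baseline_spread = 1, seed = 10)
  nc <- generate_normal_cohort(d)
  reos <- stable_reos(nc)
  tum <- generate_tumor_cohort(d)
  s <- setNames(tum$tumor$values[, 1], gene_ids(tum$tumor))
  res <- call_sample_degs(s, reos)
  expect_true(attr(res, "converged"))
  # rerunning capped at the converged iteration count reproduces the calls
  again <- suppressWarnings(call_sample_degs(s, reos,
                                             max_iter = attr(res, "iterations")))
  expect_identical(again$status, res$status)
})

test_that("the iterative caller matches an independently coded naive version", {
  set.seed(77)
  for (rep in 1:8) {
    G <- sample(5:8, 1)
    d <- cohort_design(G, 10, 1,
                       planted_up = data.frame(gene = 1, frequency = 1, effect = 3),
                       noise_sd = 0.6, baseline_spread = 1.2,
                       seed = 1000 + rep)
    nc <- generate_normal_cohort(d)
    reos <- stable_reos(nc)
    if (nrow(reos$pairs) == 0) next
    tum <- generate_tumor_cohort(d)
    s <- setNames(tum$tumor$values[, 1], gene_ids(tum$tumor))
    got <- suppressWarnings(call_sample_degs(s, reos))
    expect_identical(got$status, unname(oracle_call_sample(s, reos)))
  }
})

test_that("the mean-reference comparator exhibits the documented pitfall", {
  nor <- make_em(cbind(c(10, 5), c(2, 5), c(3, 5)), genes = c("A", "B"))
  m <- rowMeans(nor$values)   # A: 5, B: 5
  s <- setNames(c(6, 5), c("A", "B"))
  calls <- call_vs_mean_reference(s, nor)
  expect_equal(unname(calls["A"]), "UP")      # above cohort mean
  expect_equal(unname(calls["B"]), "DOWN")    # tie -> DOWN by strict >
  # pitfall: A is UP versus the mean but DOWN versus its own paired normal
  paired <- make_paired(matrix(c(6, 5), 2, 1), matrix(c(10, 5), 2, 1),
                        genes = c("A", "B"))
  pcalls <- paired_calls(paired)
  expect_equal(unname(pcalls$status["A", 1]), "DOWN")
})
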