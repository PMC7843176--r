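test_that("generators are pure functions of design and seed", {
  d <- cohort_design(20, 6, 8, noise_sd = 0.4, seed = 99)
  expect_identical(generate_normal_cohort(d)$values,
                   generate_normal_cohort(d)$values)
  p1 <- generate_paired_cohort(d)
  p2 <- generate_paired_cohort(d)
  expect_identical(p1$cohort$tumor$values, p2$cohort$tumor$values)
  expect_identical(p1$truth$status, p2$truth$status)
  k1 <- generate_toy_knowledge(50, seed = 5)
  k2 <- generate_toy_knowledge(50, seed = 5)
  expect_identical(k1$collection$sets, k2$collection$sets)
  expect_identical(k1$network$edges, k2$network$edges)
  d2 <- cohort_design(20, 6, 8, noise_sd = 0.4, seed = 100)
  expect_false(identical(generate_normal_cohort(d)$values,
                         generate_normal_cohort(d2)$values))
})

test_that("zero noise gives identical columns and fully stable orderings", {
  # the doubled-tail exact p for a unanimous pair is 2^(1-n), so at least
  # 6 samples are needed before any pair can clear FDR 0.05
  d <- cohort_design(10, 8, 3, noise_sd = 0, baseline_spread = 1.5, seed = 3)
  nc <- generate_normal_cohort(d)
  expect_true(all(nc$values == nc$values[, 1]))
  reos <- stable_reos(nc)
  # every pair has distinct baselines almost surely -> all pairs stable
  expect_equal(nrow(reos$pairs), choose(10, 2))
})

test_that("truth bookkeeping equals realized planted counts exactly", {
  d <- cohort_design(30, 4, 40,
                     planted_up = data.frame(gene = 1:3, frequency = 0.6, effect = 2),
                     planted_down = data.frame(gene = 4:5, frequency = 0.3, effect = 2),
                     seed = 17)
  pc <- generate_paired_cohort(d)
  expect_equal(pc$truth$frequency,
               rowSums(pc$truth$status != "NONE") / 40)
  unplanted <- setdiff(rownames(pc$truth$status), d$gene_ids[1:5])
  expect_true(all(pc$truth$status[unplanted, ] == "NONE"))
  d0 <- cohort_design(30, 4, 40, seed = 17)
  expect_true(all(generate_paired_cohort(d0)$truth$status == "NONE"))
})

test_that("invalid designs are rejected", {
  expect_error(cohort_design(10, 4, 4,
                             planted_up = data.frame(gene = 1, frequency = 0.5, effect = 0)),
               "nonzero effect")
  expect_error(cohort_design(10, 4, 4,
                             planted_up = data.frame(gene = 1, frequency = 1.2, effect = 1)),
               "frequencies")
  expect_error(cohort_design(10, 4, 4,
                             planted_up = data.frame(gene = 2, frequency = 1, effect = 1),
                             planted_down = data.frame(gene = 2, frequency = 1, effect = 1)),
               "both up and down")
  expect_error(generate_normal_cohort(cohort_design(10, 1, 4)), "n_normal")
})

test_that("realized plant counts are binomially distributed across seeds", {
  counts <- vapply(1:100, function(s) {
    d <- cohort_design(2, 2, 448,
                       planted_up = data.frame(gene = 1, frequency = 0.5, effect = 1),
                       seed = s)
    sum(generate_paired_cohort(d)$truth$status[1, ] != "NONE")
  }, numeric(1))
  se_mean <- sqrt(448 * 0.25) / sqrt(100)
  expect_lt(abs(mean(counts) - 224), 3 * se_mean)
})

test_that("monotone platform views preserve within-sample orderings", {
  d <- cohort_design(15, 6, 2, noise_sd = 0.5, seed = 8)
  nc <- generate_normal_cohort(d)
  for (id in c("affine", "cube", "exp")) {
    view <- generate_platform_view(nc, id, extra_noise_sd = 0, seed = 1, a = 3, b = -2)
    expect_equal(apply(view$values, 2, rank), apply(nc$values, 2, rank))
    expect_equal(view$platform, id)
  }
  ident <- generate_platform_view(nc, "affine", extra_noise_sd = 0, seed = 1,
                                  a = 1, b = 0)
  expect_equal(ident$values, nc$values)
})

test_that("methylation plants give exact hypermethylation frequencies", {
  mc <- generate_methylation_cohort(50, 115,
                                    planted_hyper = c(g0001 = 1.0, g0002 = 0.4),
                                    seed = 4)
  expect_true(all(mc$tumor$values >= 0 & mc$tumor$values <= 1))
  hm <- hypermethylation_frequency(mc)
  expect_equal(hm$frequency[hm$gene == "g0001"], 1.0)
  expect_true(hm$hypermethylated[hm$gene == "g0001"])
  # 0.4 * 115 = 46 raised pairs: below the strict 50% rule
  expect_equal(hm$n_higher[hm$gene == "g0002"], 46L)
  expect_false(hm$hypermethylated[hm$gene == "g0002"])
})

test_that("unplanted methylation frequencies center on one half", {
  mc <- generate_methylation_cohort(100, 115, seed = 12)
  hm <- hypermethylation_frequency(mc)
  se <- sqrt(0.25 / 115) / sqrt(100)
  expect_lt(abs(mean(hm$frequency) - 0.5), 3 * se + 0.01)
})

test_that("toy knowledge honors edge counts and planting", {
  k0 <- generate_toy_knowledge(40, n_edges = 0, seed = 2)
  expect_equal(nrow(k0$network$edges), 0L)
  sub <- direct_neighbors(k0$network, "g0001")
  expect_length(sub$neighbors, 0L)
  kp <- generate_toy_knowledge(1000, n_sets = 10, n_edges = 50, seed = 2,
                               plant = list(genes = sprintf("g%04d", 1:10), size = 20))
  expect_true(all(sprintf("g%04d", 1:10) %in% kp$collection$sets$planted_set))
  expect_length(kp$collection$sets$planted_set, 20L)
})
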