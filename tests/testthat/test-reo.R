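test_that("pair orientation counts match the naive double loop", {
  em <- make_em(matrix(rep(c(1, 2), 5), 2, 5, byrow = FALSE),
                genes = c("A", "B"))
  cnt <- pair_orientation_counts(em)
  expect_equal(cnt$k_lt, 5L)
  expect_equal(cnt$k_gt, 0L)
  expect_equal(cnt$k_tie, 0L)

  em_tie <- make_em(rbind(1:4, 1:4))
  expect_equal(pair_orientation_counts(em_tie)$k_tie, 4L)

  set.seed(31)
  vals <- matrix(sample(1:5, 24, TRUE), 4, 6)
  em_r <- make_em(vals)
  got <- pair_orientation_counts(em_r)
  ref <- oracle_pair_counts(vals)
  ord <- function(df) { rownames(df) <- NULL; df[order(df$i, df$j), ] }
  expect_equal(ord(as.data.frame(got)), ord(ref), ignore_attr = TRUE)
  expect_true(all(got$k_gt + got$k_lt + got$k_tie == 6L))
})

test_that("doubled-tail binomial p-values hit the analytic corners", {
  expect_equal(unideg:::binom_reo_p(10, 10), 0.001953125)
  expect_equal(unideg:::binom_reo_p(5, 10), 1.0)
  expect_equal(unideg:::binom_reo_p(9, 10), 0.021484375)
  # at the symmetric null this equals binom.test's two-sided p
  for (n in c(3, 8, 15)) for (k in 0:n)
    expect_equal(unideg:::binom_reo_p(max(k, n - k), n),
                 binom.test(k, n, 0.5)$p.value)
})

test_that("stable_reos matches an independent brute-force caller", {
  set.seed(41)
  for (rep in 1:25) {
    G <- sample(3:6, 1)
    n <- sample(4:12, 1)
    vals <- matrix(rnorm(G * n, sd = 1), G, n) + rnorm(G, sd = 2)
    em <- make_em(vals)
    got <- stable_reos(em)
    exp_pairs <- oracle_stable_reos(vals)
    key <- function(df) sort(paste(df$a, df$b))
    expect_identical(key(got$pairs), key(exp_pairs))
    # orientation uniqueness and majority support
    unordered <- paste(pmin(got$pairs$a, got$pairs$b),
                       pmax(got$pairs$a, got$pairs$b))
    expect_false(any(duplicated(unordered)))
    expect_true(all(got$pairs$k / got$pairs$n > 0.5))
    expect_lte(nrow(got$pairs), choose(G, 2))
  }
})

test_that("stable REOs are invariant under strictly monotone transforms", {
  set.seed(5)
  em <- make_em(matrix(rnorm(300), 15, 20) + rnorm(15, sd = 2))
  base <- stable_reos(em)
  transforms <- list(function(x) x^3, function(x) 2^x, function(x) 5 * x - 40)
  for (f in transforms) {
    em_t <- expression_matrix(f(em$values), platform = "t", log_scale = FALSE)
    expect_identical(stable_reos(em_t)$pairs, base$pairs)
  }
  # per-sample different monotone maps also preserve within-sample order
  v <- em$values
  for (s in seq_len(ncol(v))) v[, s] <- exp(v[, s] / s)
  expect_identical(stable_reos(make_em(v))$pairs, base$pairs)
})

test_that("intersection keeps consistent orientations and counts conflicts", {
  u <- c("A", "B", "C", "D")
  s1 <- make_reos(u, a = c("A", "B", "C"), b = c("B", "C", "D"), n = 10)
  expect_identical(intersect_stable_reos(s1, s1)$pairs[, c("a", "b")],
                   s1$pairs[, c("a", "b")])
  s2 <- make_reos(u, a = c("B", "B", "C"), b = c("A", "C", "D"), n = 8)
  got <- suppressMessages(intersect_stable_reos(s1, s2))
  expect_equal(attr(got, "n_conflicts"), 1L)   # A>B vs B>A
  expect_equal(nrow(got$pairs), 2L)
  expect_equal(got$pairs$n, rep(18L, 2))       # support pooled across cohorts
  expect_equal(got$pairs$n_a, rep(10L, 2))
  expect_equal(got$pairs$n_b, rep(8L, 2))
})

test_that("zero-noise platform views intersect with full retention", {
  d <- cohort_design(12, 8, 2, noise_sd = 0, baseline_spread = 1, seed = 6)
  nc <- generate_normal_cohort(d)
  va <- generate_platform_view(nc, "affine", 0, seed = 1, a = 2, b = 3)
  vb <- generate_platform_view(nc, "cube", 0, seed = 2)
  ra <- stable_reos(va)
  rb <- stable_reos(vb)
  both <- intersect_stable_reos(ra, rb)
  expect_equal(attr(both, "n_conflicts"), 0L)
  expect_equal(nrow(both$pairs), nrow(ra$pairs))
  expect_equal(nrow(both$pairs), nrow(rb$pairs))
})

test_that("REO set files round-trip", {
  u <- c("A", "B", "C")
  s <- make_reos(u, a = c("A", "C"), b = c("B", "B"), k = c(9, 8), n = 10)
  path <- withr::local_tempfile()
  write_reo_set(s, path)
  back <- read_reo_set(path)
  expect_equal(back$gene_universe, u)
  expect_equal(back$pairs, s$pairs)
  expect_equal(back$n_samples, 10L)
})
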