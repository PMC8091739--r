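test_that("read_gmt parses, deduplicates and validates", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S1\tdesc\ta\tb\tb", f)
  sets <- read_gmt(f)
  expect_equal(sets$S1, c("a", "b"))

  writeLines(character(), f)
  expect_error(read_gmt(f), "empty")

  writeLines(c("S1\tdesc\ta", "S1\tdesc\tb"), f)
  expect_error(read_gmt(f), "duplicate.*S1")

  writeLines("S1\tdesc", f)
  expect_error(read_gmt(f), "line 1")
})

test_that("ora_test matches the closed-form hypergeometric tail", {
  universe <- paste0("g", 1:10)
  res <- ora_test(universe[1:5], universe[1:5], universe)
  expect_equal(res$k, 5L)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)  # 1/252

  expect_equal(ora_test(universe[1:5], universe[6:10], universe)$p, 1)
  expect_equal(ora_test(universe[1:5], c("zz", "yy"), universe)$p, 1)
  expect_error(ora_test(c("g1", "nope"), universe[1:3], universe), "subset")
})

test_that("ora_test equals brute-force pmf summation for N <= 12", {
  set.seed(30)
  for (rep in 1:25) {
    N <- sample(3:12, 1)
    universe <- paste0("u", seq_len(N))
    gs <- sample(universe, sample(seq_len(N), 1))
    q <- sample(universe, sample(seq_len(N), 1))
    res <- ora_test(q, gs, universe)
    expect_equal(res$p,
                 brute_hyper_upper(res$k, N, length(gs), length(q)),
                 tolerance = 1e-12)
  }
})

test_that("bh_fdr performs the step-up adjustment", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_fdr(c(0.1, 1.2)), "0,1")

  set.seed(31)
  for (rep in 1:50) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), stats::p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
    # FDR order agrees (non-strictly) with p order
    expect_true(all(diff(bh_fdr(p)[order(p)]) >= -1e-12))
  }
})

test_that("enrich ranks the planted pathway first on synthetic fixtures", {
  cfg <- synthetic_config(n_nodes = 300L, n_positives = 20L, seed = 6L)
  pl <- plant_positives(generate_pin(cfg), cfg)
  sets <- generate_gene_sets(pl$graph, pl$positives, cfg)
  tbl <- enrich(pl$positives, sets, pl$graph$nodes)
  expect_s3_class(tbl, "enrichment_table")
  expect_equal(tbl$gene_set[1L], "PLANTED_PATHWAY")
  expect_true(tbl$significant[1L])
  expect_equal(nrow(tbl), length(sets))
  expect_true(all(tbl$fdr >= tbl$p_value - 1e-12))
  expect_true(all(tbl$overlap <= pmin(tbl$set_size, tbl$query_size)))
})

test_that("degenerate queries and thresholds behave per contract", {
  universe <- paste0("g", 1:30)
  sets <- structure(list(A = universe[1:10], B = universe[11:30]),
                    class = "gene_set_collection")
  # query = universe: every draw takes the whole universe, all p = 1
  tbl <- enrich(universe, sets, universe)
  expect_true(all(tbl$p_value == 1))
  expect_false(any(tbl$significant))

  tbl0 <- enrich(universe[1:8], sets, universe, fdr_threshold = 0)
  expect_false(any(tbl0$significant))
  expect_error(enrich(universe[1:3],
                      structure(list(), class = "gene_set_collection"),
                      universe), "empty")
})

test_that("random queries give calibrated null p-values", {
  # the exact upper-tail hypergeometric p is discrete and super-uniform, so
  # its Kolmogorov distance from the continuous uniform plateaus around
  # 0.12-0.17 regardless of sample size; calibration is therefore checked as
  # (a) conservativeness against uniform and (b) agreement with the exact
  # discrete null distribution
  set.seed(32)
  universe <- paste0("g", 1:200)
  pvals <- replicate(500, {
    gs <- sample(universe, 40)
    q <- sample(universe, 30)
    ora_test(q, gs, universe)$p
  })
  grid <- seq(0.01, 0.99, by = 0.01)
  emp <- vapply(grid, function(t) mean(pvals <= t), 0)
  expect_true(all(emp <= grid + 0.05))   # never anti-conservative
  # exact null CDF of P(X >= k) for X ~ Hypergeom(N=200, K=40, n=30)
  k <- 0:30
  pmf <- stats::dhyper(k, 40, 160, 30)
  pk <- stats::phyper(k - 1, 40, 160, 30, lower.tail = FALSE)
  null_cdf <- function(t) sum(pmf[pk <= t])
  ks_exact <- max(abs(emp - vapply(grid, null_cdf, 0)))
  expect_lt(ks_exact, 0.1)
})
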