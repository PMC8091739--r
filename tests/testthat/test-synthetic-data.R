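test_that("synthetic_config validates counts and fractions", {
  expect_error(synthetic_config(edges_per_new_node = 0), "positive")
  expect_error(synthetic_config(n_positives = 500, n_nodes = 500), "n_positives")
  expect_error(synthetic_config(positive_cohesion = 1.2), "fractions")
  expect_error(synthetic_config(n_nodes = 3, edges_per_new_node = 3,
                                n_positives = 1),
               "edges_per_new_node")
})

test_that("generate_pin is deterministic and scale-free-ish", {
  cfg <- synthetic_config(n_nodes = 500L, edges_per_new_node = 3L, seed = 11L)
  g1 <- generate_pin(cfg)
  g2 <- generate_pin(cfg)
  expect_identical(g1$edges, g2$edges)

  # ~2000 edges at n=500, m=3 (each new node adds m out + 1 in edge)
  expect_gt(nrow(g1$edges), 1700)
  expect_lt(nrow(g1$edges), 2100)

  deg <- compute_degrees(g1)
  expect_gt(max(deg$indegree), 5 * stats::median(deg$indegree))

  # connected as an undirected graph
  g_und <- igraph::as_undirected(
    igraph::graph_from_data_frame(g1$edges, vertices = g1$nodes))
  expect_equal(igraph::components(g_und)$no, 1L)
})

test_that("top-decile indegree share exceeds the uniform share", {
  for (seed in c(3, 17)) {
    g <- generate_pin(synthetic_config(n_nodes = 300L, seed = seed))
    ind <- sort(compute_degrees(g)$indegree, decreasing = TRUE)
    top <- sum(ind[seq_len(30)])
    expect_gt(top / sum(ind), 0.1)
  }
})

test_that("plant_positives produces a cohesive class at cohesion 1", {
  gaps <- vapply(1:20, function(s) {
    cfg <- tiny_synth(seed = s, cohesion = 1.0)
    pl <- plant_positives(generate_pin(cfg), cfg)
    set.seed(10000 + s)
    rnd <- sample(setdiff(pl$graph$nodes, pl$positives),
                  length(pl$positives))
    adjacency_jaccard(pl$graph, pl$positives) -
      adjacency_jaccard(pl$graph, rnd)
  }, 0)
  expect_true(all(gaps > 0))
})

test_that("plant_positives at cohesion 0 leaves no Jaccard signal", {
  gaps <- vapply(1:20, function(s) {
    cfg <- tiny_synth(seed = s, cohesion = 0)
    pl <- plant_positives(generate_pin(cfg), cfg)
    set.seed(20000 + s)
    rnd <- sample(setdiff(pl$graph$nodes, pl$positives),
                  length(pl$positives))
    adjacency_jaccard(pl$graph, pl$positives) -
      adjacency_jaccard(pl$graph, rnd)
  }, 0)
  expect_lt(abs(mean(gaps)), 3 * stats::sd(gaps))
})

test_that("plant_positives respects n_positives = 0 and determinism", {
  cfg0 <- synthetic_config(n_positives = 0L, n_nodes = 100L, seed = 5L)
  g <- generate_pin(cfg0)
  pl <- plant_positives(g, cfg0)
  expect_equal(pl$positives, character())
  expect_identical(pl$graph$edges, g$edges)

  cfg <- tiny_synth(seed = 9)
  g <- generate_pin(cfg)
  p1 <- plant_positives(g, cfg)
  p2 <- plant_positives(g, cfg)
  expect_identical(p1$positives, p2$positives)
  expect_identical(p1$graph$edges, p2$graph$edges)
  expect_equal(length(p1$positives), cfg$n_positives)
})

test_that("generate_drug_target_map enriches for the planted class", {
  cfg <- synthetic_config(n_nodes = 300L, n_positives = 25L, n_drugs = 50L,
                          positive_target_enrichment = 0.8, seed = 2L)
  g <- generate_pin(cfg)
  pl <- plant_positives(g, cfg)
  m <- generate_drug_target_map(pl$graph, pl$positives, cfg)
  m2 <- generate_drug_target_map(pl$graph, pl$positives, cfg)
  expect_identical(unclass(m), unclass(m2))
  expect_equal(length(m), 50L)

  ov <- vapply(m, function(tg) length(intersect(tg, pl$positives)), 0L)
  expected_null <- mean(lengths(m)) * length(pl$positives) / n_genes(pl$graph)
  expect_gt(mean(ov), expected_null)
})

test_that("drug targets are uniform when enrichment is off", {
  cfg <- synthetic_config(n_nodes = 200L, n_positives = 0L,
                          positive_target_enrichment = 0, seed = 3L)
  g <- generate_pin(cfg)
  m <- generate_drug_target_map(g, character(), cfg)
  expect_true(all(unlist(m) %in% g$nodes))
  expect_error(generate_drug_target_map(
    g, character(), synthetic_config(n_nodes = 200L,
                                     targets_per_drug = c(2L, 300L))),
    "upper bound")
})

test_that("generate_gene_sets seeds one true pathway and writes GMT", {
  cfg <- synthetic_config(n_nodes = 300L, n_positives = 20L,
                          gene_set_size = c(10L, 30L), seed = 4L)
  g <- generate_pin(cfg)
  pl <- plant_positives(g, cfg)
  sets <- generate_gene_sets(pl$graph, pl$positives, cfg)
  expect_length(sets, cfg$n_gene_sets)
  expect_true("PLANTED_PATHWAY" %in% names(sets))
  expect_gte(length(intersect(sets$PLANTED_PATHWAY, pl$positives)),
             ceiling(0.7 * length(pl$positives)))

  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  sets2 <- read_gmt(f)
  expect_equal(unclass(sets2), unclass(sets), ignore_attr = TRUE)

  one <- generate_gene_sets(pl$graph, character(),
                            synthetic_config(n_nodes = 300L, n_gene_sets = 1L,
                                             seed = 4L))
  expect_length(one, 1L)
})
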