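test_that("degrees count distinct in/out neighbors", {
  d <- compute_degrees(pg("a->b"))
  expect_equal(d[d$gene == "a", c("indegree", "outdegree")],
               data.frame(indegree = 0L, outdegree = 1L), ignore_attr = TRUE)
  expect_equal(d[d$gene == "b", c("indegree", "outdegree")],
               data.frame(indegree = 1L, outdegree = 0L), ignore_attr = TRUE)

  d3 <- compute_degrees(pg("a->b", "b->c", "c->a"))
  expect_true(all(d3$indegree == 1L & d3$outdegree == 1L))

  g <- random_digraph(8, 0.3, seed = 5)
  d <- compute_degrees(g)
  expect_equal(sum(d$indegree), nrow(g$edges))
  expect_equal(sum(d$outdegree), nrow(g$edges))
})

test_that("betweenness matches hand counts and the enumeration oracle", {
  b <- compute_betweenness(pg("a->b", "b->c"))
  expect_equal(unname(b[c("a", "b", "c")]), c(0, 1, 0))

  # directed 4-cycle: each node is interior to 3 ordered pairs' unique
  # shortest paths (one length-2 and two length-3 paths)
  cyc <- pg("n1->n2", "n2->n3", "n3->n4", "n4->n1")
  expect_equal(unname(compute_betweenness(cyc)), rep(3, 4))
  expect_equal(compute_betweenness(cyc), brute_betweenness(cyc))

  expect_equal(unname(compute_betweenness(pin_graph(NULL, nodes = letters[1:4]))),
               rep(0, 4))
})

test_that("betweenness equals path enumeration on random digraphs and trees", {
  for (seed in c(2, 9, 31)) {
    g <- random_digraph(6, 0.3, seed = seed)
    expect_equal(compute_betweenness(g), brute_betweenness(g),
                 tolerance = 1e-12)
  }
  # two-level directed tree: root -> a,b ; a -> c,d
  tree <- pg("r->a", "r->b", "a->c", "a->d")
  expect_equal(compute_betweenness(tree), brute_betweenness(tree))
  expect_equal(unname(compute_betweenness(tree)[c("r", "a", "b", "c", "d")]),
               c(0, 2, 0, 0, 0))
})

test_that("closeness follows the reachability-scaled convention", {
  cl <- compute_closeness(pg("a->b", "b->c"))
  expect_equal(unname(cl["a"]), 2 / 3)          # (2/2) * (2/3)
  expect_equal(unname(cl["b"]), (1 / 2) * 1)    # reaches c at distance 1
  expect_equal(unname(cl["c"]), 0)              # sink

  full <- pg("a->b", "b->a", "a->c", "c->a", "b->c", "c->b")
  expect_equal(unname(compute_closeness(full)), rep(1, 3))
})

test_that("pagerank is uniform on cycles, normalized, hub-dominant", {
  cyc <- pg("a->b", "b->c", "c->d", "d->a")
  expect_equal(unname(compute_pagerank(cyc)), rep(0.25, 4), tolerance = 1e-8)

  star <- pg("l1->hub", "l2->hub", "l3->hub", "l4->hub")
  pr <- compute_pagerank(star)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  expect_equal(names(which.max(pr)), "hub")

  for (seed in c(4, 12)) {
    g <- random_digraph(9, 0.25, seed = seed)
    pr <- compute_pagerank(g)
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    expect_true(all(pr > 0))
    # independent oracle: igraph's PageRank with the same damping
    ig <- igraph::page_rank(
      igraph::graph_from_data_frame(g$edges, vertices = g$nodes),
      damping = 0.85)$vector
    expect_equal(unname(pr[names(ig)]), unname(ig), tolerance = 1e-6)
  }
})

test_that("clustering coefficient matches the undirected formula", {
  tri <- pg("a->b", "b->c", "c->a")
  expect_equal(unname(compute_clustering(tri)), rep(1, 3))

  star <- pg("hub->l1", "hub->l2", "hub->l3")
  expect_equal(unname(compute_clustering(star)["hub"]), 0)

  # square 1-2-3-4 plus diagonal 1-3: node 1 has k=3, e=2 -> C = 2/3
  sq <- pg("n1->n2", "n2->n3", "n3->n4", "n4->n1", "n1->n3")
  expect_equal(unname(compute_clustering(sq)["n1"]), 2 / 3)
})

test_that("nnd averages neighbor degrees on the undirected projection", {
  star <- pg("hub->l1", "hub->l2", "hub->l3")
  nn <- compute_nnd(star)
  expect_equal(unname(nn["hub"]), 1)
  expect_equal(unname(nn[c("l1", "l2", "l3")]), rep(3, 3))

  cyc <- pg("a->b", "b->c", "c->a")  # 2-regular undirected
  expect_equal(unname(compute_nnd(cyc)), rep(2, 3))

  path <- pg("a->b", "b->c")
  expect_equal(unname(compute_nnd(path)["b"]), 1)
})

test_that("clustering and nnd are invariant under edge-direction reversal", {
  for (seed in c(6, 21)) {
    g <- random_digraph(8, 0.3, seed = seed)
    rev <- pin_graph(data.frame(from = g$edges$to, to = g$edges$from),
                     nodes = g$nodes)
    expect_equal(compute_clustering(g), compute_clustering(rev))
    expect_equal(compute_nnd(g), compute_nnd(rev))
  }
})

test_that("bow-tie decomposition labels the worked example", {
  g <- pg("1->2", "2->3", "3->2", "3->4")
  lab <- bowtie_decompose(g)
  expect_equal(unname(lab[c("1", "2", "3", "4")]),
               c("input", "core", "core", "output"))

  g5 <- pg("1->2", "2->3", "3->2", "3->4", "4->5")
  expect_equal(unname(bowtie_decompose(g5)["5"]), "output")

  full <- pg("a->b", "b->c", "c->a")
  expect_true(all(bowtie_decompose(full) == "core"))

  expect_warning(lab0 <- bowtie_decompose(pg("a->b", "b->c")), "degenerate")
  expect_true(all(lab0 == "other"))
})

test_that("one-hot bow-tie flags are mutually exclusive", {
  g <- pg("1->2", "2->3", "3->2", "3->4", "9->9x")
  oh <- bowtie_onehot(bowtie_decompose(g))
  expect_true(all(rowSums(oh) <= 1))
  expect_equal(colnames(oh), c("bowtie_input", "bowtie_core", "bowtie_output"))
})

test_that("maximum matching and driver counts match brute force", {
  path <- pg("1->2", "2->3")
  expect_equal(maximum_matching(path), 2L)
  expect_equal(maximum_matching(path), brute_matching(path))
  expect_equal(driver_count(path), 1L)

  expect_equal(maximum_matching(pin_graph(NULL, nodes = letters[1:5])), 0L)
  expect_equal(driver_count(pin_graph(NULL, nodes = letters[1:5])), 5L)

  cyc <- pg("a->b", "b->c", "c->d", "d->a")
  expect_equal(maximum_matching(cyc), 4L)   # perfect matching on a cycle
  expect_equal(driver_count(cyc), 1L)       # floor rule: max(0, 1)
})

test_that("indispensability follows the ND-recomputation definition", {
  path <- pg("1->2", "2->3")
  flags <- classify_indispensable(path)
  expect_equal(unname(flags[c("1", "2", "3")]), c(0L, 1L, 0L))
  expect_equal(unname(flags), unname(brute_indispensable(path)))

  edgeless <- pin_graph(NULL, nodes = letters[1:4])
  expect_true(all(classify_indispensable(edgeless) == 0L))
})

test_that("assemble_metric_table has 12 aligned columns", {
  g <- pg("1->2", "2->3", "3->2", "3->4")
  tbl <- assemble_metric_table(g)
  expect_equal(ncol(tbl), 12L)
  expect_equal(tbl$gene, g$nodes)
  expect_equal(tbl$betweenness, unname(compute_betweenness(g)))
  expect_equal(tbl$pagerank, unname(compute_pagerank(g)))
  expect_equal(tbl$bowtie_core,
               unname(as.integer(bowtie_decompose(g) == "core")))

  empty <- suppressWarnings(
    assemble_metric_table(pin_graph(NULL, nodes = c("x", "y"))))
  expect_equal(ncol(empty), 12L)
  expect_true(all(empty$indegree == 0L & empty$outdegree == 0L &
                  empty$betweenness == 0 & empty$closeness == 0))
})

test_that("latent-metric Spearman correlations honor sign and n.a. dims", {
  g <- generate_pin(synthetic_config(n_nodes = 60L, seed = 8L))
  tbl <- suppressWarnings(assemble_metric_table(g))
  latent <- cbind(dim_1 = as.numeric(tbl$outdegree),
                  dim_2 = max(tbl$pagerank) - tbl$pagerank,
                  dim_3 = 0)
  rownames(latent) <- tbl$gene
  co <- correlate_latent_metrics(latent, tbl)
  expect_equal(unname(co["dim_1", "outdegree"]), 1, tolerance = 1e-12)
  expect_equal(unname(co["dim_2", "pagerank"]), -1, tolerance = 1e-12)
  expect_true(attr(co, "na_dims")[["dim_3"]])
  expect_true(all(is.na(co["dim_3", ])))
  expect_true(all(abs(co[!is.na(co)]) <= 1 + 1e-12))

  bad <- latent[rev(seq_len(nrow(latent))), ]
  expect_error(correlate_latent_metrics(bad, tbl), "aligned")
})
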