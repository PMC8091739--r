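#' Per-gene indegree and outdegree
#'
#' Indegree counts distinct upstream neighbors, outdegree distinct downstream
#' neighbors (the graph is simple, so counts equal numbers of incident edges).
#'
#' @param graph a \code{pin_graph}.
#' @return data.frame with columns \code{gene}, \code{indegree},
#'   \code{outdegree}, in graph node order.
#' @export
compute_degrees <- function(graph) {
  stopifnot(inherits(graph, "pin_graph"))
  n <- length(graph$nodes)
  data.frame(
    gene = graph$nodes,
    indegree = tabulate(match(graph$edges$to, graph$nodes), nbins = n),
    outdegree = tabulate(match(graph$edges$from, graph$nodes), nbins = n),
    stringsAsFactors = FALSE)
}

#' Directed shortest-path betweenness centrality
#'
#' Number of shortest directed paths between ordered gene pairs passing
#' through each gene (endpoints excluded); a pair's contribution is split
#' equally among its equal-length shortest paths.
#'
#' @param graph a \code{pin_graph}.
#' @return named numeric vector in graph node order.
#' @export
compute_betweenness <- function(graph) {
  stopifnot(inherits(graph, "pin_graph"))
  g <- as_igraph(graph)
  b <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  stats::setNames(as.numeric(b), graph$nodes)
}

#' Out-closeness centrality with reachability scaling
#'
#' For gene i with r reachable genes at total distance S, closeness is
#' (r / (N - 1)) * (r / S): the reciprocal mean out-distance to reachable
#' genes, scaled by the reachable fraction (Wasserman-Faust convention, so
#' the score is well defined on disconnected directed graphs). Genes reaching
#' nothing score 0.
#'
#' @param graph a \code{pin_graph}.
#' @return named numeric vector in graph node order.
#' @export
compute_closeness <- function(graph) {
  stopifnot(inherits(graph, "pin_graph"))
  n <- length(graph$nodes)
  if (n == 1L) return(stats::setNames(0, graph$nodes))
  d <- igraph::distances(as_igraph(graph), mode = "out")
  diag(d) <- Inf
  cl <- apply(d, 1L, function(row) {
    fin <- row[is.finite(row)]
    r <- length(fin)
    if (r == 0L) 0 else (r / (n - 1)) * (r / sum(fin))
  })
  stats::setNames(as.numeric(cl), graph$nodes)
}

#' PageRank by power iteration
#'
#' Damped random-walk stationary distribution on the directed graph; dangling
#' genes (outdegree 0) redistribute their mass uniformly. Iterates
#' \code{v <- (1 - damping)/N + damping * (t(P) v + dangling/N)} until the L1
#' change drops below \code{tol}.
#'
#' @param graph a \code{pin_graph}.
#' @param damping damping factor, default 0.85.
#' @param tol L1 convergence tolerance, default 1e-10.
#' @param max_iter iteration cap, default 1000.
#' @return named numeric vector summing to 1, in graph node order.
#' @export
compute_pagerank <- function(graph, damping = 0.85, tol = 1e-10,
                             max_iter = 1000L) {
  stopifnot(inherits(graph, "pin_graph"))
  n <- length(graph$nodes)
  i <- match(graph$edges$from, graph$nodes)
  j <- match(graph$edges$to, graph$nodes)
  outdeg <- tabulate(i, nbins = n)
  v <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    w <- v / pmax(outdeg, 1L)
    flow <- numeric(n)
    if (length(i) > 0L) {
      agg <- rowsum(w[i], j)
      flow[as.integer(rownames(agg))] <- agg[, 1L]
    }
    dangling <- sum(v[outdeg == 0L])
    v_new <- (1 - damping) / n + damping * (flow + dangling / n)
    if (sum(abs(v_new - v)) < tol) {
      v <- v_new / sum(v_new)
      return(stats::setNames(v, graph$nodes))
    }
    v <- v_new
  }
  stop("PageRank power iteration failed to converge in ", max_iter,
       " iterations")
}

#' Local clustering coefficient (undirected projection)
#'
#' \eqn{C_i = 2 e_i / (k_i (k_i - 1))} where \eqn{k_i} is the number of
#' distinct undirected neighbors of gene i and \eqn{e_i} the number of
#' undirected links among them; genes with \eqn{k_i < 2} score 0.
#'
#' @param graph a \code{pin_graph}.
#' @return named numeric vector in [0,1], in graph node order.
#' @export
compute_clustering <- function(graph) {
  stopifnot(inherits(graph, "pin_graph"))
  g <- as_igraph(graph, directed = FALSE)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  stats::setNames(as.numeric(cc), graph$nodes)
}

#' Nearest-neighbor degree (undirected projection)
#'
#' Mean undirected degree over a gene's undirected neighbors; isolated genes
#' score 0.
#'
#' @param graph a \code{pin_graph}.
#' @return named numeric vector in graph node order.
#' @export
compute_nnd <- function(graph) {
  stopifnot(inherits(graph, "pin_graph"))
  g <- as_igraph(graph, directed = FALSE)
  deg <- igraph::degree(g)
  al <- igraph::as_adj_list(g, mode = "all")
  nnd <- vapply(al, function(nb) {
    nb <- unique(as.integer(nb))
    if (length(nb) == 0L) 0 else mean(deg[nb])
  }, 0)
  stats::setNames(as.numeric(nnd), graph$nodes)
}

#' Bow-tie decomposition of a directed graph
#'
#' The core is the largest strongly connected component (ties broken by the
#' component containing the lexicographically smallest gene); input genes lie
#' outside the core but can reach it; output genes are reachable from it; all
#' remaining genes (tendrils, tubes, disconnected) are labeled "other". A
#' degenerate size-1 core labels every gene "other" with a warning.
#'
#' @param graph a \code{pin_graph}.
#' @return named character vector with levels input/core/output/other, in
#'   graph node order.
#' @export
bowtie_decompose <- function(graph) {
  stopifnot(inherits(graph, "pin_graph"))
  n <- length(graph$nodes)
  lab <- stats::setNames(rep("other", n), graph$nodes)
  if (n == 0L) return(lab)
  g <- as_igraph(graph)
  comp <- igraph::components(g, mode = "strong")
  max_size <- max(comp$csize)
  if (max_size < 2L) {
    warning("largest strongly connected component has size 1; ",
            "bow-tie decomposition degenerate, all genes labeled 'other'")
    return(lab)
  }
  cand <- which(comp$csize == max_size)
  if (length(cand) > 1L) {
    # tie-break: component containing the lexicographically smallest gene
    firsts <- vapply(cand, function(cid)
      min(graph$nodes[comp$membership == cid]), "")
    cand <- cand[order(firsts)][1L]
  }
  core <- comp$membership == cand
  c0 <- which(core)[1L]
  d_to <- igraph::distances(g, v = c0, mode = "in")[1L, ]    # who reaches core
  d_from <- igraph::distances(g, v = c0, mode = "out")[1L, ] # core reaches who
  lab[core] <- "core"
  lab[!core & is.finite(d_to)] <- "input"
  lab[!core & is.finite(d_from)] <- "output"
  lab
}

#' One-hot encoding of bow-tie labels
#' @param labels output of \code{bowtie_decompose}.
#' @return data.frame with binary columns \code{bowtie_input},
#'   \code{bowtie_core}, \code{bowtie_output} ("other" rows are all zero).
#' @export
bowtie_onehot <- function(labels) {
  data.frame(bowtie_input = as.integer(labels == "input"),
             bowtie_core = as.integer(labels == "core"),
             bowtie_output = as.integer(labels == "output"))
}

#' Maximum matching size for network controllability
#'
#' Size of a maximum matching in the bipartite graph that has an out-copy and
#' an in-copy of every gene and one bipartite edge per directed edge — the
#' structural-controllability construction behind minimum driver-node counts.
#'
#' @param graph a \code{pin_graph}.
#' @return integer matching size.
#' @export
maximum_matching <- function(graph) {
  stopifnot(inherits(graph, "pin_graph"))
  if (nrow(graph$edges) == 0L) return(0L)
  n <- length(graph$nodes)
  i <- match(graph$edges$from, graph$nodes)
  j <- match(graph$edges$to, graph$nodes)
  bg <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n), rep(TRUE, n)),
    edges = as.vector(rbind(i, n + j)),
    directed = FALSE)
  as.integer(igraph::max_bipartite_match(bg)$matching_size)
}

#' Minimum number of driver nodes (ND)
#'
#' \code{ND = max(N - matching_size, 1)}: the genes left unmatched by a
#' maximum matching must be driven externally; a perfectly matched network
#' still needs one driver.
#'
#' @param graph a \code{pin_graph}.
#' @return integer driver-node count.
#' @export
driver_count <- function(graph) {
  stopifnot(inherits(graph, "pin_graph"))
  max(length(graph$nodes) - maximum_matching(graph), 1L)
}

#' Indispensable genes under controllability analysis
#'
#' A gene is indispensable when deleting it (with its incident edges)
#' increases the minimum driver-node count: \code{ND(G - v) > ND(G)}.
#'
#' @param graph a \code{pin_graph}.
#' @return named integer (0/1) vector in graph node order.
#' @export
classify_indispensable <- function(graph) {
  stopifnot(inherits(graph, "pin_graph"))
  nd0 <- driver_count(graph)
  flags <- vapply(graph$nodes, function(v) {
    keep <- graph$edges$from != v & graph$edges$to != v
    sub <- pin_graph(graph$edges[keep, , drop = FALSE],
                     nodes = setdiff(graph$nodes, v))
    as.integer(driver_count(sub) > nd0)
  }, integer(1L))
  stats::setNames(flags, graph$nodes)
}

#' Assemble the per-gene network-metric table
#'
#' Twelve fixed columns: gene, indegree, outdegree, betweenness, closeness,
#' pagerank, clustering, nnd, bowtie_input, bowtie_core, bowtie_output,
#' indispensable — the nine-metric suite with the bow-tie layer one-hot
#' encoded.
#'
#' @param graph a \code{pin_graph}.
#' @return data.frame of class \code{node_metric_table}, rows in graph node
#'   order.
#' @export
assemble_metric_table <- function(graph) {
  stopifnot(inherits(graph, "pin_graph"))
  deg <- compute_degrees(graph)
  oh <- bowtie_onehot(suppressWarnings(bowtie_decompose(graph)))
  tbl <- data.frame(
    gene = graph$nodes,
    indegree = deg$indegree,
    outdegree = deg$outdegree,
    betweenness = unname(compute_betweenness(graph)),
    closeness = unname(compute_closeness(graph)),
    pagerank = unname(compute_pagerank(graph)),
    clustering = unname(compute_clustering(graph)),
    nnd = unname(compute_nnd(graph)),
    bowtie_input = oh$bowtie_input,
    bowtie_core = oh$bowtie_core,
    bowtie_output = oh$bowtie_output,
    indispensable = unname(classify_indispensable(graph)),
    stringsAsFactors = FALSE)
  class(tbl) <- c("node_metric_table", "data.frame")
  tbl
}

#' Write the metric table as TSV
#' @param metrics a \code{node_metric_table}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_metric_table <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Spearman correlation between latent dimensions and network metrics
#'
#' For every (latent dimension, metric) pair, Spearman's rho with average
#' ranks for ties. Latent dimensions with zero variance (e.g. dead rectifier
#' units encoding 0 for all genes) are flagged n.a. and carry NA correlations,
#' mirroring how dead embedding dimensions are reported alongside live ones.
#'
#' @param latent numeric N x d matrix, rows aligned to \code{metrics$gene}
#'   (rownames checked when present).
#' @param metrics a \code{node_metric_table} (non-numeric columns dropped).
#' @return d x m matrix of class \code{latent_metric_correlation} with an
#'   \code{na_dims} logical attribute marking zero-variance dimensions.
#' @export
correlate_latent_metrics <- function(latent, metrics) {
  latent <- as.matrix(latent)
  stopifnot(nrow(latent) == nrow(metrics))
  if (!is.null(rownames(latent)) && !all(rownames(latent) == metrics$gene))
    stop("latent matrix rows are not aligned to the metric table genes")
  num <- metrics[vapply(metrics, is.numeric, TRUE)]
  if (is.null(colnames(latent)))
    colnames(latent) <- paste0("dim_", seq_len(ncol(latent)))
  na_dims <- apply(latent, 2L, function(x) stats::var(x) == 0)
  rho <- matrix(NA_real_, ncol(latent), ncol(num),
                dimnames = list(colnames(latent), names(num)))
  live <- which(!na_dims)
  if (length(live) > 0L) {
    rl <- apply(latent[, live, drop = FALSE], 2L, rank)
    rm_ <- apply(as.matrix(num), 2L, rank)
    rho[live, ] <- suppressWarnings(stats::cor(rl, rm_, method = "pearson"))
  }
  structure(rho, na_dims = na_dims, class = "latent_metric_correlation")
}

#' Write a latent-metric correlation matrix as TSV
#' @param corr a \code{latent_metric_correlation}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_correlation_matrix <- function(corr, path) {
  df <- data.frame(dimension = rownames(corr), unclass(corr)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
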