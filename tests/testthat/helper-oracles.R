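# Brute-force oracles, independent of the package implementations.

# small pin_graph from "a->b" edge strings
pg <- function(..., nodes = NULL) {
  specs <- c(...)
  if (length(specs) == 0L)
    return(pin_graph(NULL, nodes = nodes))
  parts <- strsplit(specs, "->", fixed = TRUE)
  pin_graph(data.frame(from = trimws(vapply(parts, `[[`, "", 1L)),
                       to = trimws(vapply(parts, `[[`, "", 2L)),
                       stringsAsFactors = FALSE),
            nodes = nodes)
}

# seeded Erdos-Renyi digraph (no self-loops) on n named nodes
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- letters[seq_len(n)]
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < p
  pin_graph(pairs[keep, , drop = FALSE], nodes = nodes)
}

# boolean reachability closure (Floyd-Warshall); reach[i,j] TRUE iff a
# directed path i -> ... -> j of length >= 1 exists
brute_reach <- function(graph) {
  n <- length(graph$nodes)
  r <- matrix(FALSE, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges) > 0L)
    r[cbind(match(graph$edges$from, graph$nodes),
            match(graph$edges$to, graph$nodes))] <- TRUE
  for (k in seq_len(n)) for (i in seq_len(n)) if (r[i, k])
    r[i, ] <- r[i, ] | r[k, ]
  r
}

# bow-tie labels by definition: core = largest SCC (mutual reachability,
# lexicographic tie-break), input reaches core, output reached from core
brute_bowtie <- function(graph) {
  n <- length(graph$nodes)
  lab <- stats::setNames(rep("other", n), graph$nodes)
  if (n == 0L) return(lab)
  r <- brute_reach(graph)
  mutual <- r & t(r)
  diag(mutual) <- TRUE
  # SCC membership: rows of `mutual` partition the nodes
  comp_id <- apply(mutual, 1L, function(row) paste(which(row), collapse = ","))
  sizes <- table(comp_id)
  mx <- max(sizes)
  if (mx < 2L) return(lab)
  cand <- names(sizes)[sizes == mx]
  firsts <- vapply(cand, function(cid)
    min(graph$nodes[comp_id == cid]), "")
  core_id <- cand[order(firsts)][1L]
  core <- comp_id == core_id
  c0 <- which(core)[1L]
  lab[core] <- "core"
  lab[!core & r[, c0]] <- "input"
  lab[!core & r[c0, ]] <- "output"
  lab
}

# exhaustive maximum matching in the bipartite controllability construction:
# out-copy/in-copy per node, one bipartite edge per directed edge
brute_matching <- function(graph) {
  edges <- graph$edges
  m <- nrow(edges)
  if (m == 0L) return(0L)
  best <- 0L
  recurse <- function(i, used_from, used_to, size) {
    if (size + (m - i + 1L) <= best) return()
    if (i > m) { best <<- max(best, size); return() }
    f <- edges$from[i]; t <- edges$to[i]
    if (!(f %in% used_from) && !(t %in% used_to))
      recurse(i + 1L, c(used_from, f), c(used_to, t), size + 1L)
    recurse(i + 1L, used_from, used_to, size)
  }
  recurse(1L, character(), character(), 0L)
  best
}

brute_nd <- function(graph) {
  max(length(graph$nodes) - brute_matching(graph), 1L)
}

# definitional indispensability: ND(G - v) > ND(G), via the brute matcher
brute_indispensable <- function(graph) {
  nd0 <- brute_nd(graph)
  vapply(graph$nodes, function(v) {
    keep <- graph$edges$from != v & graph$edges$to != v
    sub <- pin_graph(graph$edges[keep, , drop = FALSE],
                     nodes = setdiff(graph$nodes, v))
    as.integer(brute_nd(sub) > nd0)
  }, integer(1L))
}

# betweenness by exhaustive shortest-path enumeration (BFS path counting)
brute_betweenness <- function(graph) {
  n <- length(graph$nodes)
  adj <- lapply(graph$nodes, function(v)
    graph$edges$to[graph$edges$from == v])
  names(adj) <- graph$nodes
  bt <- stats::setNames(numeric(n), graph$nodes)
  all_shortest <- function(s, t) {
    # BFS layers, then recursive path reconstruction
    dist <- stats::setNames(rep(Inf, n), graph$nodes)
    dist[s] <- 0
    frontier <- s
    while (length(frontier) > 0L && !is.finite(dist[t])) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(dist[nxt])]
      dist[nxt] <- dist[frontier[1L]] + 1
      frontier <- nxt
    }
    if (!is.finite(dist[t])) return(list())
    paths <- list()
    walk <- function(v, acc) {
      if (v == t) { paths[[length(paths) + 1L]] <<- acc; return() }
      for (w in adj[[v]]) if (dist[w] == dist[v] + 1 && dist[w] <= dist[t])
        walk(w, c(acc, w))
    }
    walk(s, s)
    paths
  }
  for (s in graph$nodes) for (t in graph$nodes) {
    if (s == t) next
    paths <- all_shortest(s, t)
    if (length(paths) == 0L) next
    for (p in paths) {
      inner <- setdiff(p, c(s, t))
      bt[inner] <- bt[inner] + 1 / length(paths)
    }
  }
  bt
}

# upper-tail hypergeometric P(X >= k) by direct pmf summation
brute_hyper_upper <- function(k, N, K, n) {
  kk <- seq.int(max(k, 0L), min(K, n))
  if (length(kk) == 0L) return(if (k <= 0) 1 else 0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# tiny desk settings shared by heavier tests
tiny_synth <- function(seed = 1L, n_nodes = 200L, n_positives = 15L,
                       cohesion = 0.9) {
  synthetic_config(n_nodes = n_nodes, n_positives = n_positives,
                   positive_cohesion = cohesion, seed = seed)
}
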