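#' Configuration for the synthetic PIN world
#'
#' Defaults emulate, at desk scale, a sparse directed scale-free interactome
#' with a small planted positive class (the known drug targets) whose
#' adjacency rows are topologically cohesive, plus a drug->target map and GMT
#' gene-set collections. One global seed fans out to per-stage child seeds
#' (seed, seed+1, ...) so stages can be regenerated independently.
#'
#' @param n_nodes number of genes.
#' @param edges_per_new_node out-edges each newly attached gene sends.
#' @param n_positives size of the planted positive class.
#' @param positive_cohesion probability in [0,1] that a planted positive's
#'   out-neighbors are drawn from a shared anchor neighborhood rather than at
#'   random; 0 = no signal, 1 = maximal cohesion.
#' @param n_drugs number of synthetic drugs.
#' @param targets_per_drug integer range (length-2) of targets per drug.
#' @param positive_target_enrichment fraction of drug targets drawn from the
#'   planted positives / anchor neighborhood.
#' @param n_gene_sets number of gene sets in the GMT collection.
#' @param gene_set_size integer range (length-2) of gene-set sizes.
#' @param seed global integer seed.
#' @return a validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_nodes = 500L, edges_per_new_node = 3L,
                             n_positives = 30L, positive_cohesion = 0.9,
                             n_drugs = 50L, targets_per_drug = c(2L, 8L),
                             positive_target_enrichment = 0.5,
                             n_gene_sets = 25L, gene_set_size = c(10L, 40L),
                             seed = 1L) {
  cfg <- list(n_nodes = as.integer(n_nodes),
              edges_per_new_node = as.integer(edges_per_new_node),
              n_positives = as.integer(n_positives),
              positive_cohesion = positive_cohesion,
              n_drugs = as.integer(n_drugs),
              targets_per_drug = as.integer(targets_per_drug),
              positive_target_enrichment = positive_target_enrichment,
              n_gene_sets = as.integer(n_gene_sets),
              gene_set_size = as.integer(gene_set_size),
              seed = as.integer(seed))
  if (cfg$n_nodes <= 0L || cfg$edges_per_new_node <= 0L || cfg$n_drugs <= 0L ||
      cfg$n_gene_sets <= 0L)
    stop("synthetic_config: all counts must be positive")
  if (cfg$n_positives < 0L || cfg$n_positives >= cfg$n_nodes)
    stop("synthetic_config: need 0 <= n_positives < n_nodes")
  if (cfg$positive_cohesion < 0 || cfg$positive_cohesion > 1 ||
      cfg$positive_target_enrichment < 0 || cfg$positive_target_enrichment > 1)
    stop("synthetic_config: fractions must lie in [0,1]")
  if (cfg$n_nodes < cfg$edges_per_new_node + 1L)
    stop("synthetic_config: need n_nodes >= edges_per_new_node + 1")
  if (length(cfg$targets_per_drug) != 2L || length(cfg$gene_set_size) != 2L)
    stop("synthetic_config: targets_per_drug and gene_set_size are ranges")
  class(cfg) <- "synthetic_config"
  cfg
}

# zero-padded deterministic gene names: lexicographic order == creation order
synthetic_gene_names <- function(n) {
  sprintf(paste0("g%0", nchar(as.character(n)), "d"), seq_len(n))
}

#' Generate a sparse directed scale-free PIN
#'
#' Growth by preferential attachment: after an initial directed cycle of
#' \code{edges_per_new_node + 1} genes, each new gene sends
#' \code{edges_per_new_node} edges to distinct existing genes chosen with
#' probability proportional to indegree + 1, and receives one edge from a
#' uniformly chosen existing gene. The result is connected as an undirected
#' graph, heavy-tailed in indegree, and a pure function of the seed.
#'
#' @param config a \code{synthetic_config}.
#' @return a \code{pin_graph}.
#' @export
generate_pin <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_nodes
  m <- config$edges_per_new_node
  nodes <- synthetic_gene_names(n)
  with_seed(config$seed, {
    m0 <- m + 1L
    from <- seq_len(m0)
    to <- c(seq_len(m0)[-1L], 1L)
    indeg <- integer(n)
    indeg[to] <- 1L
    ef <- vector("list", n)
    et <- vector("list", n)
    ef[[1L]] <- from
    et[[1L]] <- to
    for (v in seq.int(m0 + 1L, n)) {
      existing <- seq_len(v - 1L)
      k <- min(m, v - 1L)
      targets <- sample(existing, k, prob = indeg[existing] + 1)
      src <- sample(existing, 1L)
      ef[[v]] <- c(rep.int(v, k), src)
      et[[v]] <- c(targets, v)
      indeg[targets] <- indeg[targets] + 1L
      indeg[v] <- indeg[v] + 1L
    }
    pin_graph(data.frame(from = nodes[unlist(ef)], to = nodes[unlist(et)],
                         stringsAsFactors = FALSE), nodes = nodes)
  })
}

# internal: undirected neighborhood within `steps` hops of `anchor`
undirected_neighborhood <- function(graph, anchor, steps) {
  g <- as_igraph(graph, directed = FALSE)
  nb <- igraph::ego(g, order = steps,
                    nodes = match(anchor, graph$nodes))[[1L]]
  setdiff(graph$nodes[as.integer(nb)], anchor)
}

#' Plant a topologically cohesive positive class in a PIN
#'
#' Picks an anchor gene of above-median undirected degree (capped at the 80th
#' percentile so the anchor is not a global hub whose neighborhood spans the
#' network), samples \code{n_positives} genes preferentially from its 2-step
#' undirected neighborhood (falling back to 3 steps when too small), and
#' rewires each positive so at least a \code{positive_cohesion} fraction of
#' its out-edges land inside the anchor's immediate (1-hop) neighborhood —
#' the compact shared support that makes positives' adjacency rows mutually
#' similar (higher pairwise Jaccard than a random gene sample), the learnable
#' signal the downstream classifier is expected to recover.
#'
#' @param graph a \code{pin_graph}, typically from \code{generate_pin}.
#' @param config a \code{synthetic_config} (uses child seed \code{seed + 1}).
#' @return a list of class \code{planted_pin}: \code{graph} (rewired
#'   \code{pin_graph}), \code{positives} (sorted gene identifiers),
#'   \code{anchor}, \code{neighborhood} (the 2-step sampling neighborhood)
#'   and \code{inside} (the 1-hop rewiring support). The rewired graph must
#'   be the one carried forward; the input graph is unchanged.
#' @export
plant_positives <- function(graph, config) {
  stopifnot(inherits(graph, "pin_graph"), inherits(config, "synthetic_config"))
  np <- config$n_positives
  if (np == 0L)
    return(structure(list(graph = graph, positives = character(),
                          anchor = NA_character_,
                          neighborhood = character(), inside = character()),
                     class = "planted_pin"))
  coh <- config$positive_cohesion
  with_seed(config$seed + 1L, {
    deg <- tabulate(match(c(graph$edges$from, graph$edges$to), graph$nodes),
                    nbins = length(graph$nodes))
    md <- stats::median(deg)
    eligible <- graph$nodes[deg > md & deg <= stats::quantile(deg, 0.8)]
    if (length(eligible) == 0L) eligible <- graph$nodes[deg > md]
    anchor <- sample(eligible, 1L)
    nbhd <- undirected_neighborhood(graph, anchor, 2L)
    if (length(nbhd) < np) {
      nbhd <- undirected_neighborhood(graph, anchor, 3L)
      if (length(nbhd) < np)
        stop("anchor 3-step neighborhood smaller than n_positives; ",
             "increase connectivity or reduce n_positives")
    }
    in_nbhd <- stats::runif(np) < coh
    pos <- character(np)
    pool_nb <- sample(nbhd)
    used <- character()
    for (i in seq_len(np)) {
      if (in_nbhd[i]) {
        cand <- setdiff(pool_nb, used)
      } else {
        cand <- setdiff(graph$nodes, c(anchor, used))
      }
      pos[i] <- cand[[1L + floor(stats::runif(1) * length(cand))]]
      used <- c(used, pos[i])
    }
    # rewire each positive: >= coh fraction of out-edges inside the anchor's
    # immediate neighborhood (anchor itself counts as inside)
    inside <- c(anchor, undirected_neighborhood(graph, anchor, 1L))
    edges <- graph$edges
    for (p in pos) {
      out_idx <- which(edges$from == p)
      k <- length(out_idx)
      if (k == 0L) next
      need <- ceiling(coh * k)
      is_in <- edges$to[out_idx] %in% inside
      deficit <- need - sum(is_in)
      if (deficit > 0L) {
        movable <- out_idx[!is_in]
        move <- movable[seq_len(deficit)]
        for (e in move) {
          cand <- setdiff(inside, c(p, edges$to[edges$from == p]))
          if (length(cand) == 0L) break
          edges$to[e] <- cand[[1L + floor(stats::runif(1) * length(cand))]]
        }
      }
    }
    structure(list(graph = pin_graph(edges, nodes = graph$nodes),
                   positives = sort(pos), anchor = anchor,
                   neighborhood = sort(nbhd), inside = sort(inside)),
              class = "planted_pin")
  })
}

#' Mean pairwise Jaccard similarity of adjacency rows
#'
#' Diagnostic used to verify planted cohesion: Jaccard similarity of the
#' out-neighbor sets of every pair of the given genes, averaged.
#'
#' @param graph a \code{pin_graph}.
#' @param genes character vector of genes (length >= 2).
#' @return mean pairwise Jaccard index (pairs with two empty rows count 0).
#' @export
adjacency_jaccard <- function(graph, genes) {
  stopifnot(inherits(graph, "pin_graph"), length(genes) >= 2L)
  outs <- lapply(genes, function(g) graph$edges$to[graph$edges$from == g])
  pairs <- utils::combn(length(genes), 2L)
  mean(apply(pairs, 2L, function(ij) {
    a <- outs[[ij[1L]]]; b <- outs[[ij[2L]]]
    u <- length(union(a, b))
    if (u == 0L) 0 else length(intersect(a, b)) / u
  }))
}

#' Generate a synthetic drug -> target map
#'
#' Each drug draws its target count uniformly from
#' \code{targets_per_drug}; a \code{positive_target_enrichment} fraction of
#' targets comes from the planted positives (plus anchor neighborhood), the
#' remainder uniformly from all genes. Child seed \code{seed + 2}.
#'
#' @param graph a \code{pin_graph}.
#' @param positives character vector of planted positives (may be empty).
#' @param config a \code{synthetic_config}.
#' @param neighborhood optional anchor neighborhood to include in the
#'   enriched pool (defaults to none).
#' @return a \code{drug_target_map}.
#' @export
generate_drug_target_map <- function(graph, positives, config,
                                     neighborhood = character()) {
  stopifnot(inherits(graph, "pin_graph"), inherits(config, "synthetic_config"))
  rng <- config$targets_per_drug
  if (max(rng) > length(graph$nodes))
    stop("targets_per_drug upper bound exceeds the number of genes")
  pool <- unique(c(positives, neighborhood))
  enr <- if (length(pool) > 0L) config$positive_target_enrichment else 0
  with_seed(config$seed + 2L, {
    drugs <- sprintf("drug%03d", seq_len(config$n_drugs))
    rows <- lapply(seq_along(drugs), function(i) {
      nt <- sample(seq.int(rng[1L], rng[2L]), 1L)
      from_pool <- stats::runif(nt) < enr
      t1 <- if (any(from_pool))
        sample(pool, min(sum(from_pool), length(pool))) else character()
      t2 <- sample(graph$nodes, nt - length(t1))
      data.frame(drug = drugs[i], target = unique(c(t1, t2)),
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    drug_target_map(rows$drug, rows$target)
  })
}

#' Generate a synthetic GMT gene-set collection
#'
#' Emits \code{n_gene_sets} sets with sizes uniform in \code{gene_set_size}.
#' Exactly one set (the "true pathway", named \code{PLANTED_PATHWAY}) is
#' seeded to contain at least 70\% of the planted genes, so over-representation
#' analysis of a query recovering the planted class should rank it first.
#' Child seed \code{seed + 3}.
#'
#' @param graph a \code{pin_graph}.
#' @param planted character vector of planted genes.
#' @param config a \code{synthetic_config}.
#' @return named list of character vectors of class \code{gene_set_collection}.
#' @export
generate_gene_sets <- function(graph, planted, config) {
  stopifnot(inherits(graph, "pin_graph"), inherits(config, "synthetic_config"))
  rng <- config$gene_set_size
  if (max(rng) > length(graph$nodes))
    stop("gene_set_size upper bound exceeds the number of genes")
  with_seed(config$seed + 3L, {
    sizes <- sample(seq.int(rng[1L], rng[2L]), config$n_gene_sets,
                    replace = TRUE)
    sets <- lapply(sizes, function(s) sort(sample(graph$nodes, s)))
    names(sets) <- sprintf("SET%03d", seq_along(sets))
    if (length(planted) > 0L) {
      need <- ceiling(0.7 * length(planted))
      size <- max(sizes[1L], need)
      core <- sample(planted, need)
      fill <- sample(setdiff(graph$nodes, core), size - need)
      sets[[1L]] <- sort(c(core, fill))
      names(sets)[1L] <- "PLANTED_PATHWAY"
    }
    structure(sets, class = "gene_set_collection")
  })
}

#' Write a gene-set collection in GMT format
#'
#' GMT dialect: \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param sets a named list of character vectors.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(length(sets) > 0L, !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
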