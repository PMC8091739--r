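#' Construct a directed protein-interaction network (PIN)
#'
#' The canonical graph container used throughout the package. Nodes are gene
#' identifiers (exact strings, no alias resolution); a directed edge
#' \code{i -> j} means gene \code{j} is a downstream interacting partner of
#' gene \code{i}. Duplicate edges are collapsed and self-loops removed; both
#' events are counted in the attached load report. Nodes are ordered
#' lexicographically so that matrix layouts are deterministic across runs.
#'
#' @param edges two-column data.frame (or matrix) of character source/target
#'   gene identifiers.
#' @param nodes optional character vector of additional isolated nodes to
#'   retain.
#' @return an object of class \code{pin_graph}: a list with \code{nodes}
#'   (sorted unique gene identifiers), \code{edges} (deduplicated, loop-free
#'   data.frame with columns \code{from}, \code{to}) and \code{report}
#'   (n_nodes, n_edges, n_duplicates_dropped, n_self_loops_dropped).
#' @export
pin_graph <- function(edges, nodes = NULL) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L)
    stop("edges must have at least two columns (source, target)")
  edges <- data.frame(from = as.character(edges[[1L]]),
                      to = as.character(edges[[2L]]),
                      stringsAsFactors = FALSE)
  n_raw <- nrow(edges)
  endpoint_nodes <- unique(c(edges$from, edges$to))  # before loop removal
  loops <- edges$from == edges$to
  n_loops <- sum(loops)
  edges <- edges[!loops, , drop = FALSE]
  dup <- duplicated(edges)
  n_dup <- sum(dup)
  edges <- edges[!dup, , drop = FALSE]
  all_nodes <- sort(unique(c(endpoint_nodes, as.character(nodes))))
  rownames(edges) <- NULL
  structure(
    list(nodes = all_nodes, edges = edges,
         report = list(n_nodes = length(all_nodes), n_edges = nrow(edges),
                       n_duplicates_dropped = n_dup,
                       n_self_loops_dropped = n_loops,
                       n_rows_read = n_raw)),
    class = "pin_graph")
}

#' @export
print.pin_graph <- function(x, ...) {
  cat(sprintf("pin_graph: %d genes, %d directed interactions\n",
              length(x$nodes), nrow(x$edges)))
  r <- x$report
  if (r$n_duplicates_dropped > 0L || r$n_self_loops_dropped > 0L)
    cat(sprintf("  (load dropped %d duplicate edge(s), %d self-loop(s))\n",
                r$n_duplicates_dropped, r$n_self_loops_dropped))
  invisible(x)
}

#' Number of genes in a PIN
#' @param graph a \code{pin_graph}.
#' @return integer gene count.
#' @export
n_genes <- function(graph) {
  stopifnot(inherits(graph, "pin_graph"))
  length(graph$nodes)
}

#' Read a directed edge list into a PIN graph
#'
#' Reads two-column delimited text (source, target). Lines starting with
#' \code{#} are ignored. Duplicate edges and self-loops are dropped with
#' counts recorded in the load report.
#'
#' @param path path to the edge-list file.
#' @param delimiter field delimiter, default tab.
#' @param has_header logical; skip the first non-comment line if TRUE.
#' @return a \code{pin_graph}.
#' @export
read_edge_list <- function(path, delimiter = "\t", has_header = FALSE) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (has_header && length(idx) > 0L) idx <- idx[-1L]
  if (length(idx) == 0L)
    return(pin_graph(NULL))
  parts <- strsplit(lines[idx], delimiter, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    bad <- idx[which(nf < 2L)[1L]]
    stop(sprintf("parse error at line %d of %s: fewer than 2 columns",
                 bad, path))
  }
  edges <- data.frame(from = vapply(parts, `[[`, "", 1L),
                      to = vapply(parts, `[[`, "", 2L),
                      stringsAsFactors = FALSE)
  g <- pin_graph(edges)
  message(sprintf(
    "read_edge_list: %d genes, %d edges (%d duplicates, %d self-loops dropped)",
    length(g$nodes), nrow(g$edges), g$report$n_duplicates_dropped,
    g$report$n_self_loops_dropped))
  g
}

#' Write a PIN graph as a delimited edge list
#' @param graph a \code{pin_graph}.
#' @param path output file path.
#' @param delimiter field delimiter, default tab.
#' @return invisibly, the path.
#' @export
write_edge_list <- function(graph, path, delimiter = "\t") {
  stopifnot(inherits(graph, "pin_graph"))
  utils::write.table(graph$edges, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Binary adjacency matrix of a PIN
#'
#' Row/column order follows \code{graph$nodes}; entry (i, j) is 1 iff the
#' directed edge i -> j exists, so row i is gene i's downstream interaction
#' pattern and sums to its outdegree.
#'
#' @param graph a non-empty \code{pin_graph}.
#' @return N x N binary matrix with dimnames set to the gene order.
#' @export
to_adjacency <- function(graph) {
  stopifnot(inherits(graph, "pin_graph"))
  n <- length(graph$nodes)
  if (n == 0L) stop("cannot build an adjacency matrix from an empty graph")
  a <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges) > 0L) {
    i <- match(graph$edges$from, graph$nodes)
    j <- match(graph$edges$to, graph$nodes)
    a[cbind(i, j)] <- 1
  }
  a
}

#' Recover a PIN graph from a binary adjacency matrix
#' @param adjacency square binary matrix with gene dimnames.
#' @return a \code{pin_graph} whose edge set is the nonzero entries.
#' @export
from_adjacency <- function(adjacency) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  nodes <- rownames(adjacency)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(adjacency)))
  nz <- which(adjacency != 0, arr.ind = TRUE)
  pin_graph(data.frame(from = nodes[nz[, 1L]], to = nodes[nz[, 2L]],
                       stringsAsFactors = FALSE), nodes = nodes)
}

#' Read a drug -> target table
#'
#' Expects delimited text with header columns \code{drug}, \code{target} and
#' optionally \code{indication}; target genes are aggregated per drug with set
#' semantics.
#'
#' @param path path to the table.
#' @param delimiter field delimiter, default tab.
#' @return a named list of class \code{drug_target_map}: per drug, a character
#'   vector of unique target genes; per-drug indications (if present) are kept
#'   in \code{attr(, "indication")}.
#' @export
read_drug_target_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("drug-target file not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (nrow(df) == 0L) stop("drug-target table has no data rows: ", path)
  if (!all(c("drug", "target") %in% names(df)))
    stop("drug-target table must have 'drug' and 'target' columns")
  if (any(!nzchar(trimws(df$target))))
    stop(sprintf("parse error: row %d is missing a target",
                 which(!nzchar(trimws(df$target)))[1L]))
  drug_target_map(df$drug, df$target,
                  if ("indication" %in% names(df)) df$indication else NULL)
}

#' Build a drug -> target map from vectors
#' @param drug character vector of drug identifiers (one per row).
#' @param target character vector of target genes (parallel to \code{drug}).
#' @param indication optional per-row indication label.
#' @return a \code{drug_target_map}.
#' @export
drug_target_map <- function(drug, target, indication = NULL) {
  stopifnot(length(drug) == length(target))
  m <- lapply(split(as.character(target), as.character(drug)),
              function(x) sort(unique(x)))
  if (any(lengths(m) == 0L)) stop("every drug needs at least one target")
  out <- structure(m, class = "drug_target_map")
  if (!is.null(indication)) {
    ind <- vapply(split(as.character(indication), as.character(drug)),
                  function(x) x[1L], "")
    attr(out, "indication") <- ind[names(m)]
  }
  out
}

#' @export
print.drug_target_map <- function(x, ...) {
  cat(sprintf("drug_target_map: %d drugs, %d distinct target genes\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Write a drug -> target map as TSV
#' @param map a \code{drug_target_map}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_drug_target_table <- function(map, path) {
  stopifnot(inherits(map, "drug_target_map"))
  ind <- attr(map, "indication")
  rows <- do.call(rbind, lapply(names(map), function(d) {
    data.frame(drug = d, target = map[[d]],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(ind)) rows$indication <- ind[rows$drug]
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Intersect a gene set with the PIN's gene universe
#'
#' Exact string matching only; identifier harmonization is the caller's
#' responsibility. Logs counts before/after and warns on an empty result.
#'
#' @param genes character vector of gene identifiers.
#' @param graph a \code{pin_graph}.
#' @return the (sorted, unique) subset of \code{genes} present in the graph.
#' @export
map_genes_to_pin <- function(genes, graph) {
  stopifnot(inherits(graph, "pin_graph"))
  genes <- unique(as.character(genes))
  mapped <- sort(intersect(genes, graph$nodes))
  message(sprintf("map_genes_to_pin: %d of %d genes mapped onto the PIN",
                  length(mapped), length(genes)))
  if (length(genes) > 0L && length(mapped) == 0L)
    warning("none of the supplied genes are present in the PIN")
  mapped
}

#' Read a gene list (one identifier per line)
#' @param path file path.
#' @return character vector of unique gene identifiers (input order).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene-list file not found: ", path)
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !grepl("^#", x)])
}

#' Write a gene list (one identifier per line)
#' @param genes character vector.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

# internal: igraph view of a pin_graph, preserving node order
as_igraph <- function(graph, directed = TRUE) {
  g <- igraph::make_empty_graph(n = length(graph$nodes), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = graph$nodes)
  if (nrow(graph$edges) > 0L) {
    g <- igraph::add_edges(g, as.vector(rbind(
      match(graph$edges$from, graph$nodes),
      match(graph$edges$to, graph$nodes))))
  }
  if (!directed)
    g <- igraph::as_undirected(g, mode = "collapse")
  g
}

# internal: run code with a local, restored RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
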