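#' Read a GMT gene-set collection
#'
#' GMT dialect: \code{name<TAB>description<TAB>gene1<TAB>gene2...} per line.
#' Genes are deduplicated within a set; duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return named list of character vectors of class
#'   \code{gene_set_collection}.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop(sprintf("GMT parse error at line %d: fewer than 3 fields",
                 which(nf < 3L)[1L]))
  nms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene-set name in GMT: ", nms[duplicated(nms)][1L])
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- nms
  structure(sets, class = "gene_set_collection")
}

#' Hypergeometric over-representation test
#'
#' Counts the overlap k between the query and the gene set (both restricted
#' to the universe) and computes the upper-tail hypergeometric probability
#' P(X >= k) with population size N = |universe|, K = |gene set in universe|
#' successes, and n = |query| draws.
#'
#' @param query gene set of interest (must lie within the universe).
#' @param gene_set pathway gene set (intersected with the universe).
#' @param universe background gene universe.
#' @return list with \code{k} (overlap) and \code{p} (upper-tail p-value).
#' @export
ora_test <- function(query, gene_set, universe) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (!all(query %in% universe))
    stop("query genes must be a subset of the universe")
  K <- length(intersect(gene_set, universe))
  n <- length(query)
  k <- length(intersect(query, gene_set))
  p <- stats::phyper(k - 1L, K, length(universe) - K, n, lower.tail = FALSE)
  list(k = k, p = p)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment: sort p ascending, q_i = p_i * m / i, enforce
#' monotonicity from the largest rank downwards, cap at 1, return in the
#' input order.
#'
#' @param pvalues numeric vector of p-values in [0,1].
#' @return numeric vector of FDR values, same order as input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0,1]")
  m <- length(pvalues)
  if (m == 0L) return(numeric())
  ord <- order(pvalues)
  q <- pvalues[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Over-representation analysis of a query against a gene-set collection
#'
#' One hypergeometric upper-tail test per set (see \code{\link{ora_test}})
#' with Benjamini-Hochberg FDR across the collection; all rows are returned,
#' sorted by p ascending, with a significance flag at \code{fdr_threshold}.
#'
#' @param query gene set of interest (within the universe).
#' @param collection a \code{gene_set_collection}.
#' @param universe background universe (defaults in the pipeline to the PIN
#'   gene set).
#' @param fdr_threshold significance cutoff, default 0.05.
#' @return data.frame of class \code{enrichment_table}: \code{gene_set},
#'   \code{set_size}, \code{query_size}, \code{universe_size},
#'   \code{overlap}, \code{p_value}, \code{neg_log10_p}, \code{fdr},
#'   \code{significant}.
#' @export
enrich <- function(query, collection, universe, fdr_threshold = 0.05) {
  if (length(collection) == 0L) stop("empty gene-set collection")
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  res <- lapply(collection, function(gs) ora_test(query, gs, universe))
  tbl <- data.frame(
    gene_set = names(collection),
    set_size = vapply(collection, function(gs)
      length(intersect(gs, universe)), 0L),
    query_size = length(query),
    universe_size = length(universe),
    overlap = vapply(res, function(r) as.integer(r$k), 0L),
    p_value = vapply(res, function(r) r$p, 0),
    stringsAsFactors = FALSE)
  tbl$neg_log10_p <- -log10(tbl$p_value)
  tbl$fdr <- bh_fdr(tbl$p_value)
  tbl$significant <- tbl$fdr < fdr_threshold
  tbl <- tbl[order(tbl$p_value, tbl$gene_set), ]
  rownames(tbl) <- NULL
  class(tbl) <- c("enrichment_table", "data.frame")
  tbl
}

#' Write an enrichment table as TSV
#' @param table an \code{enrichment_table}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_enrichment_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
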