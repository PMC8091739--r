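#' Infer repositionable drug candidates by target overlap
#'
#' A drug is a repositioning candidate when at least one of its known targets
#' lies in the putative-target set; candidates are ranked by the number of
#' overlapping genes (descending), ties broken alphabetically by drug name.
#'
#' @param drug_map a \code{drug_target_map}.
#' @param putative character vector (or \code{putative_target_set}) of
#'   putative target genes.
#' @param exclude_drugs optional drug identifiers to drop (e.g. drugs already
#'   indicated for the query disease); none are dropped by default.
#' @return data.frame of class \code{repositioning_table} with columns
#'   \code{drug}, \code{overlap_genes} (sorted, semicolon-joined),
#'   \code{n_overlap}, \code{rank}; only drugs with \code{n_overlap >= 1}.
#' @export
infer_candidates <- function(drug_map, putative, exclude_drugs = character()) {
  stopifnot(inherits(drug_map, "drug_target_map"))
  if (length(drug_map) == 0L) stop("empty drug-target map")
  putative <- names(putative) %||% as.character(putative)
  drug_map <- drug_map[setdiff(names(drug_map), exclude_drugs)]
  overlaps <- lapply(drug_map, function(tg) sort(intersect(tg, putative)))
  n <- lengths(overlaps)
  keep <- n >= 1L
  if (length(putative) == 0L || !any(keep)) {
    warning("no drug has a target in the putative set")
    tbl <- data.frame(drug = character(), overlap_genes = character(),
                      n_overlap = integer(), rank = integer(),
                      stringsAsFactors = FALSE)
    class(tbl) <- c("repositioning_table", "data.frame")
    return(tbl)
  }
  drugs <- names(drug_map)[keep]
  ord <- order(-n[keep], drugs)
  tbl <- data.frame(
    drug = drugs[ord],
    overlap_genes = vapply(overlaps[keep][ord], paste, "", collapse = "; "),
    n_overlap = as.integer(n[keep][ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE)
  rownames(tbl) <- NULL
  message(sprintf("infer_candidates: %d of %d drugs are repositioning candidates",
                  nrow(tbl), length(drug_map)))
  class(tbl) <- c("repositioning_table", "data.frame")
  tbl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a repositioning table as TSV
#' @param table a non-empty \code{repositioning_table}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_repositioning_report <- function(table, path) {
  stopifnot(inherits(table, "repositioning_table"))
  if (nrow(table) == 0L) stop("refusing to write an empty repositioning table")
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a repositioning table written by \code{write_repositioning_report}
#' @param path TSV path.
#' @return a \code{repositioning_table}.
#' @export
read_repositioning_report <- function(path) {
  tbl <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  tbl$n_overlap <- as.integer(tbl$n_overlap)
  tbl$rank <- as.integer(tbl$rank)
  class(tbl) <- c("repositioning_table", "data.frame")
  tbl
}
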