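#' Read a GMT gene-set file
#'
#' One set per line: set name, description, then tab-separated gene
#' symbols. Genes duplicated within a line are collapsed to a single
#' membership with a warning; a line with fewer than three fields is a
#' parse error reporting the line number.
#'
#' @param path GMT file path.
#' @return A list `sets` (named list of gene vectors), `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descriptions <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) in set ", fields[1], " deduplicated")
      genes <- unique(genes)
    }
    sets[[fields[1]]] <- genes
    descriptions[fields[1]] <- fields[2]
  }
  list(sets = sets, descriptions = descriptions)
}

#' Write gene sets in GMT format
#'
#' @param sets named list of gene-symbol vectors.
#' @param path output path.
#' @param descriptions optional named character descriptions (default
#'   `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for the overlap of a size-`n` query with a size-`M` set in a
#' universe of `N` genes:
#' `1 - sum_{j < k} C(M, j) C(N - M, n - j) / C(N, n)`, evaluated as the
#' complementary (upper) sum with log-space binomial coefficients so small
#' tail probabilities keep full relative precision.
#'
#' @param k observed overlap.
#' @param M set size.
#' @param n query size.
#' @param N universe size.
#' @return The upper-tail p-value.
#' @export
hypergeom_upper_tail <- function(k, M, n, N) {
  if (k < 0 || M < 0 || n < 0 || N < 1 || M > N || n > N ||
      k > min(M, n))
    stop("inconsistent hypergeometric counts")
  if (k == 0) return(1)
  j <- k:min(M, n)
  upper <- sum(exp(lchoose(M, j) + lchoose(N - M, n - j) - lchoose(N, n)))
  min(max(upper, 0), 1)
}

#' Map shortest-path CpG nodes to a unique gene list
#'
#' Takes the union of the genes annotated to every CpG on every path;
#' unannotated CpGs are dropped with a warning.
#'
#' @param paths a path list from [graph_shortest_paths()].
#' @param annotation data.frame `cpg_id`, `gene`.
#' @return A sorted unique character vector of gene symbols.
#' @export
map_paths_to_genes <- function(paths, annotation) {
  cpgs <- unique(unlist(paths))
  hit <- cpgs %in% annotation$cpg_id
  if (any(!hit))
    warning(sum(!hit), " path CpG(s) missing from the annotation dropped")
  sort(unique(annotation$gene[annotation$cpg_id %in% cpgs[hit]]))
}

#' Hypergeometric gene-set enrichment with BH control
#'
#' Each set is tested for over-representation of the query genes by the
#' hypergeometric upper tail; p-values are BH-adjusted across all tested
#' sets and results sorted by p. Query genes outside the universe are
#' dropped with a message.
#'
#' @param query_genes character query gene symbols.
#' @param genesets named list of gene-symbol vectors.
#' @param universe background gene symbols (N).
#' @param fdr_threshold significance gate on q (default 0.05).
#' @return A data.frame `set`, `k`, `M`, `n`, `N`, `p`, `q`,
#'   `significant`, `overlap_genes` (`;`-separated), sorted by p.
#' @export
enrich <- function(query_genes, genesets, universe, fdr_threshold = 0.05) {
  if (length(genesets) == 0) stop("empty gene-set collection")
  query_genes <- unique(query_genes)
  outside <- setdiff(query_genes, universe)
  if (length(outside) > 0)
    message(length(outside), " query gene(s) outside the universe dropped")
  query <- intersect(query_genes, universe)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(genesets), function(nm) {
    set <- intersect(unique(genesets[[nm]]), universe)
    overlap <- intersect(query, set)
    data.frame(set = nm, k = length(overlap), M = length(set), n = n,
               N = N,
               p = hypergeom_upper_tail(length(overlap), length(set), n, N),
               overlap_genes = paste(sort(overlap), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < fdr_threshold
  out <- out[order(out$p, out$set),
             c("set", "k", "M", "n", "N", "p", "q", "significant",
               "overlap_genes")]
  rownames(out) <- NULL
  out
}
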