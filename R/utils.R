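#' @useDynLib epiaccel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor ecdf lm coef predict p.adjust pt rnorm runif sd var
#'   quantile dnorm fisher.test kruskal.test ks.test median plogis rbinom
#'   dist setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DISEASE_GROUPS <- c("AD", "PD", "PSP", "FTD")

#' Derive a named sub-seed from a master seed
#'
#' Each stage of the pipeline draws its randomness from an independent named
#' stream so stages can be re-run in isolation with identical results.
#'
#' @param master integer master seed.
#' @param stream character stream name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}

#' Construct a methylation dataset
#'
#' A light container pairing a samples-by-sites value matrix with per-sample
#' metadata (age, group label, train/test split).
#'
#' @param values numeric matrix, samples in rows, CpG sites in columns;
#'   dimnames must carry sample and site identifiers.
#' @param meta data.frame with columns `sample_id`, `age`, `group`, `split`.
#' @return An object of class `methyl_dataset`.
#' @export
methyl_dataset <- function(values, meta) {
  stopifnot(is.matrix(values), nrow(values) == nrow(meta))
  if (is.null(rownames(values))) rownames(values) <- meta$sample_id
  stopifnot(
    !anyDuplicated(colnames(values)), !anyDuplicated(rownames(values)),
    identical(rownames(values), as.character(meta$sample_id)),
    all(c("sample_id", "age", "group", "split") %in% names(meta))
  )
  structure(list(values = values, meta = meta), class = "methyl_dataset")
}

#' @export
print.methyl_dataset <- function(x, ...) {
  cat(sprintf(
    "<methyl_dataset> %d samples x %d CpG sites; groups: %s; %.1f%% missing\n",
    nrow(x$values), ncol(x$values),
    paste(sprintf("%s=%d", names(table(x$meta$group)), table(x$meta$group)),
          collapse = ", "),
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' Subset a methylation dataset by samples and/or sites
#'
#' @param data a `methyl_dataset`.
#' @param samples logical/integer/character index over samples (optional).
#' @param sites index over site columns (optional).
#' @return A `methyl_dataset`.
#' @export
subset_dataset <- function(data, samples = NULL, sites = NULL) {
  v <- data$values
  m <- data$meta
  if (!is.null(samples)) {
    v <- v[samples, , drop = FALSE]
    m <- m[samples, , drop = FALSE]
  }
  if (!is.null(sites)) v <- v[, sites, drop = FALSE]
  rownames(m) <- NULL
  methyl_dataset(v, m)
}
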