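#' OTU count tables
#'
#' A `count_table` holds non-negative integer counts of OTUs per sample,
#' with samples as rows and OTUs as columns (the vegan orientation, and
#' the orientation of mothur `.shared` files).  Per-sample totals are
#' always recomputed from the counts, never cached.
#'
#' @param counts integer matrix, samples x OTUs, with unique rownames
#'   (sample ids) and colnames (OTU ids).
#' @return an object of class `count_table`.
#' @export
count_table <- function(counts) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("count_table needs sample ids as rownames and OTU ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "double" # large totals overflow 32-bit integers
  structure(list(counts = counts), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d OTUs, %s reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
otu_ids <- function(x) colnames(x$counts)

#' @rdname count_table
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname count_table
#' @export
sample_totals <- function(x) rowSums(x$counts)

#' Subset a count table
#'
#' @param x a `count_table`.
#' @param samples,otus character or logical selectors; `NULL` keeps all.
#' @return a `count_table`.
#' @export
subset_counts <- function(x, samples = NULL, otus = NULL) {
  m <- x$counts
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  if (!is.null(otus)) m <- m[, otus, drop = FALSE]
  count_table(m)
}

stopifnot_count_table <- function(x) {
  if (!inherits(x, "count_table")) stop("expected a count_table")
  invisible(x)
}
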