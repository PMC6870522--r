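#' Construct a sample-by-OTU count table
#'
#' The central container of the package: a non-negative integer matrix with
#' samples as rows and OTUs as columns, both carrying unique identifiers.
#' Library sizes (per-sample read totals) are derivable via
#' [library_sizes()]. All joins downstream are by identifier, never by
#' position; row and column order is preserved as given.
#'
#' @param counts numeric matrix of non-negative integers, samples x OTUs.
#'   Dimnames are required unless `sample_ids`/`otu_ids` are supplied.
#' @param sample_ids,otu_ids optional character vectors overriding dimnames.
#' @return an object of class `count_table`.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("otuA", "otuB", "otuC")))
#' ct <- count_table(m)
#' library_sizes(ct)
#' @export
count_table <- function(counts, sample_ids = NULL, otu_ids = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (!is.null(otu_ids)) colnames(counts) <- otu_ids
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count_table requires sample and OTU identifiers (dimnames)")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("count_table requires at least one sample and one OTU")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(!is.finite(counts)))
    stop("non-numeric or missing count values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1L, ]
    stop(sprintf("fractional count at sample '%s', OTU '%s': counts must be integers",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  storage.mode(counts) <- "double"  # doubles hold counts > .Machine$integer.max
  counts <- round(counts)
  structure(list(counts = counts), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d OTUs, %s reads\n",
              n_samples(x), n_otus(x),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Accessors for count_table objects
#'
#' @param x a [count_table].
#' @return `sample_ids`/`otu_ids`: character vectors; `counts`: the numeric
#'   samples x OTUs matrix; `library_sizes`: named per-sample read totals;
#'   `n_samples`/`n_otus`: integers.
#' @name count_table-accessors
NULL

#' @rdname count_table-accessors
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname count_table-accessors
#' @export
otu_ids <- function(x) colnames(x$counts)

#' @rdname count_table-accessors
#' @export
counts <- function(x) x$counts

#' @rdname count_table-accessors
#' @export
library_sizes <- function(x) rowSums(x$counts)

#' @rdname count_table-accessors
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname count_table-accessors
#' @export
n_otus <- function(x) ncol(x$counts)

#' Subset a count table by identifier or index
#'
#' @param x a [count_table].
#' @param samples,otus identifiers (character) or indices to keep; `NULL`
#'   keeps everything.
#' @return a [count_table].
#' @export
subset_table <- function(x, samples = NULL, otus = NULL) {
  m <- x$counts
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  if (!is.null(otus)) m <- m[, otus, drop = FALSE]
  count_table(m)
}
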