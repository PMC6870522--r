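#' Relative abundance of OTUs
#'
#' @param table a [count_table].
#' @param scope `"per_sample"`: each row divided by its library size (rows
#'   sum to 1); `"global"`: one proportion per OTU, total OTU reads over the
#'   grand total (sums to 1).
#' @return a samples x OTUs matrix (`per_sample`) or named vector (`global`).
#' @export
relative_abundance <- function(table, scope = c("per_sample", "global")) {
  scope <- match.arg(scope)
  m <- counts(table)
  if (scope == "global") {
    gt <- sum(m)
    if (gt <= 0) stop("grand total is zero")
    return(colSums(m) / gt)
  }
  ls <- rowSums(m)
  if (any(ls == 0))
    stop("zero-total sample(s) under per-sample scope: ",
         paste(rownames(m)[ls == 0], collapse = ", "))
  sweep(m, 1L, ls, "/")
}

filter_report <- function(name, before_ids, after_ids, threshold) {
  removed <- setdiff(before_ids, after_ids)
  structure(list(filter = name,
                 otus_before = length(before_ids),
                 otus_after = length(after_ids),
                 removed = removed,
                 threshold = threshold),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("%s filter (threshold %s): %d -> %d OTUs (%d removed)\n",
              x$filter, format(x$threshold), x$otus_before, x$otus_after,
              length(x$removed)))
  invisible(x)
}

apply_otu_filter <- function(table, keep, name, threshold) {
  if (!any(keep)) stop(name, " filter removed every OTU")
  out <- subset_table(table, otus = otu_ids(table)[keep])
  list(table = out,
       report = filter_report(name, otu_ids(table), otu_ids(out), threshold))
}

#' OTU retention filters
#'
#' The three standard abundance-based retention filters applied to amplicon
#' OTU tables before analysis, each returning the filtered table plus a
#' report of what was removed. Relative abundances must be recomputed after
#' filtering (see [relative_abundance()]); retained counts are unchanged.
#'
#' * `filter_pruned()` — the "pruned community": keep OTUs whose *global*
#'   relative abundance (reads across the whole dataset over the grand
#'   total) is at least `threshold` (default 0.005%), screening out
#'   sequencing-error OTUs.
#' * `filter_dominant()` — the "dominant community": keep OTUs reaching at
#'   least `threshold` (default 5%) relative abundance in at least one
#'   sample.
#' * `filter_min_reads()` — the "minimally pruned community": keep OTUs with
#'   at least `min_reads` (default 20) reads in at least one sample. With
#'   `zero_cells = TRUE` the alternative cell-level reading is used: cells
#'   below `min_reads` are zeroed and OTUs left with no reads are dropped.
#'
#' All thresholds are inclusive (`>=`). Each filter is idempotent.
#'
#' @param table a [count_table].
#' @param threshold retention fraction in (0, 1).
#' @param mean_proportion for `filter_pruned()`: compute global abundance as
#'   the mean of per-sample proportions instead of pooled reads (default
#'   pooled reads).
#' @param min_reads integer minimum read count (>= 1).
#' @param zero_cells see above.
#' @return list with elements `table` ([count_table]) and `report`.
#' @name otu-filters
NULL

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single value in (0, 1)")
}

#' @rdname otu-filters
#' @export
filter_pruned <- function(table, threshold = 0.00005, mean_proportion = FALSE) {
  check_threshold(threshold)
  if (sum(counts(table)) <= 0) stop("grand total is zero")
  p <- if (mean_proportion)
    colMeans(relative_abundance(table, "per_sample"))
  else relative_abundance(table, "global")
  apply_otu_filter(table, p >= threshold, "pruned", threshold)
}

#' @rdname otu-filters
#' @export
filter_dominant <- function(table, threshold = 0.05) {
  check_threshold(threshold)
  ls <- library_sizes(table)
  if (any(ls == 0)) {
    warning("excluding zero-total sample(s) from the dominance criterion: ",
            paste(sample_ids(table)[ls == 0], collapse = ", "))
    rel <- relative_abundance(
      subset_table(table, samples = sample_ids(table)[ls > 0]), "per_sample")
  } else rel <- relative_abundance(table, "per_sample")
  keep <- apply(rel, 2L, max) >= threshold
  apply_otu_filter(table, keep, "dominant", threshold)
}

#' @rdname otu-filters
#' @export
filter_min_reads <- function(table, min_reads = 20, zero_cells = FALSE) {
  if (!is.numeric(min_reads) || length(min_reads) != 1L || min_reads < 1 ||
      min_reads != round(min_reads))
    stop("min_reads must be a single integer >= 1")
  if (zero_cells) {
    m <- counts(table)
    m[m < min_reads] <- 0
    keep <- colSums(m) > 0
    if (!any(keep)) stop("minreads filter removed every OTU")
    out <- count_table(m[, keep, drop = FALSE])
    return(list(table = out,
                report = filter_report("minreads", otu_ids(table),
                                       otu_ids(out), min_reads)))
  }
  keep <- apply(counts(table), 2L, max) >= min_reads
  apply_otu_filter(table, keep, "minreads", min_reads)
}

#' Remove the host OTU from a diet metabarcoding table
#'
#' Diet tables amplified from predator gut contents are dominated by host
#' reads. This removes the single OTU assigned to the host taxon with the
#' greatest total read count across the table (one OTU table-wide, since OTU
#' identity is table-wide). Remaining reads represent prey.
#'
#' @param table a [count_table].
#' @param taxonomy taxonomy data frame from [taxonomy_map()].
#' @param host_rank,host_name the rank (one of kingdom...species) and taxon
#'   name identifying the host, e.g. `"order"`, `"Odonata"`.
#' @return list with `table` and `report`; the report's `removed` holds the
#'   host OTU id and its `host_counts` the per-sample reads removed. If no
#'   OTU matches, the table is returned unchanged with a warning.
#' @export
remove_host_otu <- function(table, taxonomy, host_rank = "order",
                            host_name = "Odonata") {
  host_rank <- match.arg(host_rank, CANONICAL_RANKS)
  cand <- taxonomy$otu_id[taxonomy[[host_rank]] == host_name]
  cand <- intersect(cand, otu_ids(table))
  if (length(cand) == 0L) {
    warning("no OTU assigned to ", host_rank, " ", host_name, "; nothing removed")
    return(list(table = table,
                report = filter_report("host_otu", otu_ids(table),
                                       otu_ids(table), host_name)))
  }
  totals <- colSums(counts(table)[, cand, drop = FALSE])
  host_otu <- cand[which.max(totals)]
  out <- subset_table(table, otus = setdiff(otu_ids(table), host_otu))
  rep <- filter_report("host_otu", otu_ids(table), otu_ids(out), host_name)
  rep$host_counts <- counts(table)[, host_otu]
  list(table = out, report = rep)
}

#' Remove near-zero-variance columns
#'
#' Screens out abundance columns that carry (almost) no information before
#' discriminant analysis. A column is removed when it is constant, or when
#' the frequency ratio of its most common to second most common value
#' exceeds `freq_cut` *and* the fraction of distinct values is below
#' `unique_cut`. The default cutoffs (95/5 = 19 and 10%) follow the common
#' feature-screening convention.
#'
#' @param m numeric samples x features matrix (>= 2 rows).
#' @param freq_cut frequency-ratio cutoff (strictly greater than removes).
#' @param unique_cut distinct-value percentage cutoff (strictly less than
#'   removes).
#' @return list with `matrix` (columns kept) and `removed` (column names).
#' @export
near_zero_variance_filter <- function(m, freq_cut = 95 / 5, unique_cut = 10) {
  if (nrow(m) < 2L) stop("need at least 2 samples")
  nzv <- apply(m, 2L, function(x) {
    tab <- sort(table(x), decreasing = TRUE)
    if (length(tab) == 1L) return(TRUE)          # constant column
    ratio <- tab[1L] / tab[2L]
    pct_unique <- 100 * length(tab) / length(x)
    ratio > freq_cut && pct_unique < unique_cut
  })
  list(matrix = m[, !nzv, drop = FALSE], removed = colnames(m)[nzv])
}
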