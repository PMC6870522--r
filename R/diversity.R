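#' Alpha diversity of a single sample
#'
#' `shannon()` computes Shannon's index H = -sum p_i log p_i over nonzero
#' proportions (natural log by default, the convention of most community
#' ecology software); `richness()` counts OTUs with at least one read.
#'
#' @param x numeric vector of OTU counts for one sample.
#' @param base logarithm base for `shannon()`.
#' @return a scalar; 0 <= H <= log(richness).
#' @examples
#' shannon(c(1, 2, 3))
#' richness(c(0, 5, 0, 1))
#' @export
shannon <- function(x, base = exp(1)) {
  if (sum(x) <= 0) stop("zero-total sample")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p, base = base))
}

#' @rdname shannon
#' @export
richness <- function(x) sum(x > 0)

#' Pairwise beta diversity measures
#'
#' * `whittaker_beta()` — incidence-based turnover between two samples
#'   (Koleff pairwise form): with `a` shared OTUs and `b`, `c` unique to
#'   each sample, beta_w = (b + c) / (2a + b + c), in `[0, 1]`.
#' * `bray_curtis()` — abundance-based: sum |a_i - b_i| / sum (a_i + b_i).
#' * `aitchison_distance()` — Euclidean distance between centered-log-ratio
#'   transforms of the two compositions; the compositional beta-diversity
#'   measure. Zero counts are replaced additively by `zero_replacement`
#'   before closure (the strategy used when none is stated). The distance is
#'   invariant to the total count scale of each sample.
#'
#' @param x,y non-negative count vectors over the same OTUs.
#' @param zero_replacement pseudo-count substituted for zeros.
#' @return a scalar dissimilarity.
#' @examples
#' whittaker_beta(c(1, 1, 0), c(0, 1, 1))
#' bray_curtis(c(6, 2), c(2, 2))
#' @export
whittaker_beta <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (sum(x) == 0 && sum(y) == 0) stop("both samples are empty")
  a <- sum(x > 0 & y > 0)
  b <- sum(x > 0 & y == 0)
  c <- sum(x == 0 & y > 0)
  if (2 * a + b + c == 0) stop("both samples are empty")
  (b + c) / (2 * a + b + c)
}

#' @rdname whittaker_beta
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both samples are empty")
  sum(abs(x - y)) / tot
}

#' @rdname whittaker_beta
#' @export
aitchison_distance <- function(x, y, zero_replacement = 0.5) {
  stopifnot(length(x) == length(y))
  if (sum(x) <= 0 || sum(y) <= 0) stop("zero-total sample")
  clr <- function(v) {
    v[v == 0] <- zero_replacement
    v <- v / sum(v)
    log(v) - mean(log(v))
  }
  sqrt(sum((clr(x) - clr(y))^2))
}

#' Pairwise distance matrix over the samples of a count table
#'
#' @param table a [count_table].
#' @param metric `"bray_curtis"`, `"whittaker"` or `"aitchison"`.
#' @param ... passed to the pairwise metric.
#' @return a symmetric samples x samples matrix with zero diagonal.
#' @export
distance_matrix <- function(table,
                            metric = c("bray_curtis", "whittaker", "aitchison"),
                            ...) {
  metric <- match.arg(metric)
  f <- switch(metric, bray_curtis = bray_curtis,
              whittaker = whittaker_beta, aitchison = aitchison_distance)
  m <- counts(table)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <- f(m[i, ], m[j, ], ...)
  }
  d
}

#' Exact rarefaction (subsampling without replacement)
#'
#' Draws `depth` reads from a sample without replacement — a multivariate
#' hypergeometric draw, never the with-replacement approximation — via
#' sequential conditional hypergeometric sampling.
#'
#' @param x non-negative integer count vector.
#' @param depth target total (<= `sum(x)`).
#' @return integer vector of the same length summing to `depth`.
#' @export
rarefy_counts <- function(x, depth) {
  total <- sum(x)
  if (depth > total)
    stop(sprintf("depth %d exceeds sample total %d; exclude the sample upstream",
                 depth, total))
  out <- numeric(length(x))
  remaining_pool <- total
  remaining_draw <- depth
  for (i in seq_along(x)) {
    if (remaining_draw == 0L) break
    k <- stats::rhyper(1L, x[i], remaining_pool - x[i], remaining_draw)
    out[i] <- k
    remaining_pool <- remaining_pool - x[i]
    remaining_draw <- remaining_draw - k
  }
  names(out) <- names(x)
  out
}

#' Rarefaction curves for a count table
#'
#' Repeatedly subsamples every sample to each depth and summarises a
#' diversity metric as mean and standard deviation over iterations. Samples
#' shallower than a depth are flagged (`NA` with a record in
#' `$too_shallow`), not silently dropped.
#'
#' @param table a [count_table].
#' @param depths ascending integer depths.
#' @param metric `"richness"` or `"faith_pd"` (requires `tree`).
#' @param iterations subsample draws per depth (default 100).
#' @param tree `ape::phylo`, needed for `"faith_pd"`.
#' @param seed integer RNG seed.
#' @return data frame with columns depth, sample_id, mean, sd, iterations;
#'   attribute `too_shallow` lists flagged (depth, sample) pairs.
#' @export
rarefaction_curve <- function(table, depths, metric = c("richness", "faith_pd"),
                              iterations = 100, tree = NULL, seed = 1) {
  metric <- match.arg(metric)
  if (length(depths) == 0L) stop("empty depth list")
  if (is.unsorted(depths)) stop("depths must be sorted ascending")
  if (metric == "faith_pd" && is.null(tree)) stop("faith_pd requires a tree")
  local_seed(seed)
  m <- counts(table)
  value_of <- function(cnt) {
    if (metric == "richness") richness(cnt)
    else faith_pd(names(cnt)[cnt > 0], tree)
  }
  res <- list(); flagged <- list()
  for (d in depths) for (s in rownames(m)) {
    if (sum(m[s, ]) < d) {
      flagged[[length(flagged) + 1L]] <- data.frame(depth = d, sample_id = s)
      res[[length(res) + 1L]] <- data.frame(depth = d, sample_id = s,
                                            mean = NA_real_, sd = NA_real_,
                                            iterations = iterations)
      next
    }
    vals <- replicate(iterations, value_of(rarefy_counts(m[s, ], d)))
    res[[length(res) + 1L]] <- data.frame(depth = d, sample_id = s,
                                          mean = mean(vals),
                                          sd = stats::sd(vals),
                                          iterations = iterations)
  }
  out <- do.call(rbind, res)
  attr(out, "too_shallow") <- if (length(flagged)) do.call(rbind, flagged)
  else NULL
  out
}

#' Mean rarefied community
#'
#' Rarefies every sample to a common depth `iterations` times and returns
#' the mean table plus the per-cell standard deviation; the +1SD / -1SD
#' tables are floored at 0.
#'
#' @param table a [count_table]; samples shallower than `depth` error.
#' @param depth target depth; default the smallest library size.
#' @param iterations number of subsample draws.
#' @param seed integer RNG seed.
#' @return list of matrices `mean`, `sd`, `plus_sd`, `minus_sd`.
#' @export
mean_rarefied_table <- function(table, depth = min(library_sizes(table)),
                                iterations = 100, seed = 1) {
  local_seed(seed)
  m <- counts(table)
  acc <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  acc2 <- acc
  for (it in seq_len(iterations)) {
    draw <- t(apply(m, 1L, rarefy_counts, depth = depth))
    acc <- acc + draw
    acc2 <- acc2 + draw^2
  }
  mu <- acc / iterations
  sdm <- sqrt(pmax(acc2 / iterations - mu^2, 0) * iterations / max(iterations - 1, 1))
  list(mean = mu, sd = sdm, plus_sd = mu + sdm, minus_sd = pmax(mu - sdm, 0))
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal subtree connecting the present
#' leaves to the root (the root path is counted, the common convention;
#' set `include_root = FALSE` to span only the leaves' most recent common
#' ancestor).
#'
#' @param present character vector of leaf names present in the sample.
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param include_root count branches from the spanning subtree up to the
#'   root (default TRUE).
#' @return scalar PD >= 0; an empty set returns 0 with a warning.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' faith_pd(c("A", "B"), tr)   # 3
#' @export
faith_pd <- function(present, tree, include_root = TRUE) {
  if (length(present) == 0L) {
    warning("empty OTU set; PD = 0")
    return(0)
  }
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("OTUs not in tree: ", paste(missing, collapse = ", "))
  tips <- match(present, tree$tip.label)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  marked <- logical(ntip + tree$Nnode)
  for (t in tips) {
    node <- t
    while (node != root && !marked[node]) {
      marked[node] <- TRUE
      node <- parent[node]
    }
  }
  keep <- marked[tree$edge[, 2L]]
  pd <- sum(tree$edge.length[keep])
  if (!include_root && length(present) >= 1L) {
    # subtract the chain from the root down to the MRCA of the present set
    mrca_node <- if (length(tips) == 1L) tips else {
      anc <- function(t) { p <- t; path <- t
        while (p != root) { p <- parent[p]; path <- c(path, p) }; path }
      paths <- lapply(tips, anc)
      common <- Reduce(intersect, paths)
      common[1L]
    }
    node <- mrca_node
    while (node != root) {
      e <- which(tree$edge[, 2L] == node)
      pd <- pd - tree$edge.length[e]
      node <- parent[node]
    }
  }
  pd
}
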