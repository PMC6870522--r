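gower_center <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  rm_ <- rowMeans(a); gm <- mean(a)
  sweep(sweep(a, 1L, rm_), 2L, rm_) + gm
}

hat_matrix <- function(x) {
  q <- qr(x)
  qq <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(qq)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the variation of a distance matrix among the terms of a
#' factorial design using sequential (Type-I) sums of squares on the
#' Gower-centered inner-product matrix (McArdle & Anderson decomposition),
#' with significance by free permutation of sample labels. Term order
#' follows the design formula as written.
#'
#' @param d symmetric distance matrix (or `dist`) with sample ids.
#' @param data data frame of factors, rows aligned with `d`.
#' @param formula right-hand-side formula or character, e.g.
#'   `~ Species + Location + Species:Location`.
#' @param nperm number of label permutations (default 10000).
#' @param seed integer RNG seed.
#' @param permutations optional integer matrix of explicit permutations
#'   (rows = permuted index vectors), e.g. an exhaustive enumeration;
#'   overrides `nperm`/`seed`.
#' @return data frame of class `permanova_table` with one row per term plus
#'   Residuals and Total: Df, SumOfSqs, MeanSqs, F, R2, p. p-values are
#'   `(#(F* >= F) + 1) / (nperm + 1)`.
#' @export
permanova <- function(d, data, formula, nperm = 10000, seed = 1,
                      permutations = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(nrow(data) == n)
  if (is.character(formula)) formula <- stats::as.formula(paste("~", formula))
  trm <- stats::terms(formula)
  labels <- attr(trm, "term.labels")
  if (length(labels) == 0L) stop("design has no terms")
  for (v in all.vars(formula)) {
    if (!v %in% names(data)) stop("factor '", v, "' not in data")
    data[[v]] <- factor(data[[v]])
    if (nlevels(data[[v]]) < 2L) stop("factor '", v, "' has a single level")
  }
  G <- gower_center(d)
  ss_total <- sum(diag(G))
  # cumulative hat matrices, one per sequential model
  hats <- vector("list", length(labels))
  dfs <- integer(length(labels))
  prev_rank <- 1L  # intercept
  for (k in seq_along(labels)) {
    f_k <- stats::as.formula(paste("~", paste(labels[seq_len(k)], collapse = "+")))
    x <- stats::model.matrix(f_k, data)
    rk <- qr(x)$rank
    hats[[k]] <- hat_matrix(x)
    dfs[k] <- rk - prev_rank
    prev_rank <- rk
  }
  if (any(dfs == 0L)) stop("singular design: term(s) with zero df: ",
                           paste(labels[dfs == 0L], collapse = ", "))
  df_res <- n - prev_rank
  if (df_res <= 0L) stop("no residual degrees of freedom")
  j <- matrix(1 / n, n, n)
  stat_terms <- function(gmat) {
    cum <- vapply(hats, function(h) sum(h * gmat), 0) - sum(j * gmat)
    ss <- diff(c(0, cum))
    ss_res <- sum(diag(gmat)) - cum[length(cum)]
    f <- (ss / dfs) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- stat_terms(G)
  if (is.null(permutations)) {
    local_seed(seed)
    permutations <- t(replicate(nperm, sample.int(n)))
  }
  nperm_eff <- nrow(permutations)
  exceed <- numeric(length(labels))
  for (r in seq_len(nperm_eff)) {
    p_ <- permutations[r, ]
    fp <- stat_terms(G[p_, p_])$f
    exceed <- exceed + (fp >= obs$f - 1e-12)
  }
  pvals <- (exceed + 1) / (nperm_eff + 1)
  out <- data.frame(
    term = c(labels, "Residuals", "Total"),
    Df = c(dfs, df_res, n - 1L),
    SumOfSqs = c(obs$ss, obs$ss_res, ss_total),
    MeanSqs = c(obs$ss / dfs, obs$ss_res / df_res, NA),
    F = c(obs$f, NA, NA),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE)
  class(out) <- c("permanova_table", "data.frame")
  attr(out, "nperm") <- nperm_eff
  out
}

#' Principal coordinates analysis (classical MDS)
#'
#' Eigendecomposition of the Gower-centered distance matrix. Axes are
#' ordered by eigenvalue; axes with negative eigenvalues are reported but
#' excluded from the returned coordinates by default.
#'
#' @param d symmetric distance matrix or `dist`.
#' @param eps eigenvalues within `eps * max(|eigenvalue|)` of zero are
#'   treated as null.
#' @return list: `points` (samples x positive axes, scaled by sqrt of
#'   eigenvalue), `eigenvalues` (all, descending), `negative` (indices of
#'   negative eigenvalues).
#' @export
pcoa <- function(d, eps = 1e-9) {
  G <- gower_center(d)
  e <- eigen(G, symmetric = TRUE)
  lambda <- e$values
  tol <- eps * max(abs(lambda), 1)
  pos <- which(lambda > tol)
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda[pos]), length(pos))
  rownames(pts) <- rownames(as.matrix(d))
  colnames(pts) <- paste0("Axis", seq_along(pos))
  list(points = pts, eigenvalues = lambda, negative = which(lambda < -tol))
}

loo_lda_success <- function(scores, groups) {
  n <- nrow(scores)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(
      MASS::lda(scores[-i, , drop = FALSE], grouping = groups[-i]))
    pred[i] <- as.character(stats::predict(fit, scores[i, , drop = FALSE])$class)
  }
  pred
}

#' Canonical analysis of principal coordinates (CAP) discriminant analysis
#'
#' PCoA axes of the distance matrix are fed into linear discriminant
#' analysis. The number of axes is chosen (unless fixed) to maximize
#' leave-one-out classification success over 2..(n - groups - 1), and group
#' separation is tested by permuting group labels and recomputing the
#' leave-one-out success at the chosen axis count.
#'
#' @param d distance matrix or `dist`.
#' @param groups factor of group labels (>= 2 groups, each >= 2 samples).
#' @param max_axes `"auto"` or a fixed integer axis count.
#' @param nperm label permutations for the significance test (default 1000).
#' @param seed integer RNG seed.
#' @return list of class `cap_result`: `n_axes`, `ld_scores` (samples x
#'   discriminants), `classification` (per-sample LOO prediction),
#'   `group_success` (per-group fraction correct), `success` (overall),
#'   `p_value`, `proportion_of_trace`.
#' @export
cap_discrim <- function(d, groups, max_axes = "auto", nperm = 1000, seed = 1) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L))
    stop("every group needs >= 2 samples; offending: ",
         paste(names(which(table(groups) < 2L)), collapse = ", "))
  ord <- pcoa(d)
  n <- nrow(ord$points)
  g <- nlevels(groups)
  hi <- min(n - g - 1L, ncol(ord$points))
  if (hi < 2L) stop("too few samples/axes for discriminant analysis")
  if (identical(max_axes, "auto")) {
    cand <- 2L:hi
    succ <- vapply(cand, function(m) {
      mean(loo_lda_success(ord$points[, seq_len(m), drop = FALSE], groups) ==
             as.character(groups))
    }, 0)
    n_axes <- cand[which.max(succ)]
  } else {
    n_axes <- as.integer(max_axes)
    if (n_axes < 1L || n_axes > ncol(ord$points)) stop("invalid axis count")
  }
  scores <- ord$points[, seq_len(n_axes), drop = FALSE]
  pred <- loo_lda_success(scores, groups)
  correct <- pred == as.character(groups)
  success <- mean(correct)
  group_success <- c(tapply(correct, groups, mean))
  fit <- suppressWarnings(MASS::lda(scores, grouping = groups))
  ld <- stats::predict(fit, scores)$x
  trace_prop <- fit$svd^2 / sum(fit$svd^2)
  names(trace_prop) <- paste0("LD", seq_along(trace_prop))
  local_seed(seed)
  exceed <- 0L
  for (r in seq_len(nperm)) {
    gp <- sample(groups)
    sp <- mean(loo_lda_success(scores, gp) == as.character(gp))
    if (sp >= success - 1e-12) exceed <- exceed + 1L
  }
  structure(list(n_axes = n_axes, ld_scores = ld, classification = pred,
                 group_success = group_success, success = success,
                 p_value = (exceed + 1) / (nperm + 1),
                 proportion_of_trace = trace_prop),
            class = "cap_result")
}

#' @export
print.cap_result <- function(x, ...) {
  cat(sprintf("CAP: %d PCoA axes, classification success %.1f%% (p = %.4g)\n",
              x$n_axes, 100 * x$success, x$p_value))
  invisible(x)
}

#' Kruskal-Wallis rank sum test (tie-corrected)
#'
#' @param values numeric vector.
#' @param groups factor of the same length (>= 2 groups).
#' @return list: `statistic` (H, tie-corrected), `df`, `p.value` (chi-square
#'   approximation).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  n <- length(values)
  r <- rank(values)
  rs <- tapply(r, groups, sum)
  ns <- tabulate(groups)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- if (correction > 0) h / correction else 0
  df <- nlevels(groups) - 1L
  list(statistic = h, df = df,
       p.value = stats::pchisq(h, df, lower.tail = FALSE))
}

#' Conover-Iman post-hoc test after Kruskal-Wallis
#'
#' Pairwise t statistics from rank sums with the pooled tie-corrected rank
#' variance: t = (Rbar_i - Rbar_j) / sqrt(S2 * (n-1-H)/(n-k) * (1/n_i + 1/n_j)),
#' df = n - k, with S2 the variance of all ranks.
#'
#' @param values numeric vector.
#' @param groups factor (>= 2 groups, each non-empty).
#' @param p_adjust p adjustment method (see [stats::p.adjust]); default
#'   `"none"`.
#' @return data frame: group1, group2, statistic, p.value (two-sided,
#'   adjusted).
#' @export
conover_posthoc <- function(values, groups, p_adjust = "none") {
  groups <- factor(groups)
  if (any(tabulate(groups) == 0L)) stop("empty group")
  n <- length(values)
  k <- nlevels(groups)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ns <- tabulate(groups)
  h <- kruskal_wallis(values, groups)$statistic
  s2 <- (sum(r^2) - n * (n + 1)^2 / 4) / (n - 1)
  df <- n - k
  pairs <- utils::combn(levels(groups), 2L)
  stat <- p <- numeric(ncol(pairs))
  for (c_ in seq_len(ncol(pairs))) {
    i <- match(pairs[1L, c_], levels(groups))
    j <- match(pairs[2L, c_], levels(groups))
    se <- sqrt(s2 * ((n - 1 - h) / df) * (1 / ns[i] + 1 / ns[j]))
    stat[c_] <- (rbar[i] - rbar[j]) / se
    p[c_] <- 2 * stats::pt(abs(stat[c_]), df, lower.tail = FALSE)
  }
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             statistic = stat, p.value = stats::p.adjust(pmin(p, 1), p_adjust),
             stringsAsFactors = FALSE)
}

#' Shared OTU counts across sample groups
#'
#' An OTU is present in a group when it has at least one read in at least
#' one of the group's samples.
#'
#' @param table a [count_table].
#' @param grouping factor over the table's samples.
#' @return list: `per_group` (OTUs present per group), `pairwise` (group x
#'   group shared-OTU matrix; diagonal = per-group totals), `unique_to_group`,
#'   `shared_by_all`, `total_present` (OTUs present in >= 1 sample).
#' @export
shared_otu_counts <- function(table, grouping) {
  grouping <- factor(grouping)
  if (length(grouping) != n_samples(table))
    stop("grouping must cover all samples")
  if (any(tabulate(grouping) == 0L)) stop("empty group")
  m <- counts(table) > 0
  pres <- t(vapply(levels(grouping), function(g)
    colSums(m[grouping == g, , drop = FALSE]) > 0, logical(n_otus(table))))
  per_group <- rowSums(pres)
  pw <- pres %*% t(pres)
  in_any <- colSums(pres) > 0
  uniq <- vapply(seq_len(nrow(pres)), function(i)
    sum(pres[i, ] & colSums(pres) == 1L), 0)
  names(uniq) <- levels(grouping)
  list(per_group = per_group, pairwise = pw, unique_to_group = uniq,
       shared_by_all = sum(colSums(pres) == nrow(pres)),
       total_present = sum(in_any))
}

#' Aggregate a count table to a taxonomic rank
#'
#' Counts are summed over OTUs sharing the rank-level name; OTUs with no
#' assignment at the rank are pooled as `"Unassigned"`. Read totals are
#' conserved.
#'
#' @param table a [count_table].
#' @param taxonomy taxonomy data frame ([taxonomy_map()]).
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return list: `counts` (samples x taxa), `global` (proportion of total
#'   reads per taxon), `per_sample` (row-closed proportions).
#' @export
aggregate_taxonomy <- function(table, taxonomy, rank = "phylum") {
  rank <- match.arg(rank, CANONICAL_RANKS)
  labels <- taxonomy[[rank]][match(otu_ids(table), taxonomy$otu_id)]
  labels[is.na(labels) | !nzchar(labels)] <- "Unassigned"
  m <- counts(table)
  agg <- t(rowsum(t(m), group = labels))
  global <- colSums(agg) / sum(agg)
  ord <- order(global, decreasing = TRUE)
  agg <- agg[, ord, drop = FALSE]
  global <- global[ord]
  list(counts = agg, global = global,
       per_sample = sweep(agg, 1L, pmax(rowSums(agg), 1), "/"))
}
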