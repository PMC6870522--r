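#' Summarise a count table as a metacommunity for neutral-model fitting
#'
#' Each sample is treated as a local community drawn from a shared
#' metacommunity. The summary holds everything the Sloan occurrence-
#' abundance model needs: per-OTU metacommunity relative abundance `p`,
#' observed occurrence frequency `f_obs` (fraction of local communities in
#' which the OTU was detected), the effective local community size `N`
#' (mean per-sample read total), and the detection limit `d = 1/N`.
#'
#' OTUs with zero reads in the table (possible after subsetting to a group)
#' are dropped; their ids are recorded in `$dropped`.
#'
#' @param table a [count_table] with >= 2 samples, all totals > 0.
#' @param p_method `"pooled_reads"` (default: OTU reads over grand total) or
#'   `"mean_proportion"` (mean of per-sample proportions).
#' @return object of class `metacommunity_summary`: `p`, `f_obs` (named
#'   vectors), `N`, `d`, `n_local`, `dropped`.
#' @export
prepare_metacommunity <- function(table, p_method = c("pooled_reads",
                                                      "mean_proportion")) {
  p_method <- match.arg(p_method)
  if (n_samples(table) < 2L)
    stop("occurrence frequency is undefined for a single sample")
  ls <- library_sizes(table)
  if (any(ls == 0))
    stop("zero-total sample(s): ", paste(sample_ids(table)[ls == 0],
                                         collapse = ", "))
  m <- counts(table)
  present <- colSums(m) > 0
  dropped <- colnames(m)[!present]
  m <- m[, present, drop = FALSE]
  p <- if (p_method == "pooled_reads") colSums(m) / sum(m)
  else colMeans(sweep(m, 1L, rowSums(m), "/"))
  f_obs <- colMeans(m > 0)
  N <- mean(ls)
  structure(list(p = p, f_obs = f_obs, N = N, d = 1 / N,
                 n_local = nrow(m), dropped = dropped),
            class = "metacommunity_summary")
}

#' @export
print.metacommunity_summary <- function(x, ...) {
  cat(sprintf("metacommunity: %d OTUs over %d local communities, N = %.0f, d = %.3g\n",
              length(x$p), x$n_local, x$N, x$d))
  invisible(x)
}

#' Predicted occurrence frequency under the Sloan neutral model
#'
#' At neutral stationarity the relative abundance of a taxon with
#' metacommunity abundance `p` in a local community of size `N` with
#' migration rate `m` follows Beta(N m p, N m (1 - p)). The taxon is
#' detected when its abundance exceeds the detection limit `d`, so its
#' expected occurrence frequency across local communities is
#' `1 - pbeta(d, N m p, N m (1 - p))`.
#'
#' @param p metacommunity relative abundance(s) in (0, 1).
#' @param N effective local community size (> 0).
#' @param m migration rate in (0, 1].
#' @param d detection limit in (0, 1).
#' @return predicted occurrence frequency in `[0, 1]`, vectorised over `p`.
#' @examples
#' predict_occurrence_neutral(0.01, N = 1000, m = 0.1, d = 0.001)  # ~0.9057
#' @export
predict_occurrence_neutral <- function(p, N, m, d) {
  stopifnot(N > 0, m > 0, m <= 1, d > 0, d < 1)
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  alpha <- N * m * p
  beta <- N * m * (1 - p)
  if (any(alpha <= 0) || any(beta <= 0)) stop("beta shape parameters must be > 0")
  stats::pbeta(d, alpha, beta, lower.tail = FALSE)
}

#' Predicted occurrence under the binomial sampling null
#'
#' The no-dispersal, no-drift null: each local community is a random
#' binomial subsample of the metacommunity, so a taxon is detected when
#' more than `floor(N d)` of `round(N)` reads hit it. With
#' `at_least_one = TRUE` the detection cutoff is >= 1 read instead.
#'
#' @inheritParams predict_occurrence_neutral
#' @param at_least_one use the >= 1 read detection rule.
#' @return predicted occurrence frequency, vectorised over `p`.
#' @export
predict_occurrence_binomial <- function(p, N, d, at_least_one = FALSE) {
  stopifnot(N > 0, d > 0, d < 1)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  cutoff <- if (at_least_one) 0L else floor(N * d)
  stats::pbinom(cutoff, round(N), p, lower.tail = FALSE)
}

#' Fit the Sloan neutral model to occurrence-abundance data
#'
#' Estimates the migration rate `m` by bounded least squares: minimises
#' `sum((f_obs - f_pred(m))^2)` over m in `[1e-6, 1]` with a
#' derivative-based optimizer (relative tolerance 1e-8, up to 500
#' iterations, multi-start at 0.01/0.1/0.5 if the first start fails).
#' Fit quality is the generalised R^2 `1 - SSE/SST` and the Gaussian
#' residual AIC `n log(SSE/n) + 2k` with k = 2 for the neutral model
#' (m + residual variance) and k = 1 for the binomial null.
#'
#' @param summary a `metacommunity_summary` from [prepare_metacommunity()].
#' @param init_m starting value for m.
#' @return object of class `neutral_fit`: `m`, `se_m`, `f_pred` (named),
#'   `r2`, `aic`, `r2_binomial`, `aic_binomial`, `f_pred_binomial`,
#'   `converged`, plus the summary's `N`, `d`, `n_local`.
#' @export
fit_neutral <- function(summary, init_m = 0.1) {
  p <- summary$p; f_obs <- summary$f_obs
  N <- summary$N; d <- summary$d
  if (length(p) < 10L) warning("fewer than 10 OTUs; fit will be unstable")
  if (length(unique(f_obs)) == 1L) stop("all occurrence frequencies identical")
  ok <- p > 0 & p < 1
  sse_of <- function(m) sum((f_obs[ok] -
                               predict_occurrence_neutral(p[ok], N, m, d))^2)
  fit <- NULL; converged <- FALSE
  for (start in unique(c(init_m, 0.01, 0.1, 0.5))) {
    fit <- stats::nlminb(start, sse_of, lower = 1e-6, upper = 1,
                         control = list(iter.max = 500, rel.tol = 1e-8))
    if (fit$convergence == 0) { converged <- TRUE; break }
  }
  m_hat <- fit$par
  f_pred <- rep(NA_real_, length(p)); names(f_pred) <- names(p)
  f_pred[ok] <- predict_occurrence_neutral(p[ok], N, m_hat, d)
  n <- sum(ok)
  sse <- fit$objective
  sst <- sum((f_obs[ok] - mean(f_obs[ok]))^2)
  r2 <- 1 - sse / sst
  # standard error of m via the Gauss-Newton curvature of the SSE
  eps <- max(1e-5, 1e-4 * m_hat)
  m_lo <- max(1e-6, m_hat - eps); m_hi <- min(1, m_hat + eps)
  d2 <- (sse_of(m_hi) - 2 * sse + sse_of(m_lo)) / ((m_hi - m_lo) / 2)^2
  sigma2 <- sse / max(n - 1, 1)
  se_m <- if (is.finite(d2) && d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
  # detection for the null must mirror f_obs (count >= 1), not the
  # two-read cutoff that floor(N*d) = 1 would impose
  f_bin <- predict_occurrence_binomial(p[ok], N, d, at_least_one = TRUE)
  sse_bin <- sum((f_obs[ok] - f_bin)^2)
  f_pred_bin <- rep(NA_real_, length(p)); names(f_pred_bin) <- names(p)
  f_pred_bin[ok] <- f_bin
  structure(list(m = m_hat, se_m = se_m, f_pred = f_pred,
                 r2 = r2, aic = n * log(sse / n) + 2 * 2,
                 r2_binomial = 1 - sse_bin / sst,
                 aic_binomial = n * log(sse_bin / n) + 2 * 1,
                 f_pred_binomial = f_pred_bin,
                 converged = converged, N = N, d = d,
                 n_local = summary$n_local),
            class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral model: m = %.4f (SE %.4f), R2 = %.3f, AIC = %.1f\n",
              x$m, x$se_m, x$r2, x$aic))
  cat(sprintf("binomial null:       R2 = %.3f, AIC = %.1f\n",
              x$r2_binomial, x$aic_binomial))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' @param p proportion estimate(s).
#' @param n number of trials.
#' @param level confidence level in percent (e.g. 95, 99).
#' @return two-column matrix `lower`, `upper`; always within `[0, 1]` and
#'   containing `p`.
#' @export
wilson_interval <- function(p, n, level = 95) {
  z <- stats::qnorm(1 - (1 - level / 100) / 2)
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(lower = pmax(center - half, 0), upper = pmin(center + half, 1))
}

#' Classify OTUs as neutral or under positive/negative selection
#'
#' Builds a confidence band around each OTU's predicted occurrence using a
#' binomial-proportion interval with `n_local` trials: an OTU observed more
#' often than the upper bound is classified `above` (consistent with
#' positive host selection), less often than the lower bound `below`
#' (negative selection), and otherwise `neutral`. Boundary equality counts
#' as neutral.
#'
#' @param summary a `metacommunity_summary`.
#' @param fit a `neutral_fit` (must have converged).
#' @param level confidence level in percent, 95 or 99 (override with
#'   `allow_any_level = TRUE`).
#' @param method `"wilson"` (default; the convention of the published
#'   fitting scripts), `"jeffreys"`, or `"prediction"` — a binomial
#'   prediction band `qbinom((1±level)/2, n_local, f_pred)/n_local`. The
#'   Wilson/Jeffreys bands are confidence intervals *around the predicted
#'   frequency* and are anti-conservative for OTUs predicted near 0 or 1
#'   occupancy (e.g. f_pred = 0.99 over 30 hosts: observed occupancy 1 is
#'   expected 74% of the time yet lies above the Wilson band); the
#'   prediction band has calibrated coverage under the fitted model.
#' @param allow_any_level permit levels other than 95/99.
#' @return list of class `otu_classification`: `class` (named factor with
#'   levels neutral/above/below), `lower`, `upper`, `fractions` (named
#'   numeric summing to 1), `neutral_fraction`, `level`.
#' @export
classify_otus <- function(summary, fit, level = 95,
                          method = c("wilson", "jeffreys", "prediction"),
                          allow_any_level = FALSE) {
  method <- match.arg(method)
  if (!allow_any_level && !level %in% c(95, 99))
    stop("level must be 95 or 99 (set allow_any_level to override)")
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  ok <- !is.na(fit$f_pred)
  f_pred <- fit$f_pred[ok]
  f_obs <- summary$f_obs[names(f_pred)]
  n <- summary$n_local
  a <- 1 - (1 - level / 100) / 2
  ci <- switch(method,
    wilson = wilson_interval(f_pred, n, level),
    jeffreys = cbind(
      lower = stats::qbeta(1 - a, n * f_pred + 0.5, n * (1 - f_pred) + 0.5),
      upper = stats::qbeta(a, n * f_pred + 0.5, n * (1 - f_pred) + 0.5)),
    prediction = cbind(lower = stats::qbinom(1 - a, n, f_pred) / n,
                       upper = stats::qbinom(a, n, f_pred) / n))
  cls <- rep("neutral", length(f_pred))
  cls[f_obs > ci[, "upper"]] <- "above"
  cls[f_obs < ci[, "lower"]] <- "below"
  cls <- factor(cls, levels = c("neutral", "above", "below"))
  names(cls) <- names(f_pred)
  fractions <- table(cls) / length(cls)
  list(class = cls, lower = ci[, "lower"], upper = ci[, "upper"],
       fractions = c(fractions), neutral_fraction = unname(fractions["neutral"]),
       level = level)
}

#' Compare the neutral model with the binomial sampling null
#'
#' @param summary a `metacommunity_summary`.
#' @param init_m starting value passed to [fit_neutral()].
#' @return data frame with one row per model: model, R2, AIC, dAIC,
#'   preferred (lowest AIC).
#' @export
compare_models <- function(summary, init_m = 0.1) {
  fit <- fit_neutral(summary, init_m = init_m)
  aics <- c(neutral = fit$aic, binomial = fit$aic_binomial)
  data.frame(model = names(aics),
             R2 = c(fit$r2, fit$r2_binomial),
             AIC = unname(aics),
             dAIC = unname(aics - min(aics)),
             preferred = unname(aics == min(aics)),
             stringsAsFactors = FALSE)
}

#' Fit the neutral model independently within sample groups
#'
#' Mirrors the two model sets used for host-associated data: one fit per
#' sampling location (pooling host species), or one per species-by-location
#' combination. Each group gets its own metacommunity summary and fit;
#' groups with fewer than `min_samples` samples are skipped with a warning.
#'
#' @param table a [count_table].
#' @param metadata data frame with `sample_id` and the grouping columns.
#' @param group_by character vector of metadata column names (one or more;
#'   several columns define the interaction grouping).
#' @param level confidence level for classification (95 or 99).
#' @param min_samples minimum samples per group (default 2).
#' @param p_method passed to [prepare_metacommunity()].
#' @return list of class `group_fits`: `fits` (per-group list with
#'   `summary`, `fit`, `classification`), `neutral_fractions` (named),
#'   `mean_neutral_fraction`, `sd_neutral_fraction`, `skipped`.
#' @export
fit_per_group <- function(table, metadata, group_by, level = 99,
                          min_samples = 2L, p_method = "pooled_reads") {
  joined <- join_metadata(table, metadata)
  md <- joined$metadata
  for (g in group_by) if (!g %in% names(md)) stop("no metadata column '", g, "'")
  key <- interaction(md[group_by], drop = TRUE, sep = " x ")
  fits <- list(); skipped <- character()
  for (g in levels(key)) {
    ids <- md$sample_id[key == g]
    if (length(ids) < min_samples) {
      warning("skipping group '", g, "' with ", length(ids), " sample(s)")
      skipped <- c(skipped, g)
      next
    }
    sub <- subset_table(joined$table, samples = ids)
    res_g <- tryCatch({
      summ <- prepare_metacommunity(sub, p_method = p_method)
      fit <- fit_neutral(summ)
      cls <- if (fit$converged) classify_otus(summ, fit, level = level) else NULL
      list(summary = summ, fit = fit, classification = cls)
    }, error = function(e) e)
    if (inherits(res_g, "error")) {
      warning("skipping group '", g, "': ", conditionMessage(res_g))
      skipped <- c(skipped, g)
    } else fits[[g]] <- res_g
  }
  if (length(fits) == 0L) stop("no viable group")
  nf <- vapply(fits, function(x)
    if (is.null(x$classification)) NA_real_ else
      x$classification$neutral_fraction, 0)
  structure(list(fits = fits, neutral_fractions = nf,
                 mean_neutral_fraction = mean(nf, na.rm = TRUE),
                 sd_neutral_fraction = stats::sd(nf, na.rm = TRUE),
                 skipped = skipped, level = level),
            class = "group_fits")
}

#' @export
print.group_fits <- function(x, ...) {
  cat(sprintf("neutral fits for %d group(s), %d%% CI\n",
              length(x$fits), x$level))
  for (g in names(x$fits))
    cat(sprintf("  %-25s m = %.4f  neutral = %.1f%%\n", g, x$fits[[g]]$fit$m,
                100 * x$neutral_fractions[g]))
  cat(sprintf("mean neutral fraction: %.1f%% (SD %.2f%%)\n",
              100 * x$mean_neutral_fraction, 100 * x$sd_neutral_fraction))
  invisible(x)
}

lineage_pair_distance <- function(l1, l2) {
  shared <- 0L
  for (k in seq_len(7L)) {
    if (nzchar(l1[k]) && l1[k] == l2[k]) shared <- k else break
  }
  100 * (7L - shared) / 7L
}

#' Average taxonomic distinctness of a set of lineages
#'
#' Delta+ (average taxonomic distinctness): the mean pairwise taxonomic
#' path length among taxa, with equal step weights across the seven ranks.
#' The distance between two taxa is `100 * (7 - s) / 7` where `s` is the
#' deepest rank down to which their lineages agree, so taxa sharing no
#' kingdom score 100 and identical lineages score 0.
#'
#' @param taxonomy taxonomy data frame ([taxonomy_map()]) for the taxa of
#'   one class (>= 2 rows).
#' @return scalar Delta+ in `[0, 100]`.
#' @export
taxonomic_distinctness <- function(taxonomy) {
  lin <- as.matrix(taxonomy[, CANONICAL_RANKS, drop = FALSE])
  n <- nrow(lin)
  if (n < 2L) stop("need >= 2 taxa")
  s <- 0; np <- 0L
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    s <- s + lineage_pair_distance(lin[i, ], lin[j, ])
    np <- np + 1L
  }
  s / np
}

#' Compare taxonomic distinctness between OTU selection classes
#'
#' Bootstrap null: for each class, `n_boot` random subsets of the pooled
#' lineages at the class's size give the expected distribution of Delta+
#' for a class of that size; the observed value is compared to it.
#'
#' @param taxonomy taxonomy data frame covering all classified OTUs.
#' @param classes named factor as in `otu_classification$class`.
#' @param n_boot bootstrap resamples (default 999).
#' @param seed integer RNG seed.
#' @return data frame per class: class, n, delta_plus, boot_mean, boot_lo,
#'   boot_hi (2.5/97.5% quantiles), p (two-sided bootstrap tail).
#' @export
selection_class_distinctness <- function(taxonomy, classes, n_boot = 999,
                                         seed = 1) {
  local_seed(seed)
  tax <- taxonomy[match(names(classes), taxonomy$otu_id), , drop = FALSE]
  pooled <- tax[!is.na(tax$otu_id), , drop = FALSE]
  out <- list()
  for (cl in levels(classes)) {
    ids <- names(classes)[classes == cl]
    sub <- tax[tax$otu_id %in% ids, , drop = FALSE]
    if (nrow(sub) < 2L) next
    obs <- taxonomic_distinctness(sub)
    boot <- replicate(n_boot, taxonomic_distinctness(
      pooled[sample.int(nrow(pooled), nrow(sub)), , drop = FALSE]))
    p_tail <- (min(sum(boot <= obs), sum(boot >= obs)) + 1) / (n_boot + 1)
    out[[cl]] <- data.frame(class = cl, n = nrow(sub), delta_plus = obs,
                            boot_mean = mean(boot),
                            boot_lo = unname(stats::quantile(boot, 0.025)),
                            boot_hi = unname(stats::quantile(boot, 0.975)),
                            p = min(2 * p_tail, 1),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
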