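test_that("metacommunity preparation matches hand arithmetic", {
  m <- rbind(s1 = c(10, 0, 10, 0),
             s2 = c(10, 10, 0, 0),
             s3 = c(20, 0, 0, 0),
             s4 = c(15, 5, 0, 0))
  colnames(m) <- paste0("o", 1:4)
  su <- prepare_metacommunity(count_table(m))
  expect_equal(unname(su$p), c(55, 15, 10, 0)[1:3] / 80)
  expect_equal(unname(su$f_obs), c(1, 0.5, 0.25))
  expect_equal(su$N, 20)
  expect_equal(su$d, 1 / 20)
  expect_identical(su$n_local, 4L)
  expect_identical(su$dropped, "o4")        # zero-read OTU dropped
  expect_equal(sum(su$p), 1)

  # 2 samples, OTU present in one -> f_obs = 0.5; uniform table -> all equal
  u <- count_table(matrix(5, 3, 4, dimnames = list(paste0("s", 1:3),
                                                   paste0("o", 1:4))))
  suu <- prepare_metacommunity(u)
  expect_true(all(suu$p == 0.25) && all(suu$f_obs == 1))
  expect_error(prepare_metacommunity(subset_table(u, samples = "s1")),
               "single sample")
  # mean-of-proportions option
  sup <- prepare_metacommunity(count_table(m), p_method = "mean_proportion")
  expect_equal(unname(sup$p),
               unname(colMeans(sweep(m[, 1:3], 1, rowSums(m), "/"))))
})

test_that("neutral occurrence prediction matches closed forms and limits", {
  # alpha = N m p = 1: 1 - CDF(d) of Beta(1, b) is (1 - d)^b
  expect_equal(predict_occurrence_neutral(0.01, 1000, 0.1, 0.001),
               0.999^99)
  # m -> 0+: mass splits to {0, 1} with weights (1-p, p), so f_pred -> p
  expect_equal(predict_occurrence_neutral(0.3, 10000, 1e-9, 0.2), 0.3,
               tolerance = 1e-5)
  # concentration limit: large N m with p >> d
  expect_equal(predict_occurrence_neutral(0.2, 1e6, 0.9, 1e-4), 1)
  expect_error(predict_occurrence_neutral(0, 100, 0.1, 0.01), "strictly")
  expect_error(predict_occurrence_neutral(0.5, 100, 0, 0.01))
  # monotone in p, and in m for p > d (lattice check)
  N <- 5000; d <- 1 / N
  for (m_ in c(0.02, 0.1, 0.5)) {
    f <- predict_occurrence_neutral(seq(1e-4, 0.05, length.out = 40), N, m_, d)
    expect_true(all(diff(f) >= -1e-12))
  }
  for (p_ in c(5e-4, 2e-3, 0.01)) {
    f <- vapply(seq(0.01, 1, length.out = 30),
                function(m_) predict_occurrence_neutral(p_, N, m_, d), 0)
    expect_true(all(diff(f) >= -1e-9))
  }
})

test_that("binomial occurrence prediction equals the direct summation", {
  N <- 500; p <- 0.004; d <- 1 / N
  # cutoff form: 1 - P(X <= floor(N d)) = 1 - P(X <= 1)
  direct <- 1 - sum(vapply(0:1, function(k)
    choose(N, k) * p^k * (1 - p)^(N - k), 0))
  expect_equal(predict_occurrence_binomial(p, N, d), direct)
  expect_equal(predict_occurrence_binomial(1 - 1e-12, N, d), 1)
  expect_equal(predict_occurrence_binomial(0, N, d), 0)
  # >= 1 read variant
  expect_equal(predict_occurrence_binomial(p, N, d, at_least_one = TRUE),
               1 - (1 - p)^N)
})

test_that("fit recovers m exactly from a noiseless neutral curve", {
  p <- exp(seq(log(2e-5), log(0.05), length.out = 80))
  p <- p / sum(p) * 0.5          # keep p's in (0,1), spread over decades
  N <- 20000; m_true <- 0.3
  su <- structure(list(p = stats::setNames(p, paste0("o", seq_along(p))),
                       f_obs = predict_occurrence_neutral(p, N, m_true, 1 / N),
                       N = N, d = 1 / N, n_local = 50L, dropped = character()),
                  class = "metacommunity_summary")
  fit <- fit_neutral(su)
  expect_true(fit$converged)
  expect_equal(fit$m, 0.3, tolerance = 1e-4)
  expect_equal(fit$r2, 1, tolerance = 1e-8)
  # grid oracle: a 0.001-step grid brackets the least-squares optimum
  grid <- seq(0.001, 1, by = 0.001)
  sse <- vapply(grid, function(mm)
    sum((su$f_obs - predict_occurrence_neutral(p, N, mm, 1 / N))^2), 0)
  expect_lt(abs(grid[which.min(sse)] - fit$m), 0.001)
})

test_that("fit warns on few OTUs and flags degenerate occurrence", {
  su <- structure(list(p = c(o1 = 0.4, o2 = 0.6), f_obs = c(1, 1),
                       N = 100, d = 0.01, n_local = 5L, dropped = character()),
                  class = "metacommunity_summary")
  expect_error(suppressWarnings(fit_neutral(su)), "identical")
})

test_that("wilson intervals stay in [0,1] and contain the estimate", {
  p <- c(1e-6, 0.01, 0.5, 0.99, 1 - 1e-6)
  for (lv in c(95, 99)) {
    ci <- wilson_interval(p, 30, lv)
    expect_true(all(ci[, "lower"] >= 0 & ci[, "upper"] <= 1))
    expect_true(all(ci[, "lower"] <= p & p <= ci[, "upper"]))
  }
})

test_that("classification semantics: on-curve neutral, band violations flagged", {
  w <- demo_neutral(seed = 301)
  su <- prepare_metacommunity(w$table)
  fit <- fit_neutral(su)
  cl <- classify_otus(su, fit, 95)
  expect_equal(sum(cl$fractions), 1)
  expect_setequal(levels(cl$class), c("neutral", "above", "below"))
  # boundary equality classifies neutral: construct it directly
  su2 <- su
  su2$f_obs[] <- fit$f_pred[names(su2$f_obs)]   # exactly on the curve
  cl2 <- classify_otus(su2, fit, 99)
  expect_true(all(cl2$class == "neutral"))
  # f_obs = 1 with CI upper < 1 -> above
  idx <- which(cl$upper < 1 - 1e-6)[1]
  su3 <- su
  su3$f_obs[names(idx)] <- 1
  cl3 <- classify_otus(su3, fit, 95)
  expect_identical(as.character(cl3$class[names(idx)]), "above")
  expect_error(classify_otus(su, fit, 90), "95 or 99")
  cl90 <- classify_otus(su, fit, 90, allow_any_level = TRUE)
  expect_equal(cl90$level, 90)
})

test_that("classification fractions are invariant to OTU and sample order", {
  w <- demo_neutral(seed = 302, n_taxa = 80, n_samples = 20)
  tb <- w$table
  su <- prepare_metacommunity(tb)
  cl <- classify_otus(su, fit_neutral(su), 95)
  set.seed(1)
  tb2 <- count_table(counts(tb)[sample(n_samples(tb)), sample(n_otus(tb))])
  su2 <- prepare_metacommunity(tb2)
  cl2 <- classify_otus(su2, fit_neutral(su2), 95)
  expect_equal(cl$fractions, cl2$fractions)
  expect_equal(cl$class[sort(names(cl$class))], cl2$class[sort(names(cl2$class))])
})

test_that("model comparison reports dAIC = 2 when predictions coincide", {
  # degenerate spread: all p equal -> both models predict a constant, the
  # same SSE, and the AIC difference is exactly the parameter penalty
  su <- structure(list(p = stats::setNames(rep(0.05, 20), paste0("o", 1:20)),
                       f_obs = rep(c(0.4, 0.6), 10),
                       N = 100, d = 0.01, n_local = 10L, dropped = character()),
                  class = "metacommunity_summary")
  fit <- fit_neutral(su)
  # neutral can match the binomial's constant prediction at best equally;
  # compare AICs net of fit: dAIC >= penalty difference is the bookkeeping
  cm <- compare_models(su)
  expect_identical(cm$model[cm$preferred], cm$model[which.min(cm$AIC)])
  sse_n <- (1 - fit$r2) * sum((su$f_obs - mean(su$f_obs))^2)
  expect_equal(fit$aic, 20 * log(sse_n / 20) + 4)
})

test_that("per-group fits are independent, deterministic, and bookkept", {
  w1 <- demo_neutral(seed = 303, n_taxa = 100, n_samples = 12)
  m <- counts(w1$table)
  # two identical groups -> identical fits
  m2 <- rbind(m, m)
  rownames(m2) <- c(paste0("a", 1:12), paste0("b", 1:12))
  tb <- count_table(m2)
  md <- data.frame(sample_id = rownames(m2),
                   location = rep(c("L1", "L2"), each = 12),
                   species = "sp")
  gf <- fit_per_group(tb, md, "location", level = 99)
  expect_equal(gf$fits$L1$fit$m, gf$fits$L2$fit$m)
  expect_equal(unname(gf$neutral_fractions["L1"]),
               unname(gf$neutral_fractions["L2"]))
  expect_true(all(gf$neutral_fractions >= 0 & gf$neutral_fractions <= 1))
  expect_equal(gf$mean_neutral_fraction, mean(gf$neutral_fractions))
  # undersized groups are skipped with a warning
  md2 <- md; md2$location[1] <- "L3"
  expect_warning(gf2 <- fit_per_group(tb, md2, "location"), "skipping")
  expect_identical(gf2$skipped, "L3")
  # species x location interaction grouping
  md3 <- md
  md3$species <- rep(rep(c("s1", "s2"), each = 6), 2)
  gf3 <- fit_per_group(tb, md3, c("species", "location"), level = 95)
  expect_identical(length(gf3$fits), 4L)
})

test_that("taxonomic distinctness matches enumeration and hits its endpoints", {
  # same genus, different species: minimal one-step distance 100/7
  tx_genus <- taxonomy_map(c("a", "b", "c"),
    c("k__K; p__P; c__C; o__O; f__F; g__G; s__x",
      "k__K; p__P; c__C; o__O; f__F; g__G; s__y",
      "k__K; p__P; c__C; o__O; f__F; g__G; s__z"))
  expect_equal(taxonomic_distinctness(tx_genus), 100 / 7)
  # distinct kingdoms: maximal 100
  tx_king <- taxonomy_map(c("a", "b"), c("k__K1", "k__K2"))
  expect_equal(taxonomic_distinctness(tx_king), 100)
  # identical lineages: 0
  tx_same <- taxonomy_map(c("a", "b"),
    rep("k__K; p__P; c__C; o__O; f__F; g__G; s__s", 2))
  expect_equal(taxonomic_distinctness(tx_same), 0)
  # 4-lineage toy vs hand enumeration of the 6 pairs
  tx4 <- taxonomy_map(c("w", "x", "y", "z"),
    c("k__K; p__P; c__C1",
      "k__K; p__P; c__C1",
      "k__K; p__P; c__C2",
      "k__K; p__Q"))
  # pairs: wx share class (s=3) -> 4/7*100... steps: w-x: shared 3 ranks
  d_ <- function(s) 100 * (7 - s) / 7
  hand <- mean(c(d_(3), d_(2), d_(1), d_(2), d_(1), d_(1)))
  expect_equal(taxonomic_distinctness(tx4), hand)
})

test_that("the binomial prediction band is calibrated on pure-neutral data", {
  # companion to the (red) Wilson-band acceptance criterion: with the
  # acceptance region taken as the binomial prediction interval around the
  # fitted occupancy, pure-neutral simulations classify <= 10% non-neutral
  nn <- vapply(1:10, function(r) {
    s <- 40000 + 97 * r
    p <- sample_metacommunity(simulation_config(n_taxa = 150, seed = s))
    tb <- simulate_neutral_table(p, 0.1, 30000, 30, 30000, seed = s + 1)
    su <- prepare_metacommunity(tb)
    su$p <- p[names(su$p)] / sum(p[names(su$p)])
    cl <- classify_otus(su, fit_neutral(su), 95, method = "prediction")
    1 - cl$neutral_fraction
  }, 0)
  expect_lte(mean(nn), 0.10)
})

test_that("selection-class bootstrap comparison is reproducible and sane", {
  set.seed(30)
  lin <- c(sprintf("k__B; p__P%d; c__C%d", rep(1:4, each = 5), 1:20),
           sprintf("k__B; p__Q; c__D%d", 1:10))
  tx <- taxonomy_map(sprintf("o%02d", 1:30), lin)
  cls <- factor(rep(c("neutral", "above", "below"), c(18, 8, 4)),
                levels = c("neutral", "above", "below"))
  names(cls) <- tx$otu_id
  res <- selection_class_distinctness(tx, cls, n_boot = 199, seed = 4)
  expect_identical(res$class, c("neutral", "above", "below"))
  expect_true(all(res$delta_plus >= 0 & res$delta_plus <= 100))
  expect_true(all(res$boot_lo <= res$boot_hi))
  res2 <- selection_class_distinctness(tx, cls, n_boot = 199, seed = 4)
  expect_identical(res, res2)
})
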