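# brute_oneway_F and all_perms come from helper-oracles.R

test_that("permanova matches the exhaustive brute-force oracle on 6 samples", {
  set.seed(21)
  pts <- rbind(matrix(rnorm(6, 0), 3, 2), matrix(rnorm(6, 1.2), 3, 2))
  rownames(pts) <- paste0("s", 1:6)
  d <- as.matrix(dist(pts))
  md <- data.frame(grp = rep(c("a", "b"), each = 3))
  perms <- all_perms(6)
  res <- permanova(d, md, "grp", permutations = perms)

  f_obs <- brute_oneway_F(d, md$grp)
  expect_equal(res$F[1], f_obs, tolerance = 1e-10)
  f_perm <- apply(perms, 1, function(p_) brute_oneway_F(d[p_, p_], md$grp))
  p_exact <- (sum(f_perm >= f_obs - 1e-12) + 1) / (length(f_perm) + 1)
  expect_equal(res$p[1], p_exact, tolerance = 1e-12)
})

test_that("permanova agrees with vegan::adonis2 on a two-factor design", {
  set.seed(22)
  md <- data.frame(Species = rep(c("sp1", "sp2"), 8),
                   Location = rep(c("L1", "L2"), each = 8))
  m <- matrix(rpois(16 * 12, 20), 16, 12,
              dimnames = list(paste0("s", 1:16), paste0("o", 1:12)))
  m[md$Location == "L2", 1:4] <- m[md$Location == "L2", 1:4] + 30
  d <- distance_matrix(count_table(m), "bray_curtis")
  res <- permanova(d, md, "Species + Location + Species:Location",
                   nperm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ Species + Location + Species:Location,
                        data = md, permutations = 99, by = "terms")
  expect_equal(res$SumOfSqs[1:3], ref$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(res$F[1:3], ref$F[1:3], tolerance = 1e-8)
  expect_equal(res$R2[1:5], ref$R2[1:5], tolerance = 1e-8)
})

test_that("permanova table satisfies its bookkeeping invariants", {
  set.seed(23)
  md <- data.frame(g = rep(c("a", "b", "c"), each = 4))
  m <- matrix(rpois(12 * 8, 12), 12, 8,
              dimnames = list(paste0("s", 1:12), paste0("o", 1:8)))
  d <- distance_matrix(count_table(m), "bray_curtis")
  res <- permanova(d, md, "g", nperm = 199, seed = 5)
  k <- nrow(res)
  expect_equal(sum(res$SumOfSqs[seq_len(k - 2)]) + res$SumOfSqs[k - 1],
               res$SumOfSqs[k])
  expect_equal(sum(res$R2[seq_len(k - 1)]), 1)
  expect_gte(res$p[1], 1 / 200)
  # reproducible under seed
  res2 <- permanova(d, md, "g", nperm = 199, seed = 5)
  expect_identical(res, res2)
  # clearly separated clusters: R2 near 1, p at the floor
  pts <- rbind(matrix(rnorm(10, 0, .05), 5, 2), matrix(rnorm(10, 5, .05), 5, 2))
  rownames(pts) <- paste0("x", 1:10)
  dd <- as.matrix(dist(pts))
  sep <- permanova(dd, data.frame(g = rep(c("a", "b"), each = 5)), "g",
                   nperm = 199, seed = 1)
  expect_gt(sep$R2[1], 0.95)
  # the permutation floor is not exactly 1/(nperm+1) here: group-preserving
  # permutations (2 * 5! * 5! of 10!) reproduce the observed F
  expect_lte(sep$p[1], 0.05)
  expect_error(permanova(dd, data.frame(g = rep("a", 10)), "g"), "single level")
})

test_that("pcoa reconstructs euclidean configurations", {
  pts <- cbind(c(0, 3, 0, 5), c(0, 0, 4, 5))
  rownames(pts) <- paste0("s", 1:4)
  d <- as.matrix(dist(pts))
  ord <- pcoa(d)
  expect_equal(as.matrix(dist(ord$points)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  # eigenvalue sum equals the Gower-centered trace (total SS identity)
  expect_equal(sum(ord$eigenvalues), sum(d[upper.tri(d)]^2) / 4)
  # collinear points: one dominant positive axis
  line <- as.matrix(dist(cbind(1:5, 0)))
  rownames(line) <- colnames(line) <- paste0("p", 1:5)
  ordl <- pcoa(line)
  expect_equal(ncol(ordl$points), 1L)
})

test_that("cap_discrim separates disjoint clusters and is honest on noise", {
  set.seed(24)
  pts <- rbind(matrix(rnorm(20, 0, .1), 10, 2),
               matrix(rnorm(20, 4, .1), 10, 2))
  rownames(pts) <- paste0("s", 1:20)
  d <- as.matrix(dist(pts))
  grp <- rep(c("a", "b"), each = 10)
  res <- cap_discrim(d, grp, nperm = 99, seed = 1)
  expect_equal(res$success, 1)
  expect_equal(unname(res$group_success), c(1, 1))
  expect_equal(res$p_value, 1 / 100)
  expect_lte(sum(res$proportion_of_trace), 1 + 1e-9)

  # labels shuffled on structureless data: success near chance (1/2)
  set.seed(25)
  noise <- as.matrix(dist(matrix(rnorm(40), 20, 2)))
  rownames(noise) <- colnames(noise) <- paste0("n", 1:20)
  succ <- replicate(40, {
    g <- sample(rep(c("a", "b"), each = 10))
    cap_discrim(noise, g, max_axes = 2, nperm = 0, seed = 1)$success
  })
  # chance level for 2 groups is 0.5; leave-one-out is mildly pessimistic
  # on pure noise (measured mean 0.44, sd 0.20 over shuffles), so assert a
  # band around chance rather than a razor-thin binomial CI
  expect_lt(mean(succ), 0.6)
  expect_gt(mean(succ), 0.3)
  expect_error(cap_discrim(d, c("a", rep("b", 19))), ">= 2 samples")
})

test_that("kruskal-wallis matches stats::kruskal.test with and without ties", {
  x <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b", "c"), each = 2)
  mine <- kruskal_wallis(x, g)
  ref <- stats::kruskal.test(x, factor(g))
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p.value, ref$p.value)
  expect_identical(mine$df, 2L)
  # hand rank-sum oracle: H = 12/(n(n+1)) * sum R_j^2/n_j - 3(n+1)
  expect_equal(mine$statistic, 12 / (6 * 7) * (3^2 / 2 + 7^2 / 2 + 11^2 / 2) - 21)
  # ties
  xt <- c(1, 1, 2, 2, 3, 3, 4, 5)
  gt <- rep(c("a", "b"), 4)
  expect_equal(kruskal_wallis(xt, gt)$statistic,
               unname(stats::kruskal.test(xt, factor(gt))$statistic))
  # identical distributions across groups -> H = 0
  expect_equal(kruskal_wallis(c(1, 2, 1, 2), rep(c("a", "b"), each = 2))$statistic,
               0, tolerance = 1e-12)
})

test_that("kruskal-wallis chi-square p agrees with exhaustive permutation", {
  x <- c(3, 9, 14, 20, 26, 31)
  g <- rep(c("a", "b", "c"), each = 2)
  mine <- kruskal_wallis(x, g)
  perms <- all_perms(6)
  h_all <- apply(perms, 1, function(p_) kruskal_wallis(x[p_], g)$statistic)
  p_exact <- mean(h_all >= mine$statistic - 1e-12)
  # chi-square approximation error at n = 6 is sizable but bounded
  expect_lt(abs(mine$p.value - p_exact), 0.08)
})

test_that("conover post-hoc matches the textbook statistic and orders pairs", {
  # 9-value fixture, independent formula implementation as oracle
  x <- c(2.1, 2.5, 2.3, 4.0, 4.4, 4.1, 2.2, 2.6, 2.4)
  g <- factor(rep(c("a", "b", "c"), each = 3))
  res <- conover_posthoc(x, g)
  n <- 9; k <- 3
  r <- rank(x)
  rbar <- tapply(r, g, mean); ns <- tabulate(g)
  h <- kruskal_wallis(x, g)$statistic
  s2 <- (sum(r^2) - n * (n + 1)^2 / 4) / (n - 1)
  t_ab <- (rbar["a"] - rbar["b"]) /
    sqrt(s2 * ((n - 1 - h) / (n - k)) * (1 / 3 + 1 / 3))
  expect_equal(res$statistic[res$group1 == "a" & res$group2 == "b"],
               unname(t_ab))
  expect_equal(res$p.value[res$group1 == "a" & res$group2 == "b"],
               unname(2 * pt(abs(t_ab), n - k, lower.tail = FALSE)))
  # the shifted group (b) has the two smallest pairwise p values
  ord <- order(res$p.value)
  expect_setequal(c(res$group1[ord[1:2]], res$group2[ord[1:2]]) |>
                    table() |> which.max() |> names(), "b")
  # identical groups -> p near 1
  res2 <- conover_posthoc(c(1, 2, 3, 1, 2, 3, 9, 10, 11),
                          factor(rep(c("a", "b", "c"), each = 3)))
  expect_gt(res2$p.value[res2$group1 == "a" & res2$group2 == "b"], 0.9)
  # adjustment is applied
  res3 <- conover_posthoc(x, g, p_adjust = "bonferroni")
  expect_equal(res3$p.value,
               pmin(res$p.value * 3, 1))
})

test_that("shared OTU counts reproduce a hand-built venn diagram", {
  #              g1 only  g2 only  g3 only  g1g2  g1g3  g2g3  all
  # otus:          o1       o2       o3      o4    o5    o6    o7
  m <- rbind(
    s1 = c(1, 0, 0, 1, 1, 0, 1),
    s2 = c(0, 1, 0, 1, 0, 1, 1),
    s3 = c(0, 0, 1, 0, 1, 1, 1))
  colnames(m) <- paste0("o", 1:7)
  tb <- count_table(m)
  res <- shared_otu_counts(tb, c("g1", "g2", "g3"))
  expect_equal(unname(res$per_group), c(4, 4, 4))
  expect_equal(res$pairwise["g1", "g2"], 2)  # o4, o7
  expect_equal(res$pairwise["g1", "g3"], 2)  # o5, o7
  expect_equal(res$shared_by_all, 1)
  expect_equal(unname(res$unique_to_group), c(1, 1, 1))
  expect_equal(res$total_present, 7)
  # one group: shared-by-all = everything present
  res1 <- shared_otu_counts(tb, rep("g", 3))
  expect_equal(res1$shared_by_all, 7)
  # disjoint incidence
  m2 <- rbind(s1 = c(1, 1, 0, 0), s2 = c(0, 0, 1, 1))
  colnames(m2) <- paste0("o", 1:4)
  res2 <- shared_otu_counts(count_table(m2), c("a", "b"))
  expect_equal(res2$pairwise["a", "b"], 0)
})

test_that("taxonomy aggregation conserves reads and pools unassigned", {
  m <- matrix(c(30, 10, 5,
                45, 15, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("o1", "o2", "o3")))
  tx <- taxonomy_map(c("o1", "o2", "o3"),
                     c("k__Bacteria; p__Proteobacteria",
                       "k__Bacteria; p__Firmicutes",
                       ""))
  agg <- aggregate_taxonomy(count_table(m), tx, "phylum")
  expect_equal(sum(agg$counts), sum(m))                      # conservation
  expect_equal(unname(agg$global["Proteobacteria"]), 75 / 105)
  expect_true("Unassigned" %in% colnames(agg$counts))
  expect_equal(unname(rowSums(agg$per_sample)), c(1, 1))
  # 3:1 reads -> 75%/25%
  m2 <- matrix(c(3, 1), 1, dimnames = list("s", c("o1", "o2")))
  tx2 <- taxonomy_map(c("o1", "o2"), c("k__B; p__X", "k__B; p__Y"))
  g <- aggregate_taxonomy(count_table(m2), tx2, "phylum")$global
  expect_equal(unname(g[c("X", "Y")]), c(0.75, 0.25))
})
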