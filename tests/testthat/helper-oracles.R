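# Independent brute-force oracles shared by the unit and acceptance suites.

# one-way PERMANOVA pseudo-F from within/between squared distances
# (Anderson 2001), independent of the hat-matrix implementation
brute_oneway_F <- function(d, groups) {
  n <- nrow(d)
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  g <- length(unique(groups))
  ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
}

# all n! permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}
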