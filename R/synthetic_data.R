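#' Configuration for the synthetic community generator
#'
#' Collects every parameter of the neutral/selected community simulator so
#' a simulation is fully reproducible from its config + seed. Defaults
#' emulate a realistic amplicon survey of host gut communities: a lognormal
#' metacommunity, migration rate 0.1, local communities of 10,000
#' individuals, and per-sample read depths uniform on [20,000, 60,000]
#' (`depth_preset = "deep"` switches to the 62,000-599,000 range observed
#' in deeply sequenced surveys).
#'
#' @param n_taxa number of OTUs.
#' @param n_samples number of local communities (samples).
#' @param metacommunity `"lognormal"` or `"logseries"`.
#' @param meanlog,sdlog lognormal parameters (sdlog 0 gives a uniform
#'   metacommunity).
#' @param theta log-series parameter in (0, 1).
#' @param m migration rate in (0, 1].
#' @param N_local local community size.
#' @param depth_range per-sample read depth drawn uniformly from this range.
#' @param depth_preset `"default"` or `"deep"` (overrides `depth_range`).
#' @param spiked data frame with columns `otu` (index), `direction`
#'   (`"above"`/`"below"`), `delta` (occurrence offset > 0), or `NULL`.
#' @param host_fraction for diet tables: fraction of each sample's reads
#'   carried by the host OTU, in [0, 1). The complement (default 0.124)
#'   is the prey read fraction.
#' @param read_model read generation model, see [simulate_neutral_table()].
#' @param seed integer RNG seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 300, n_samples = 30,
                              metacommunity = c("lognormal", "logseries"),
                              meanlog = 0, sdlog = 1.5, theta = 0.99,
                              m = 0.1, N_local = 10000,
                              depth_range = c(20000, 60000),
                              depth_preset = c("default", "deep"),
                              spiked = NULL, host_fraction = 0.876,
                              read_model = c("threshold", "binomial"),
                              seed = 1) {
  metacommunity <- match.arg(metacommunity)
  depth_preset <- match.arg(depth_preset)
  read_model <- match.arg(read_model)
  if (depth_preset == "deep") depth_range <- c(62000, 599000)
  stopifnot(n_taxa >= 1, n_samples >= 1, m > 0, m <= 1, N_local >= 1,
            length(depth_range) == 2L, depth_range[1] >= 1,
            diff(depth_range) >= 0,
            host_fraction >= 0, host_fraction < 1)
  if (!is.null(spiked)) {
    stopifnot(all(c("otu", "direction", "delta") %in% names(spiked)),
              all(spiked$delta > 0),
              all(spiked$direction %in% c("above", "below")),
              all(spiked$otu >= 1 & spiked$otu <= n_taxa))
  }
  structure(list(n_taxa = n_taxa, n_samples = n_samples,
                 metacommunity = metacommunity, meanlog = meanlog,
                 sdlog = sdlog, theta = theta, m = m, N_local = N_local,
                 depth_range = depth_range, spiked = spiked,
                 host_fraction = host_fraction, read_model = read_model,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Draw a metacommunity relative-abundance vector
#'
#' Species-abundance distribution of the regional pool: lognormal (the
#' default; `sdlog = 0` degenerates to uniform) or Fisher log-series.
#'
#' @param config a [simulation_config()].
#' @return named numeric vector `p` with all entries > 0 summing to 1.
#' @export
sample_metacommunity <- function(config) {
  local_seed(config$seed)
  n <- config$n_taxa
  ab <- if (config$metacommunity == "lognormal") {
    stats::rlnorm(n, meanlog = config$meanlog, sdlog = config$sdlog)
  } else {
    th <- config$theta
    if (th <= 0 || th >= 1) stop("degenerate log-series parameter theta")
    # inversion sampling of the log-series pmf P(k) = -th^k / (k log(1-th))
    u <- stats::runif(n)
    vapply(u, function(ui) {
      k <- 1; cum <- -config$theta / log(1 - th)
      while (cum < ui && k < 1e6) {
        k <- k + 1
        cum <- cum - th^k / (k * log(1 - th))
      }
      k
    }, 0)
  }
  p <- ab / sum(ab)
  names(p) <- sprintf("otu%04d", seq_len(n))
  p
}

#' Simulate neutral local communities (stationary beta shortcut)
#'
#' For each sample j and OTU i the latent local relative abundance is drawn
#' from the stationary distribution of the neutral model,
#' Beta(N m p_i, N m (1 - p_i)), independently across OTUs. Reads are then
#' derived from the latent abundances by one of two read models:
#'
#' * `"threshold"` (default): `c_ij = floor(depth_j * x_ij)` — the reads
#'   enumerate the local community itself, which is how the occurrence-
#'   abundance fit reads the data (community size N is estimated from read
#'   counts and the detection limit is one read). Under this model an OTU
#'   is detected exactly when its latent abundance exceeds `1/depth`, so
#'   generator and [predict_occurrence_neutral()] close exactly and
#'   [fit_neutral()] is consistent for m.
#' * `"binomial"`: `c_ij ~ Binomial(depth_j, x_ij)` — an independent read-
#'   resampling layer on top of the community. This is more pessimistic
#'   about sequencing noise, but detection at one read becomes a soft
#'   threshold and the hard-threshold Sloan formula then *over*-predicts
#'   occurrence near the detection limit; m estimates inflate by roughly
#'   20-35% under realistic abundance distributions. Provided for
#'   robustness studies, not for calibration tests.
#'
#' The discrete birth-death chain ([simulate_hubbell_process()]) provides
#' the generator-independent cross-check of the stationary beta itself.
#'
#' @param p metacommunity relative abundances (named, sum 1).
#' @param m migration rate in (0, 1].
#' @param N_local local community size.
#' @param n_samples number of samples.
#' @param depths per-sample read depths (recycled to `n_samples`).
#' @param seed integer RNG seed.
#' @param read_model `"threshold"` or `"binomial"` (see above).
#' @return a [count_table] (`n_samples` x `length(p)`).
#' @export
simulate_neutral_table <- function(p, m, N_local, n_samples, depths,
                                   seed = 1,
                                   read_model = c("threshold", "binomial")) {
  read_model <- match.arg(read_model)
  stopifnot(m > 0, m <= 1, N_local >= 1, n_samples >= 1)
  local_seed(seed)
  depths <- rep_len(depths, n_samples)
  alpha <- N_local * m * p
  beta <- N_local * m * (1 - p)
  tiny <- 1e-12
  if (any(alpha < tiny)) {
    warning("clamping ", sum(alpha < tiny), " underflowing beta shape(s)")
    alpha <- pmax(alpha, tiny)
  }
  k <- length(p)
  cnt <- matrix(0, nrow = n_samples, ncol = k,
                dimnames = list(sprintf("sample%04d", seq_len(n_samples)),
                                names(p)))
  for (j in seq_len(n_samples)) {
    x <- stats::rbeta(k, alpha, beta)
    cnt[j, ] <- if (read_model == "threshold") floor(depths[j] * x)
    else stats::rbinom(k, depths[j], x)
  }
  count_table(cnt)
}

#' Simulate exact metacommunity subsamples (the binomial-null truth)
#'
#' Each sample is a pure binomial subsample of the metacommunity — no
#' dispersal limitation, no drift: `c_ij ~ Binomial(depth_j, p_i)`. This is
#' the generating process of the binomial null model and serves as the
#' reciprocal model-recovery case for [compare_models()].
#'
#' @inheritParams simulate_neutral_table
#' @return a [count_table].
#' @export
simulate_subsample_table <- function(p, n_samples, depths, seed = 1) {
  local_seed(seed)
  depths <- rep_len(depths, n_samples)
  cnt <- matrix(0, nrow = n_samples, ncol = length(p),
                dimnames = list(sprintf("sample%04d", seq_len(n_samples)),
                                names(p)))
  for (j in seq_len(n_samples))
    cnt[j, ] <- stats::rbinom(length(p), depths[j], p)
  count_table(cnt)
}

#' Simulate one local community with the discrete Hubbell process
#'
#' A zero-sum birth-death-immigration chain on `N_local` individuals: at
#' each event one individual dies and is replaced by an immigrant drawn
#' from the metacommunity `p` with probability `m`, otherwise by the
#' offspring of a surviving local individual. Run long enough (default
#' 50 N death events) the per-OTU abundances agree with the stationary beta
#' approximation used by [simulate_neutral_table()].
#'
#' @param p metacommunity relative abundances.
#' @param m migration rate; `m = 1` gives i.i.d. multinomial sampling from
#'   `p`, `m = 0` is absorbing (pure drift).
#' @param N_local community size (individuals).
#' @param events number of death events (default `50 * N_local`).
#' @param init optional initial abundance vector (counts summing to
#'   `N_local`); default a multinomial draw from `p`.
#' @param seed integer RNG seed.
#' @return integer abundance vector over the OTUs (sums to `N_local`).
#' @export
simulate_hubbell_process <- function(p, m, N_local, events = 50 * N_local,
                                     init = NULL, seed = 1) {
  stopifnot(m >= 0, m <= 1, N_local >= 1)
  local_seed(seed)
  k <- length(p)
  comm <- if (is.null(init)) {
    as.vector(stats::rmultinom(1L, N_local, p))
  } else {
    stopifnot(length(init) == k, sum(init) == N_local)
    as.numeric(init)
  }
  if (m == 1) {  # exact: every individual i.i.d. from p
    comm <- as.vector(stats::rmultinom(1L, N_local, p))
    names(comm) <- names(p)
    return(comm)
  }
  immigrant <- stats::runif(events) < m
  for (e in seq_len(events)) {
    dead <- sample.int(k, 1L, prob = comm)
    comm[dead] <- comm[dead] - 1L
    repl <- if (immigrant[e]) sample.int(k, 1L, prob = p)
    else sample.int(k, 1L, prob = comm)
    comm[repl] <- comm[repl] + 1L
  }
  names(comm) <- names(p)
  comm
}

#' Spike known non-neutral OTUs into a simulated table
#'
#' Creates ground truth for testing selection classification. For an
#' `"above"` spike, the OTU's presence in each sample is re-drawn with
#' probability `min(1, f_pred + delta)`; for `"below"`, with
#' `max(0, f_pred - delta)`. Where presence is granted but the neutral draw
#' produced no reads, a replacement count is drawn from the OTU's
#' conditional (detected) abundance distribution. All other OTUs are
#' untouched.
#'
#' @param table a [count_table] from [simulate_neutral_table()].
#' @param p the metacommunity vector used to generate `table`.
#' @param m,N_local,d generator parameters (`d` defaults to 1 / mean depth).
#' @param spiked data frame with columns `otu`, `direction`, `delta`.
#' @param seed integer RNG seed.
#' @return a [count_table] with the spiked OTUs perturbed.
#' @export
spike_selected_otus <- function(table, p, m, N_local, spiked,
                                d = 1 / mean(library_sizes(table)), seed = 1) {
  if (is.null(spiked) || nrow(spiked) == 0L) return(table)
  if (any(spiked$delta <= 0)) stop("delta must be > 0")
  local_seed(seed)
  cnt <- counts(table)
  depths <- rowSums(cnt)
  for (r in seq_len(nrow(spiked))) {
    i <- spiked$otu[r]
    f_pred <- predict_occurrence_neutral(p[i], N_local, m, d)
    target <- if (spiked$direction[r] == "above")
      min(1, f_pred + spiked$delta[r]) else max(0, f_pred - spiked$delta[r])
    present <- stats::runif(nrow(cnt)) < target
    alpha <- N_local * m * p[i]; beta <- N_local * m * (1 - p[i])
    for (j in seq_len(nrow(cnt))) {
      if (!present[j]) {
        cnt[j, i] <- 0
      } else if (cnt[j, i] == 0) {
        # redraw abundance from the beta truncated to the detected range
        # (x >= 1/depth) by CDF inversion, then convert to reads
        lo <- stats::pbeta(1 / depths[j], alpha, beta)
        u <- stats::runif(1L, min(lo, 1 - 1e-12), 1)
        x <- stats::qbeta(u, alpha, beta)
        cnt[j, i] <- max(floor(depths[j] * x), 1)
      }
    }
  }
  count_table(cnt)
}

#' Simulate a diet metabarcoding table dominated by the host OTU
#'
#' Emulates predator gut-content sequencing: one OTU carrying the host's
#' lineage receives `host_fraction` of every sample's reads (default 0.876,
#' i.e. 12.4% prey reads), and the prey OTUs share the remainder as a
#' neutral community. Removing the host OTU with [remove_host_otu()]
#' recovers the prey-only table.
#'
#' @param config a [simulation_config()]; `n_taxa` counts prey OTUs.
#' @param host_order taxonomic order assigned to the host OTU.
#' @return list: `table` (a [count_table] with the host OTU first when
#'   `host_fraction > 0`), `taxonomy` (host + prey lineages), `p_prey`
#'   (the prey metacommunity vector).
#' @export
simulate_diet_table <- function(config, host_order = "Odonata") {
  p <- sample_metacommunity(config)
  local_seed(config$seed + 1L)
  depths <- round(stats::runif(config$n_samples, config$depth_range[1],
                               config$depth_range[2]))
  host_reads <- round(config$host_fraction * depths)
  prey <- simulate_neutral_table(p, config$m, config$N_local,
                                 config$n_samples, depths - host_reads,
                                 seed = config$seed + 2L,
                                 read_model = config$read_model)
  prey_orders <- c("Diptera", "Lepidoptera", "Hymenoptera", "Coleoptera",
                   "Hemiptera")
  local_seed(config$seed + 3L)
  prey_lin <- sprintf("k__Animalia; p__Arthropoda; c__Insecta; o__%s",
                      sample(prey_orders, config$n_taxa, replace = TRUE))
  if (config$host_fraction == 0) {
    return(list(table = prey,
                taxonomy = taxonomy_map(otu_ids(prey), prey_lin),
                p_prey = p))
  }
  cnt <- cbind(host_otu = host_reads, counts(prey))
  tax <- taxonomy_map(c("host_otu", otu_ids(prey)),
                      c(sprintf("k__Animalia; p__Arthropoda; c__Insecta; o__%s",
                                host_order), prey_lin))
  list(table = count_table(cnt), taxonomy = tax, p_prey = p)
}

#' Simulate a full grouped survey (table + metadata)
#'
#' Convenience wrapper used by the pipeline and tests: draws one
#' metacommunity per group (optionally disjoint), simulates each group's
#' samples, and emits matching metadata with `species` and `location`
#' columns.
#'
#' @param config a [simulation_config()]; `n_samples` is the per-group size.
#' @param groups data frame with columns `species` and `location`, one row
#'   per group.
#' @param disjoint_metacommunities give each group its own independent
#'   metacommunity (default: shared).
#' @return list: `table`, `metadata`, `p` (list of per-group vectors).
#' @export
simulate_survey <- function(config, groups, disjoint_metacommunities = FALSE) {
  tabs <- list(); metas <- list(); ps <- list()
  for (g in seq_len(nrow(groups))) {
    cfg_g <- config
    cfg_g$seed <- config$seed + 1000L * g
    p <- if (disjoint_metacommunities || g == 1L) sample_metacommunity(cfg_g)
    else ps[[1L]]
    local_seed(cfg_g$seed + 1L)
    depths <- round(stats::runif(config$n_samples, config$depth_range[1],
                                 config$depth_range[2]))
    tab <- simulate_neutral_table(p, config$m, config$N_local,
                                  config$n_samples, depths,
                                  seed = cfg_g$seed + 2L,
                                  read_model = config$read_model)
    ids <- sprintf("%s_%s_%02d", groups$species[g], groups$location[g],
                   seq_len(config$n_samples))
    tab <- count_table(counts(tab), sample_ids = ids)
    tabs[[g]] <- counts(tab)
    metas[[g]] <- data.frame(sample_id = ids,
                             species = groups$species[g],
                             location = groups$location[g],
                             stringsAsFactors = FALSE)
    ps[[g]] <- p
  }
  list(table = count_table(do.call(rbind, tabs)),
       metadata = do.call(rbind, metas), p = ps)
}
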