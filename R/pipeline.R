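#' Pipeline configuration
#'
#' Validated bag of options for [run_pipeline()]: input paths, filter mode
#' and threshold, distance metric, design formula, CI level, grouping
#' factor, seed, and output directory.
#'
#' @param table_path path to the OTU table (classic TSV or BIOM-JSON).
#' @param metadata_path path to the sample metadata (TSV/CSV).
#' @param tree_path optional Newick tree (enables Faith's PD).
#' @param out_dir output directory (created if absent).
#' @param filter `"pruned"`, `"dominant"`, `"minreads"` or `"none"`.
#' @param filter_threshold threshold for the chosen filter (`NULL` =
#'   the filter's default).
#' @param distance distance metric for ordination/PERMANOVA.
#' @param design PERMANOVA design, e.g.
#'   `"species + location + species:location"`; `NULL` skips PERMANOVA.
#' @param cap_groups metadata column for CAP classification; `NULL` skips.
#' @param group_by metadata column(s) for per-group neutral fits.
#' @param ci_level 95 or 99.
#' @param nperm permutations for PERMANOVA.
#' @param seed integer seed used for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(table_path, metadata_path, tree_path = NULL,
                            out_dir = "ncm_out", filter = "pruned",
                            filter_threshold = NULL,
                            distance = "bray_curtis", design = NULL,
                            cap_groups = NULL, group_by = "location",
                            ci_level = 99, nperm = 10000, seed = 1) {
  stopifnot(filter %in% c("pruned", "dominant", "minreads", "none"),
            ci_level %in% c(95, 99), seed == round(seed))
  for (p in c(table_path, metadata_path, tree_path))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  structure(as.list(environment()), class = "pipeline_config")
}

log_line <- function(log, ...) c(log, paste0(format(Sys.time(), "%H:%M:%S "),
                                             sprintf(...)))

#' Run the full community-assembly pipeline
#'
#' Orchestrates the stages in analysis order: read inputs, apply the OTU
#' filter, compute alpha diversity and the distance matrix, PERMANOVA and
#' CAP when a design/grouping is configured, then per-group neutral-model
#' fits with OTU classification. All outputs are plain TSV/JSON under
#' `config$out_dir`, and a log sufficient for exact replay (package
#' version, config, seed) is written alongside. Optional stages that
#' cannot run (e.g. no tree for Faith's PD) are logged and skipped, not
#' fatal; missing mandatory inputs abort with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the in-memory results (`table`, `alpha`,
#'   `dist`, `permanova`, `cap`, `neutral`, `log`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  log <- log_line(log, "ncmtools %s | seed %d",
                  as.character(utils::packageVersion("ncmtools")), config$seed)
  log <- log_line(log, "config: %s", jsonlite::toJSON(
    config[!vapply(config, is.null, TRUE)], auto_unbox = TRUE))

  rd <- read_count_table(config$table_path)
  table <- rd$table
  metadata <- read_metadata(config$metadata_path)
  joined <- join_metadata(table, metadata)
  table <- joined$table; metadata <- joined$metadata
  log <- log_line(log, "read: %d samples x %d OTUs", n_samples(table),
                  n_otus(table))

  if (config$filter != "none") {
    fr <- switch(config$filter,
      pruned = if (is.null(config$filter_threshold)) filter_pruned(table)
               else filter_pruned(table, config$filter_threshold),
      dominant = if (is.null(config$filter_threshold)) filter_dominant(table)
                 else filter_dominant(table, config$filter_threshold),
      minreads = if (is.null(config$filter_threshold)) filter_min_reads(table)
                 else filter_min_reads(table, config$filter_threshold))
    table <- fr$table
    log <- log_line(log, "filter %s: %d -> %d OTUs", config$filter,
                    fr$report$otus_before, fr$report$otus_after)
    jsonlite::write_json(fr$report[c("filter", "otus_before", "otus_after",
                                     "threshold", "removed")],
                         file.path(config$out_dir, "filter_report.json"),
                         auto_unbox = TRUE)
    write_count_table(table, file.path(config$out_dir, "table.filtered.tsv"))
  }

  alpha <- data.frame(sample_id = sample_ids(table),
                      richness = apply(counts(table), 1L, richness),
                      shannon = apply(counts(table), 1L, shannon))
  if (!is.null(config$tree_path)) {
    tree <- read_newick(config$tree_path)
    pd_ok <- all(otu_ids(table) %in% tree$tip.label)
    if (pd_ok) {
      alpha$faith_pd <- apply(counts(table), 1L, function(x)
        faith_pd(names(x)[x > 0], tree))
    } else log <- log_line(log, "skip faith_pd: tree is missing table OTUs")
  } else log <- log_line(log, "skip faith_pd: no tree supplied")
  utils::write.table(alpha, file.path(config$out_dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  d <- distance_matrix(table, metric = config$distance)
  utils::write.table(cbind(sample_id = rownames(d), as.data.frame(d)),
                     file.path(config$out_dir, "distance_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- log_line(log, "distance: %s", config$distance)

  perm <- NULL
  if (!is.null(config$design)) {
    perm <- permanova(d, metadata, config$design, nperm = config$nperm,
                      seed = config$seed)
    utils::write.table(perm, file.path(config$out_dir, "permanova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log <- log_line(log, "permanova: %d permutations", config$nperm)
  }

  cap <- NULL
  if (!is.null(config$cap_groups)) {
    groups <- metadata[[config$cap_groups]]
    nz <- near_zero_variance_filter(relative_abundance(table, "per_sample"))
    if (length(nz$removed))
      log <- log_line(log, "near-zero variance: removed %d OTU column(s)",
                      length(nz$removed))
    cap <- tryCatch(cap_discrim(d, groups, seed = config$seed),
                    error = function(e) {
                      log <<- log_line(log, "skip cap: %s", conditionMessage(e))
                      NULL
                    })
    if (!is.null(cap))
      jsonlite::write_json(list(n_axes = cap$n_axes, success = cap$success,
                                group_success = as.list(cap$group_success),
                                p_value = cap$p_value),
                           file.path(config$out_dir, "cap.json"),
                           auto_unbox = TRUE)
  }

  neutral <- tryCatch(
    fit_per_group(table, metadata, config$group_by, level = config$ci_level),
    error = function(e) {
      log <<- log_line(log, "skip neutral fit: %s", conditionMessage(e))
      NULL
    })
  if (is.null(neutral)) {
    writeLines(log, file.path(config$out_dir, "pipeline.log"))
    return(invisible(list(table = table, alpha = alpha, dist = d,
                          permanova = perm, cap = cap, neutral = NULL,
                          log = log)))
  }
  summary_json <- list(
    level = config$ci_level,
    neutral_fractions = as.list(neutral$neutral_fractions),
    mean_neutral_fraction = neutral$mean_neutral_fraction,
    sd_neutral_fraction = neutral$sd_neutral_fraction,
    groups = lapply(neutral$fits, function(x)
      list(m = x$fit$m, se_m = x$fit$se_m, N = x$fit$N, d = x$fit$d,
           r2 = x$fit$r2, aic = x$fit$aic, r2_binomial = x$fit$r2_binomial,
           aic_binomial = x$fit$aic_binomial)))
  jsonlite::write_json(summary_json,
                       file.path(config$out_dir, "neutral_fit.json"),
                       auto_unbox = TRUE, digits = NA)
  for (g in names(neutral$fits)) {
    x <- neutral$fits[[g]]
    if (is.null(x$classification)) next
    ids <- names(x$classification$class)
    per_otu <- data.frame(otu_id = ids,
                          p = x$summary$p[ids],
                          f_obs = x$summary$f_obs[ids],
                          f_pred = x$fit$f_pred[ids],
                          ci_lo = x$classification$lower,
                          ci_hi = x$classification$upper,
                          class = as.character(x$classification$class))
    utils::write.table(per_otu,
                       file.path(config$out_dir,
                                 paste0("neutral_", gsub("[^A-Za-z0-9_-]", "_", g),
                                        ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log <- log_line(log, "neutral fit: %d group(s), mean neutral fraction %.3f",
                  length(neutral$fits), neutral$mean_neutral_fraction)
  writeLines(log, file.path(config$out_dir, "pipeline.log"))
  invisible(list(table = table, alpha = alpha, dist = d, permanova = perm,
                 cap = cap, neutral = neutral, log = log))
}
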