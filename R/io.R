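#' Read an OTU count table from classic TSV or BIOM-JSON
#'
#' Supports the two plain-text dialects in common use for OTU tables:
#'
#' * `classic-tsv`: the QIIME "classic" format. OTUs are rows, samples are
#'   columns. Comment lines starting with `#` before the header are skipped,
#'   except the header itself, whose first cell may be `#OTU ID`. An optional
#'   trailing `taxonomy` column holds GreenGenes-style lineage strings.
#' * `biom-json`: BIOM format version 1.0 (JSON object with `rows`,
#'   `columns`, `data`, `matrix_type` dense or sparse). Row metadata
#'   `taxonomy` entries, when present, are parsed into the taxonomy map.
#'
#' Output orientation is always normalized to samples x OTUs.
#'
#' @param path file path.
#' @param format `"classic-tsv"`, `"biom-json"`, or `"auto"` (sniffs a
#'   leading `{` for JSON).
#' @param orientation for classic TSV only: `"otus_as_rows"` (default,
#'   the classic convention) or `"samples_as_rows"` for pre-transposed files.
#' @return a list with elements `table` (a [count_table]) and `taxonomy`
#'   (a taxonomy data frame as from [taxonomy_map()], or `NULL`).
#' @export
read_count_table <- function(path, format = c("auto", "classic-tsv", "biom-json"),
                             orientation = c("otus_as_rows", "samples_as_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readChar(path, nchars = 1L)
    format <- if (identical(first, "{")) "biom-json" else "classic-tsv"
  }
  if (format == "biom-json") read_biom_json(path) else
    read_classic_tsv(path, orientation)
}

read_classic_tsv <- function(path, orientation = "otus_as_rows") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("parse error: need a header line and at least one data row in ", path)
  # skip leading comment lines; the last #-line before data is the header
  is_comment <- grepl("^#", lines)
  if (all(is_comment)) stop("parse error: no data rows in ", path)
  first_data <- which(!is_comment)[1L]
  header_idx <- if (first_data == 1L) 1L else first_data - 1L
  header <- strsplit(sub("^#", "", lines[header_idx]), "\t", fixed = TRUE)[[1L]]
  body <- lines[seq.int(header_idx + 1L, length(lines))]
  cells <- strsplit(body, "\t", fixed = TRUE)
  ncol_expect <- length(header)
  tax_header <- tolower(header[length(header)]) %in%
    c("taxonomy", "consensus lineage", "consensuslineage")
  if (tax_header) {
    # an empty trailing taxonomy field is dropped by strsplit; restore it
    cells <- lapply(cells, function(x)
      if (length(x) == ncol_expect - 1L) c(x, "") else x)
  }
  bad <- which(vapply(cells, length, 1L) != ncol_expect)
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: expected %d fields, found %d",
                 header_idx + bad[1L], path, ncol_expect, length(cells[[bad[1L]]])))
  tab <- do.call(rbind, cells)
  row_ids <- tab[, 1L]
  col_ids <- header[-1L]
  has_tax <- length(col_ids) > 0L &&
    tolower(col_ids[length(col_ids)]) %in% c("taxonomy", "consensus lineage", "consensuslineage")
  taxonomy <- NULL
  if (has_tax) {
    taxonomy <- taxonomy_map(row_ids, tab[, ncol_expect])
    tab <- tab[, -ncol_expect, drop = FALSE]
    col_ids <- col_ids[-length(col_ids)]
  }
  if (length(col_ids) == 0L) stop("parse error: no count columns in ", path)
  vals <- suppressWarnings(matrix(as.numeric(tab[, -1L, drop = FALSE]),
                                  nrow = nrow(tab)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("validation error: non-numeric count at row '%s', column '%s'",
                 row_ids[bad[1L]], col_ids[bad[2L]]))
  }
  dimnames(vals) <- list(row_ids, col_ids)
  if (orientation == "otus_as_rows") vals <- t(vals)
  list(table = count_table(vals), taxonomy = taxonomy)
}

read_biom_json <- function(path) {
  b <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (k in c("rows", "columns", "data", "matrix_type", "shape"))
    if (is.null(b[[k]])) stop("parse error: BIOM-JSON missing key '", k, "' in ", path)
  otus <- vapply(b$rows, function(r) as.character(r$id), "")
  samples <- vapply(b$columns, function(r) as.character(r$id), "")
  nr <- as.integer(b$shape[[1L]]); nc <- as.integer(b$shape[[2L]])
  if (length(otus) != nr || length(samples) != nc)
    stop("validation error: BIOM shape does not match rows/columns lengths")
  m <- matrix(0, nrow = nr, ncol = nc, dimnames = list(otus, samples))
  if (identical(b$matrix_type, "dense")) {
    for (i in seq_len(nr)) m[i, ] <- as.numeric(unlist(b$data[[i]]))
  } else if (identical(b$matrix_type, "sparse")) {
    for (trip in b$data) {
      trip <- as.numeric(unlist(trip))
      m[trip[1L] + 1L, trip[2L] + 1L] <- trip[3L]
    }
  } else stop("parse error: unknown matrix_type '", b$matrix_type, "'")
  taxonomy <- NULL
  lineages <- vapply(b$rows, function(r) {
    tx <- r$metadata$taxonomy
    if (is.null(tx)) NA_character_ else paste(unlist(tx), collapse = "; ")
  }, "")
  if (any(!is.na(lineages)))
    taxonomy <- taxonomy_map(otus, ifelse(is.na(lineages), "", lineages))
  list(table = count_table(t(m)), taxonomy = taxonomy)
}

#' Write a count table in classic TSV format
#'
#' @param x a [count_table].
#' @param path output file path.
#' @param taxonomy optional taxonomy data frame ([taxonomy_map()]); written
#'   as a trailing `taxonomy` column of GreenGenes-style lineage strings.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, taxonomy = NULL) {
  m <- t(x$counts)  # classic convention: OTUs as rows
  header <- paste(c("#OTU ID", colnames(m)), collapse = "\t")
  body_mat <- format(m, scientific = FALSE, trim = TRUE)
  rows <- apply(cbind(rownames(m), body_mat), 1L, paste, collapse = "\t")
  if (!is.null(taxonomy)) {
    header <- paste(header, "taxonomy", sep = "\t")
    lin <- format_lineage(taxonomy)[match(rownames(m), taxonomy$otu_id)]
    lin[is.na(lin)] <- ""
    rows <- paste(rows, lin, sep = "\t")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

CANONICAL_RANKS <- c("kingdom", "phylum", "class", "order",
                     "family", "genus", "species")
RANK_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Parse GreenGenes-style lineage strings into a taxonomy map
#'
#' A taxonomy map relates each OTU to its seven-rank lineage
#' (kingdom...species). Unassigned ranks are stored as empty strings.
#'
#' @param otu_id character vector of OTU identifiers (must be unique).
#' @param lineage character vector of lineage strings, e.g.
#'   `"k__Bacteria; p__Proteobacteria"`. Rank prefixes (`k__` etc.) are
#'   honoured when present; otherwise fields are assigned to ranks in order.
#' @return a data frame with columns `otu_id` and the seven canonical ranks.
#' @examples
#' taxonomy_map("otu1", "k__Bacteria; p__Proteobacteria")
#' @export
taxonomy_map <- function(otu_id, lineage) {
  if (anyDuplicated(otu_id)) stop("duplicate OTU identifiers in taxonomy map")
  stopifnot(length(otu_id) == length(lineage))
  out <- matrix("", nrow = length(otu_id), ncol = 7L,
                dimnames = list(NULL, CANONICAL_RANKS))
  for (i in seq_along(lineage)) {
    if (is.na(lineage[i]) || !nzchar(lineage[i])) next
    parts <- trimws(strsplit(lineage[i], ";", fixed = TRUE)[[1L]])
    for (j in seq_along(parts)) {
      pfx <- substr(parts[j], 1L, 3L)
      k <- match(pfx, RANK_PREFIXES)
      name <- if (!is.na(k)) substring(parts[j], 4L) else parts[j]
      if (is.na(k)) k <- j
      if (k <= 7L) out[i, k] <- name
    }
  }
  data.frame(otu_id = as.character(otu_id), out,
             stringsAsFactors = FALSE, check.names = FALSE)
}

format_lineage <- function(taxonomy) {
  apply(taxonomy[, CANONICAL_RANKS, drop = FALSE], 1L, function(r)
    paste0(RANK_PREFIXES, r, collapse = "; "))
}

#' Read per-sample metadata
#'
#' Tab- or comma-separated file with a header containing `sample_id`; one
#' record per sample. Extra columns are preserved as factors/covariates.
#'
#' @param path file path; the separator is sniffed from the header line
#'   (tab wins over comma).
#' @return a data frame keyed by a unique `sample_id` column.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  names(md)[1L] <- sub("^#", "", names(md)[1L])
  if (!"sample_id" %in% names(md))
    stop("metadata is missing a 'sample_id' column")
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  md
}

#' Align a count table and metadata on shared samples
#'
#' Joins by identifier and reports the samples present on only one side.
#'
#' @param table a [count_table].
#' @param metadata data frame from [read_metadata()].
#' @return list with `table` and `metadata` restricted to the shared samples
#'   (metadata reordered to the table's sample order), plus
#'   `dropped_from_table` and `dropped_from_metadata` identifier vectors.
#' @export
join_metadata <- function(table, metadata) {
  shared <- intersect(sample_ids(table), metadata$sample_id)
  if (length(shared) == 0L) stop("no samples shared between table and metadata")
  dropped_t <- setdiff(sample_ids(table), shared)
  dropped_m <- setdiff(metadata$sample_id, shared)
  if (length(dropped_t) || length(dropped_m))
    warning(sprintf("dropping %d table sample(s) and %d metadata row(s) not present on both sides",
                    length(dropped_t), length(dropped_m)))
  shared <- sample_ids(table)[sample_ids(table) %in% shared]
  list(table = subset_table(table, samples = shared),
       metadata = metadata[match(shared, metadata$sample_id), , drop = FALSE],
       dropped_from_table = dropped_t,
       dropped_from_metadata = dropped_m)
}

#' Read and write rooted trees in Newick format
#'
#' Thin wrappers over `ape` with the validation this package needs:
#' unique leaf names and non-negative branch lengths. Missing branch lengths
#' are treated as zero with a warning.
#'
#' @param path file path.
#' @return `read_newick`: an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!grepl("(", txt, fixed = TRUE)) {
    # single-leaf tree, e.g. "A:1;" — ape cannot parse it; build directly
    mt <- regmatches(txt, regexec("^\\s*([^:;,()]+)(:([0-9.eE+-]+))?;", txt))[[1L]]
    if (length(mt) == 0L) stop("Newick parse error in ", path)
    len <- if (nzchar(mt[4L])) as.numeric(mt[4L]) else {
      warning("tree has no branch lengths; treating all as 0")
      0
    }
    tree <- structure(list(edge = matrix(c(2L, 1L), 1L),
                           tip.label = trimws(mt[2L]),
                           edge.length = len, Nnode = 1L),
                      class = "phylo", order = "cladewise")
    return(tree)
  }
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path, ": ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in ", path)
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names in ", path)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths treated as 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths in ", path)
  tree
}

#' @rdname read_newick
#' @param tree an `ape::phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
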