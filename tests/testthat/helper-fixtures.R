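# Shared fixture builders. Everything is generated in code; no data files.

toy_table <- function() {
  count_table(matrix(c(5, 0, 3,
                       2, 1, 4),
                     nrow = 2, byrow = TRUE,
                     dimnames = list(c("s1", "s2"), c("otuA", "otuB", "otuC"))))
}

# classic-tsv fixture written to a temp file; returns the path
write_classic_fixture <- function(taxonomy_col = FALSE) {
  path <- tempfile(fileext = ".tsv")
  lines <- c("# Constructed from biom file",
             paste(c("#OTU ID", "s1", "s2"), collapse = "\t"),
             paste(c("otu1", "5", "2"), collapse = "\t"),
             paste(c("otu2", "0", "1"), collapse = "\t"),
             paste(c("otu3", "3", "4"), collapse = "\t"))
  if (taxonomy_col) {
    lines[2] <- paste(lines[2], "taxonomy", sep = "\t")
    tax <- c("k__Bacteria; p__Proteobacteria",
             "k__Bacteria; p__Firmicutes; c__Bacilli",
             "")
    lines[3:5] <- paste(lines[3:5], tax, sep = "\t")
  }
  writeLines(lines, path)
  path
}

write_biom_fixture <- function(sparse = FALSE) {
  path <- tempfile(fileext = ".biom")
  data_block <- if (sparse)
    '[[0,0,5],[0,1,2],[1,1,1],[2,0,3],[2,1,4]]'
  else '[[5,2],[0,1],[3,4]]'
  json <- sprintf('{
    "id": "fixture", "format": "Biological Observation Matrix 1.0.0",
    "format_url": "http://biom-format.org", "type": "OTU table",
    "generated_by": "ncmtools-test", "date": "2026-01-01T00:00:00",
    "matrix_type": "%s", "matrix_element_type": "int", "shape": [3, 2],
    "rows": [{"id": "otu1", "metadata": {"taxonomy": ["k__Bacteria", "p__Proteobacteria"]}},
             {"id": "otu2", "metadata": null},
             {"id": "otu3", "metadata": null}],
    "columns": [{"id": "s1", "metadata": null}, {"id": "s2", "metadata": null}],
    "data": %s}', if (sparse) "sparse" else "dense", data_block)
  writeLines(json, path)
  path
}

write_metadata_fixture <- function(sep = "\t", ids = c("s1", "s2")) {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  writeLines(c(paste(c("sample_id", "species", "location", "note"),
                     collapse = sep),
               vapply(seq_along(ids), function(i)
                 paste(c(ids[i], "spA", "locX", paste0("n", i)),
                       collapse = sep), "")), path)
  path
}

demo_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# small neutral world used by several suites
demo_neutral <- function(seed = 42, n_taxa = 120, n_samples = 25,
                         N = 20000, m = 0.15) {
  p <- sample_metacommunity(simulation_config(n_taxa = n_taxa, seed = seed))
  tab <- simulate_neutral_table(p, m, N, n_samples, N, seed = seed + 1)
  list(p = p, table = tab, N = N, m = m)
}
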