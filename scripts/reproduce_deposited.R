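#!/usr/bin/env Rscript
# Reproduction of the published survey numbers from the deposited OTU
# tables. The deposited inputs are NOT bundled (they require a download):
#
#   gut OTU table (unpruned, classic TSV or BIOM-JSON):
#     https://doi.org/10.6084/m9.figshare.9632084
#   per-sample metadata with columns sample_id, species, location
#     (assembled from the study's Supplementary Table S1)
#
# Usage:
#   Rscript scripts/reproduce_deposited.R --table gut.biom --metadata meta.tsv
#
# Prints, next to the published values: the three filter sizes
# (pruned 576 / dominant 59 / minimally pruned 2,599 OTUs), mean per-sample
# richness (188), per-location neutral fractions at the 99% level
# (mean ~72%, Bordubi 83%, Nagpur 63%), PERMANOVA R2 for location (~0.26)
# and species (~0.09) on the dominant community, and the number of OTUs
# shared by all host species (206).

suppressPackageStartupMessages({
  library(ncmtools)
  library(optparse)
})

opt <- parse_args(OptionParser(option_list = list(
  make_option("--table", type = "character"),
  make_option("--metadata", type = "character"),
  make_option("--nperm", type = "integer", default = 10000),
  make_option("--seed", type = "integer", default = 1))))

rd <- read_count_table(opt$table)
md <- read_metadata(opt$metadata)
j <- join_metadata(rd$table, md)
tab <- j$table; md <- j$metadata

show <- function(label, value, published)
  cat(sprintf("  %-38s %-12s (published: %s)\n", label,
              format(value), published))

cat("OTU filters (unpruned input:", n_otus(tab), "OTUs)\n")
pr <- filter_pruned(tab)
show("pruned (>= 0.005% global)", pr$report$otus_after, "576")
dom <- filter_dominant(tab)
show("dominant (>= 5% in a sample)", dom$report$otus_after, "59")
mp <- filter_min_reads(tab)
show("minimally pruned (>= 20 reads)", mp$report$otus_after, "2599")

cat("Alpha diversity (pruned community)\n")
show("mean per-sample richness",
     round(mean(apply(counts(pr$table), 1, richness))), "188")

cat("Shared OTUs (pruned community)\n")
sh <- shared_otu_counts(pr$table, md$species)
show("OTUs in all host species", sh$shared_by_all, "206")

cat("PERMANOVA, Bray-Curtis, dominant community\n")
d <- distance_matrix(dom$table, "bray_curtis")
pm <- permanova(d, md, "species + location + species:location",
                nperm = opt$nperm, seed = opt$seed)
show("R2 species", round(pm$R2[1], 2), "0.09")
show("R2 location", round(pm$R2[2], 2), "0.26")

cat("Sloan neutral model per location, 99% CI (pruned community)\n")
gf <- fit_per_group(pr$table, md, "location", level = 99)
for (g in names(gf$fits))
  cat(sprintf("  %-38s %.0f%%\n", paste0("neutral fraction, ", g),
              100 * gf$neutral_fractions[g]))
show("mean neutral fraction",
     sprintf("%.0f%%", 100 * gf$mean_neutral_fraction), "72%")
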