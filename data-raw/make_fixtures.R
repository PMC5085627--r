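# Regenerates the bundled plain-text fixtures under inst/extdata from the
# package's own code.  Run from the package root:
#   Rscript data-raw/make_fixtures.R

if (requireNamespace("mitovar", quietly = TRUE)) {
  library(mitovar)
} else {
  suppressMessages({library(Biostrings); library(tibble)})
  for (f in list.files("R", full.names = TRUE)) source(f)
}

dir <- "inst/extdata"
if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

write_reference_fixtures(dir)

wt <- function(df, file) utils::write.table(
  df, file.path(dir, file), sep = "\t", quote = FALSE, row.names = FALSE)

# tRNA stem pairs used by the RNA-disruption annotator
wt(tibble::tribble(
  ~gene, ~pos1, ~pos2,
  "tRNA-Val", 1629L, 1650L,
  "tRNA-Ile", 4272L, 4310L,
  "tRNA-Tyr", 5845L, 5881L
), "pairing_maps.tsv")

# catalog snapshot: previously reported variants (the "reported" entries
# of the bundled example tables plus well-known disease variants)
prof <- predictor_profile_fixture()
trunc <- truncating_mutation_fixture()
wt(tibble::tibble(
  label = c(prof$label[prof$reported], trunc$label[trunc$reported],
            "A3243G", "G3244A", "A5514G", "T5628C"),
  status = "reported"
), "variant_catalog.tsv")

# haplogroup tree
tree <- mini_haplo_tree()
wt(tibble::tibble(
  node = tree$node, parent = tree$parent,
  defining_variants = vapply(tree$variants, paste, character(1),
                             collapse = ",")
), "haplo_tree.tsv")

wt(novel_variant_fixture(), "novel_variants.tsv")
wt(truncating_mutation_fixture(), "truncating_mutations.tsv")
wt(predictor_profile_fixture(), "predictor_profiles.tsv")

# small worked-example Ct table (two subjects, triplicates)
utils::write.csv(tibble::tribble(
  ~sample_id, ~tissue, ~target, ~ct1, ~ct2, ~ct3,
  "case01.tumor", "tumor", "mt", 15.81, 15.92, 15.88,
  "case01.tumor", "tumor", "nuclear", 23.95, 24.05, 23.99,
  "case01.normal", "normal", "mt", 17.42, 17.36, 17.45,
  "case01.normal", "normal", "nuclear", 23.61, 23.72, 23.66,
  "case02.tumor", "tumor", "mt", 16.55, 16.49, 16.60,
  "case02.tumor", "tumor", "nuclear", 24.12, 24.03, 24.08,
  "case02.normal", "normal", "mt", 16.95, 17.02, 16.99,
  "case02.normal", "normal", "nuclear", 23.88, 23.95, 23.91
), file.path(dir, "ct_example.csv"), row.names = FALSE, quote = FALSE)

cat("fixtures written to", dir, "\n")
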