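#!/usr/bin/env Rscript
# Full-data ABCC6 analysis. Requires inputs that are not shipped with
# the package:
#   models/state1.pdb, models/state2.pdb, models/state3.pdb
#       -- the deposited three-state ABCC6 models (ModelArchive
#          accessions ma-s37e8, ma-xktqt, ma-kyp1k), single chain.
#   data/clinvar.tsv  -- ClinVar missense export (columns: hgvs_p,
#                        significance, phenotype)
#   data/gnomad.tsv   -- gnomAD missense export (columns: hgvs_p,
#                        allele_frequency, allele_count)
#   data/stability.tsv -- FoldX per-state ddG table (columns: variant,
#                        ddg_state1..3)
#
# Usage: Rscript scripts/full_data_run.R <input_dir> <output_dir> [seed]
#
# The run reports, among others: the VUS partition size, the number of
# categorized VUS, hotspot sizes and their residue sharing, the derived
# burden thresholds, reclassification counts and one-line-away counts.

suppressPackageStartupMessages(library(mechvar))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 2) stop("usage: full_data_run.R <input_dir> <out_dir> [seed]")
indir <- argv[1]; outdir <- argv[2]
seed <- if (length(argv) >= 3) as.integer(argv[3]) else 1L

cfg <- run_config(
  models = file.path(indir, "models", paste0("state", 1:3, ".pdb")),
  clinvar = file.path(indir, "data", "clinvar.tsv"),
  gnomad = file.path(indir, "data", "gnomad.tsv"),
  stability = file.path(indir, "data", "stability.tsv"),
  annotation = system.file("extdata", "abcc6_annotation.yaml",
                           package = "mechvar"),
  out_dir = outdir, n_permutations = 10000, alpha = 0.0001, seed = seed)

res <- run_full(cfg)

cat("derived burden thresholds:\n")
for (h in res$hotspots)
  cat(sprintf("  state %d, %s: min_burden %s, %d residues\n",
              h$state_id, h$weighting, format(h$min_burden),
              length(h$members)))
ov <- hotspot_union_overlap(res$hotspots)
cat(sprintf("hotspot union %d residues, %d shared across analyses (%.0f%%)\n",
            ov$union_size, ov$shared_count, 100 * ov$shared_fraction))
cat(jsonlite::toJSON(res$summary, auto_unbox = TRUE, pretty = TRUE), "\n")
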