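#!/usr/bin/env Rscript

# Thin command-line wrapper over geaoffset::run_pipeline().
#
# Usage: Rscript scripts/run_pipeline.R --config cfg.yaml --out out_dir [--seed 1]

suppressMessages({
  library(optparse)
  library(geaoffset)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character"),
  make_option("--out", type = "character", default = "pipeline_out"),
  make_option("--seed", type = "integer", default = NULL)
)))

if (is.null(opts$config)) stop("--config is required")
cfg <- yaml::read_yaml(opts$config)
if (!is.null(opts$seed)) cfg$seed <- opts$seed
summary <- run_pipeline(cfg, opts$out)
cat(sprintf("pipeline complete: %d loci, %d PAV, outputs in %s\n",
            summary$n_loci, summary$outlier_counts$pav, opts$out))
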