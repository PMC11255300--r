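#!/usr/bin/env Rscript

# Thin command-line wrapper over replifoci::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R [--config cfg.yaml] [--seed 1] \
#       [--outdir out] [--stages simulate,track,analyze,report]

suppressPackageStartupMessages({
  library(optparse)
  library(replifoci)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML pipeline config (defaults to the built-in config)"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the config seed"),
  make_option("--outdir", type = "character", default = "pipeline_out"),
  make_option("--stages", type = "character",
              default = "simulate,track,analyze,report",
              help = "comma-separated subset of simulate,track,analyze,report")
)))

config <- if (is.null(opts$config)) default_config() else
  read_pipeline_config(opts$config)
stages <- strsplit(opts$stages, ",")[[1]]

summary_tbl <- run_pipeline(config, outdir = opts$outdir, stages = stages,
                            seed = opts$seed)
if (!is.null(summary_tbl)) {
  print(as.data.frame(summary_tbl), row.names = FALSE)
}
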