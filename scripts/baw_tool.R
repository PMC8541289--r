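#!/usr/bin/env Rscript
# Thin command-line wrapper over acoustofocus::run_pipeline().
#
#   Rscript scripts/baw_tool.R <design|synth|estimate|simulate|streaming>
#       [--config cfg.yaml] [--out dir] [--input trajectories.csv]
#       [--seed N] [--flow-rate UL_MIN] [--eac J_M3] [--vpp V] [--streaming]

suppressPackageStartupMessages({
  library(acoustofocus)
  library(optparse)
})

parser <- OptionParser(
  usage = "%prog <design|synth|estimate|simulate|streaming> [options]",
  option_list = list(
    make_option("--config", type = "character", default = NULL,
                help = "YAML/JSON configuration file"),
    make_option("--out", type = "character", default = "baw_out",
                help = "output directory [default %default]"),
    make_option("--input", type = "character", default = NULL,
                help = "trajectory CSV (estimate)"),
    make_option("--seed", type = "integer", default = NULL,
                help = "RNG seed override"),
    make_option("--flow-rate", type = "double", default = NULL, dest = "flow",
                help = "flow rate override (uL/min)"),
    make_option("--eac", type = "double", default = NULL,
                help = "acoustic energy density override (J/m^3)"),
    make_option("--vpp", type = "double", default = NULL,
                help = "drive voltage override (V peak-to-peak)"),
    make_option("--streaming", action = "store_true", default = FALSE,
                help = "enable streaming drag in the simulator")
  ))
parsed <- parse_args2(parser)
if (length(parsed$args) != 1) {
  print_help(parser); quit(status = 2)
}

cfg <- read_run_config(parsed$options$config)
if (!is.null(parsed$options$seed)) cfg$simulation$seed <- parsed$options$seed
if (!is.null(parsed$options$flow)) cfg$simulation$flow_rate_ul_min <- parsed$options$flow
if (!is.null(parsed$options$eac)) cfg$drive$Eac_j_m3 <- parsed$options$eac
if (!is.null(parsed$options$vpp)) cfg$drive$Vpp_v <- parsed$options$vpp
if (parsed$options$streaming) cfg$simulation$streaming <- TRUE

report <- run_pipeline(cfg, parsed$args, out_dir = parsed$options$out,
                       input = parsed$options$input)
cat(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                     force = TRUE), "\n")
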