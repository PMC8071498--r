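#!/usr/bin/env Rscript
# Stage 2 — build the saturation-concentration calibration.
#
# Renders the six-point standard series (20-120 uM), pushes each image
# through segmentation, red-to-magenta tint and mean-saturation
# measurement, fits the calibration line and persists it as JSON.

suppressMessages({
  library(optparse)
  library(argmark)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out-dir", type = "character", default = "results",
              dest = "out_dir"),
  make_option("--config", type = "character", default = NULL)
)))

rc <- read_run_config(opts$config)
dir.create(opts$out_dir, recursive = TRUE, showWarnings = FALSE)

std <- generate_standard_series(rc$model, rc$standards, seed = opts$seed)
cal <- calibrate_from_images(std)
print(cal)
cat(sprintf("standards %s uM -> saturations %s %%\n",
            paste(cal$standards$concentration, collapse = ", "),
            paste(sprintf("%.1f", cal$standards$mean_saturation), collapse = ", ")))

write_calibration(cal, file.path(opts$out_dir, "calibration.json"))
write.csv(cal$standards, file.path(opts$out_dir, "calibration_standards.csv"),
          row.names = FALSE)
cat("wrote", file.path(opts$out_dir, "calibration.json"), "\n")
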