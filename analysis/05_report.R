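#!/usr/bin/env Rscript
# End-to-end reduced pipeline run plus the figure-style report panels
# (Zp/Zc scatter with decision boundaries, label fractions per kind, STA
# contrast-index distributions, LN transition bars).

library(patterncell)

cfg <- default_config("smoke", seed = 1)
bundle <- run_pipeline(cfg, out_dir = "results/pipeline")
make_report(bundle, out_dir = "results/figures")
message("summary: results/pipeline/summary.json; figures: results/figures/")
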