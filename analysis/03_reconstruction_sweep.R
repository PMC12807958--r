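#!/usr/bin/env Rscript
# The main experiment: the full desk-scale sweep over acceleration and
# regularization, two repeats in each of two sessions. Writes the tidy
# qc/ssim/morph/agreement tables under results/03_sweep/.
# Expect roughly 15 minutes on one CPU.

library(csmprage)

cf <- sweep_config(base_seed = 1)
t0 <- proc.time()
res <- run_sweep(cf, out_dir = "results/03_sweep", verbose = TRUE)
cat(sprintf("sweep finished in %.1f min: %d images evaluated\n",
            (proc.time() - t0)[3] / 60, nrow(res$qc)))
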