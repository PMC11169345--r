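#!/usr/bin/env Rscript
# Resolution assessment on synthetic 200-nm-bead stacks: detection by PSF
# template correlation, per-axis Gaussian FWHM from 10-slice MIPs, and the
# per-axial-segment summary.

suppressPackageStartupMessages(library(rflsm))
dir.create("results", showWarnings = FALSE)

res <- characterize_bead_resolution(seed = 101,
                                    fwhm_nm = c(x = 570, y = 666, z = 924),
                                    n_beads = 20)
write.csv(res$measurements, "results/bead_fwhm_measurements.csv",
          row.names = FALSE)
cat(sprintf("%d beads measured (ground truth X/Y/Z = 570/666/924 nm):\n",
            res$n_used))
cat(sprintf("  FWHM_x = %.0f +/- %.0f nm\n", res$mean_fwhm_nm["x"],
            res$sd_fwhm_nm["x"]))
cat(sprintf("  FWHM_y = %.0f +/- %.0f nm\n", res$mean_fwhm_nm["y"],
            res$sd_fwhm_nm["y"]))
cat(sprintf("  FWHM_z = %.0f +/- %.0f nm\n", res$mean_fwhm_nm["z"],
            res$sd_fwhm_nm["z"]))

seg <- summarize_resolution(res$measurements, segment_um = 5)
write.csv(seg$segments, "results/resolution_by_segment.csv",
          row.names = FALSE)
cat("Per-5-um-segment summary written to results/resolution_by_segment.csv\n")
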