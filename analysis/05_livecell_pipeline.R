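#!/usr/bin/env Rscript
# Dual-color live-cell processing on a synthetic granule movie with known
# stage drift and inter-channel offset: crop, MIP drift correction,
# channel registration, Richardson-Lucy deconvolution, isotropic
# resampling, and quantile normalization.

suppressPackageStartupMessages(library(rflsm))
dir.create("results", showWarnings = FALSE)

spec <- sim_spec(seed = 71, shape = c(16, 64, 64),
                 pitch_um = c(0.5, 0.25, 0.25),
                 granules = list(n = 8, d_um2_s = 0.002,
                                 velocity_um_s = c(0, 0, 0),
                                 frame_interval_s = 0.5, n_frames = 5,
                                 loc_sd_nm = 0),
                 drift_um_per_frame = c(0.12, 0.18, -0.1),
                 channel_offset_vox = c(0.5, 1.2, -0.8),
                 noise = list(photon_scale = 800, read_sd = 2, offset = 100))
mv <- render_movie(simulate_granules(spec), spec)
psf <- gaussian_psf_model(pitch_um = c(0.5, 0.25, 0.25))

res <- run_pipeline(mv$series, psf, config = list(iterations = 15))
writeLines(res$log, "results/pipeline_log.txt")
write.csv(res$drift, "results/drift_table.csv", row.names = FALSE)

cat("Pipeline stages:\n")
cat(paste0("  ", res$log, collapse = "\n"), "\n")
cat(sprintf("Estimated channel shift (%.2f, %.2f, %.2f) voxels; injected (%.2f, %.2f, %.2f)\n",
            res$channel_shift[1], res$channel_shift[2], res$channel_shift[3],
            spec$channel_offset_vox[1], spec$channel_offset_vox[2],
            spec$channel_offset_vox[3]))
dat <- res$series$data
r_t <- find_stack_offset(dat[1, 1, , , ], dat[5, 1, , , ])$shift
r_c <- find_stack_offset(dat[3, 1, , , ], dat[3, 2, , , ])$shift
cat(sprintf("Residual frame-5 misregistration (%.3f, %.3f, %.3f) voxels; residual channel offset (%.3f, %.3f, %.3f)\n",
            r_t[1], r_t[2], r_t[3], r_c[1], r_c[2], r_c[3]))
cat(sprintf("Output 99.95%% quantile (frame 1, channel 1): %.4f\n",
            quantile(dat[1, 1, , , ], 0.9995)))
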