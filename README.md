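# lrrunet

Removal of ocular (EOG) and myogenic (EMG) artifacts from single-channel EEG
segments with a deep unfolding network — **LRR-Unet** — whose stages mirror
the iterations of a penalized low-rank + sparse (robust-PCA-style)
decomposition. The package is aimed at neural-signal-processing researchers
who want a self-contained, fully seeded implementation of the method, the
classical solver it unfolds, and the evaluation protocol around it, with no
deep-learning framework dependency: the forward and backward passes run on a
small reverse-mode tape with compiled 1-D convolution kernels, validated
against finite differences in the test suite.

## The model

A contaminated segment is modeled as `R = D + N` with `D` the clean brain
signal (approximately low rank across time windows) and `N` the artifact
(temporally/spectrally sparse). The classical estimator solves

```
min_{D,N}  ||D||_* + mu ||N||_1 + beta/2 ||R - D - N||_F^2
```

by alternating singular value thresholding `D <- SVT_{1/beta}(R - N)` and
soft thresholding `N <- S_{mu/beta}(R - D)` on a window-embedded matrix
(`lrr_decompose()`, `classical_denoise()`). The unfolded network keeps this
iteration's structure for K stages but learns its operators
(`lrr_unet()`, `lrr_unet_forward()`):

```
D_k = (R_{k-1} - N_{k-1}) + NetD(R_{k-1} - N_{k-1})     # 1-D U-Net
N_k = R_{k-1} + N_{k-1} - D_k - rho_k g(N_{k-1}) + (R_{k-1} - D_k)
R_k = NetR(D_k + N_k)                                   # re-synthesis CNN
```

with `R_0 = y`, `N_0 = 0`, a fixed majorization weight `delta = 1/2`, and
one learnable step size `rho_k` per stage. Mixtures are built at controlled
SNR via `y = x + lambda * n` (`mix_segments()`), and results are scored with
the four standard metrics — temporal/spectral relative RMSE, correlation,
and SNR (`evaluate_batch()`). See the methods vignette
(`vignettes/lrr-unet-methods.Rmd`) for assumptions, defaults, and design
decisions.

## Worked example

Generate a synthetic EMG-contaminated dataset, fit a compact 3-stage model,
and score it on the deterministic −7…2 dB evaluation grid:

```r
library(lrrunet)

bundle <- synthetic_bundle(n_clean = 240, n_artifact = 200,
                           artifact_kind = "emg", ratios = c(10, 1, 1),
                           seed = 100)
train  <- build_training_set(bundle, n_repeats = 10, seed = 101)  # 2000 mixtures
val    <- build_eval_set(bundle, "val")
test   <- build_eval_set(bundle, "test")

cfg <- unfold_config(K = 3,
                     netd = netd_config(depth = 3, channels = c(4, 8, 16)),
                     netn = netn_config(n_layers = 3, channels = 8),
                     netr = netr_config(n_layers = 2, channels = 8))
fit <- lrr_unet(train, val = val, config = cfg,
                control = train_control(lr = 1e-4, batch_size = 32,
                                        max_epochs = 6, seed = 0))
print(fit)
#> LRR-Unet: deep unfolded low-rank + sparse EEG denoiser
#>   stages (K): 3   output: D_last   delta: 0.50
#>   Net-D: 1-D U-Net, depth 3, channels 4-8-16, parameters total: 5256
#>   trained 6 epoch(s); best epoch 6
#>   rho per stage: 0.1486, 0.1554, 0.1000

tab <- run_benchmark(fit, test)
tab[tab$snr_level == "mean", ]
#>    method snr_level   rrmse_t   rrmse_s        cc   snr_db
#> 11  model      mean 0.4840598 0.3008809 0.8750815 6.531229
```

The mean row reads: after denoising, the residual is ≈ 0.48 of the clean
signal's RMS in time (≈ 0.30 in the spectrum), the denoised/clean
correlation is ≈ 0.88, and the output SNR is ≈ +6.5 dB — about 9 dB above
the −2.5 dB mean input SNR of the grid. (Exact trailing digits depend on
the BLAS; the seeds make reruns on one machine identical.) Note `rho3`
still sits at its 0.1 initialization: with the clean-estimate output
`D_last`, the final stage's noise path does not feed the loss — a
structural property discussed in the methods vignette.

Per-stage step sizes are the model's interpretable coefficients
(`coef(fit)`); `predict(fit, y)` denoises new segments with per-segment
standardization inverted on output; `residuals(fit)` returns the estimated
artifact component; `plot(fit)` shows the training history.

## Command-line front end

```sh
Rscript inst/cli/lrr-unfold.R simulate --n-segments 20 --kind clean --artifact emg --snr -3 --seed 1 --out noisy.csv
Rscript inst/cli/lrr-unfold.R train --artifact emg --K 3 --epochs 6 --seed 0 --out model.rds
Rscript inst/cli/lrr-unfold.R denoise --checkpoint model.rds --in noisy.csv --out denoised.csv
Rscript inst/cli/lrr-unfold.R score --denoised denoised.csv --clean clean.csv
Rscript inst/cli/lrr-unfold.R classical-denoise --in noisy.csv --rows 16 --cols 32 --out classical.csv
```

Segment files are plain CSV, one segment per row.
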