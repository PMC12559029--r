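---
title: "Unfolded low-rank + sparse decomposition for EEG artifact removal: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unfolded low-rank + sparse decomposition for EEG artifact removal: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrrunet)
```

## The problem

A single-channel EEG segment contaminated by ocular (EOG) or myogenic (EMG)
artifacts is modeled additively, $R = D + N$, where $D$ is the clean brain
signal and $N$ the artifact. Because brain rhythms repeat across nearby time
windows, a matrix built from consecutive windows of the segment is
approximately low rank, while blink bumps and muscle bursts are concentrated
in a few samples or bands — sparse in the same representation. The classical
estimator is therefore the convex program

$$\min_{D,N}\; \|D\|_* + \mu \|N\|_1 + \tfrac{\beta}{2}\,\|R - D - N\|_F^2,$$

with the nuclear norm standing in for rank and the $\ell_1$ norm for
sparsity; the quadratic penalty replaces an equality constraint so no
Lagrange multipliers are needed. Block coordinate descent solves it by
alternating two proximal maps: singular value thresholding
$D \leftarrow \mathrm{SVT}_{1/\beta}(R - N)$ and elementwise soft
thresholding $N \leftarrow \mathcal{S}_{\mu/\beta}(R - D)$. Both steps
exactly minimize the objective in one block, so the objective is
monotonically nonincreasing — a property the test suite asserts.

The deep unfolding model keeps the *structure* of this iteration but learns
its operators. Stage $k$ of the network computes

$$D_k = (R_{k-1} - N_{k-1}) + \mathrm{NetD}(R_{k-1} - N_{k-1}),$$
$$N_k = R_{k-1} + N_{k-1} - D_k - \rho_k\, g(N_{k-1}) + (R_{k-1} - D_k),$$
$$R_k = \mathrm{NetR}(D_k + N_k),$$

with $R_0 = y$ and $N_0 = 0$. NetD is a 1-D U-Net replacing the SVT
proximal map; $g$ is a small convolution stack standing in for the gradient
of the noise regularizer, derived from a Lipschitz (Taylor) majorization of
the noise term whose closed-form update is
$\delta N_{k-1} + (1-\delta)(R_{k-1}-D_k) - \rho\, \nabla S(N_{k-1})$
with $\delta = \mu l_s / (\mu l_s + \beta)$ and
$\rho = \mu/(\mu l_s + \beta)$ (implemented verbatim in
`surrogate_update_n()` and verified against numerical minimization of the
surrogate objective). In the network $\delta$ is frozen at $1/2$ and
$\rho_k$ is one learnable scalar per stage; the second $(R_{k-1}-D_k)$ term
is the residual enhancement of the noise path. NetR re-synthesizes the next
raw input from the separated parts. The default output is $D_K$, the final
clean estimate; `output_mode = "R_last"` selects the re-synthesized signal
instead.

## Design choices in the unfolded architecture

Several points are genuinely open in this family of models; the package
resolves them as follows and exposes each as configuration.

* **Noise-update form.** The derivation with $\delta = 1/2$ gives
  half-weighted convex combinations, while the architecture as built drops
  the halves in favor of the residual-enhanced form above. The package
  implements the residual-enhanced form by default and restores the strict
  derivation under `strict_majorization = TRUE`. Both satisfy the same algebraic
  identities at zero parameters.
* **Which clean estimate feeds the noise update.** The stage dataflow feeds
  the *current* $D_k$ into Net-N (the default); `use_prev_D = TRUE` switches
  to $D_{k-1}$, with $D_0 = R_0$ at the first stage.
* **Subnetwork sizes.** No layer widths are canonical for this architecture.
  Full-size defaults are encoder channels (16, 32, 64, 128) with kernel 3,
  max-pooling by 2, transposed-convolution upsampling, and skip
  concatenation; Net-N is 3 convolution layers of 16 channels; Net-R is 2
  layers of 16 channels. All are configurable, and the reference experiments
  below use a compact variant.
* **Initialization.** Convolutions use Kaiming-uniform fan-in
  initialization; $\rho_k$ starts at 0.1. The final projection convolutions
  of Net-D and Net-R are zero-initialized, which makes every stage exactly
  the identity map at initialization: the model starts from the classical
  fixed point $D = R - N$, $y \mapsto y$, and training refines the iteration
  rather than first repairing a random perturbation. In the reduced
  experiments below this cuts the loss reached within the epoch budget by an
  order of magnitude.
* **Batch normalization** uses per-channel statistics over batch × time
  during training and running estimates (momentum 0.1) at prediction time.
* **Stage weights are not shared** by default — each stage has its own
  subnetworks and its own $\rho_k$; `share_weights_across_stages = TRUE`
  collapses the subnetworks while keeping per-stage $\rho_k$.

Two structural properties deserve a note. First, because $N_0 \equiv 0$,
the first convolution of stage 1's noise surrogate always sees an all-zero
input, so its *weight kernel* (not its bias) can never receive gradient.
Second, when the trained output is the clean estimate $D_K$ (the default),
the last stage's noise and re-synthesis modules — including $\rho_K$ — do
not feed the loss at all and are therefore inert; they exist to complete
the iteration template, and training them requires
`output_mode = "R_last"`. Both facts are inherent to the unfolded
architecture, not implementation artifacts; the test suite pins them
explicitly. Gradient-flow audits are run at a generic parameter point
rather than at the identity initialization, where the zero final
projections additionally block upstream paths.

The forward and backward passes are implemented in-package on a small
reverse-mode tape over `(channel, time, batch)` arrays with compiled 1-D
convolution kernels; every vector–Jacobian product is validated against
central finite differences in the test suite, which is the reason a
hand-rolled tape is trustworthy here.

## Synthetic data: what it emulates, what it does not

The generators emulate the structure of the public single-channel benchmark
arrays used in this literature (thousands of 2-s, 256-Hz clean EEG, EOG and
EMG segments):

* **Clean EEG** — band-filtered Gaussian processes: white noise shaped in
  the Fourier domain by gains over the canonical delta/theta/alpha/beta/
  gamma bands plus a weak $1/f$ background (amplitude `pink_gain` relative
  to the strongest band; the background vanishes when all gains are zero so
  a zero configuration yields silence). Defaults put the dominant gain on
  alpha over a delta/theta floor, the textbook resting-EEG shape. Segments
  are mean-centered and scaled to unit RMS.
* **EOG** — raised-cosine bumps of half-width 0.2 s (±30%/+10% jitter),
  single polarity on a zero baseline, one to a few events per 2-s segment.
  At these defaults ≥ 90% of spectral energy lies below 5 Hz, matching the
  band-pass applied to reference ocular recordings.
* **EMG** — Gaussian noise shaped into a 20–120 Hz band and gated by
  Tukey-windowed bursts of 50–200 ms, one to a few per segment, covering
  well under half the samples.

Mixtures follow $y = x + \lambda n$ with $\lambda$ solved from a target SNR.
Two conventions are exposed: `"power"` (the default), under which
$\lambda = \mathrm{RMS}(x) / (\mathrm{RMS}(n)\,10^{s/20})$ and the measured
power-ratio SNR equals the request to $10^{-6}$ dB, and `"rms_ratio"`, the
dialect of the public benchmark protocol with $10^{s/10}$. RMS is the plain
quadratic mean with no detrending. Each noisy/clean pair is standardized by
the noisy segment's standard deviation (both divided by the same scale, so
the additive model is preserved); training, prediction and metrics operate
in this space, which is harmless because all four metrics are invariant to a
common rescaling.

What the generators do **not** emulate: multichannel spatial structure,
nonstationary band power, line noise, electrode drift, or the amplitude
statistics of real recordings. Passing tests on this data demonstrates that
the estimator learns to separate band-limited oscillations from
spectrally/temporally concentrated interference under the stated protocol —
not that it reaches any particular performance on real EEG.

## Evaluation metrics

Four standard quantities compare a denoised segment $\hat{x}$ to its clean
reference $x$: temporal relative RMSE
$\mathrm{RMS}(\hat{x}-x)/\mathrm{RMS}(x)$; spectral relative RMSE, the same
ratio on Welch power spectral densities; the Pearson correlation; and
$\mathrm{SNR} = 10\log_{10}(P_s/P_n)$ with $P_s = \overline{x^2}$ and
$P_n = \overline{(\hat{x}-x)^2}$, which is algebraically
$-20\log_{10}\mathrm{RRMSE}_t$ — an identity the tests assert to $10^{-9}$.
The Welch estimator is not canonical in this setting, so its parameters are
explicit and recorded: Hann window of length $\min(256, L)$, 50% overlap,
one-sided density scaling. A perfectly reconstructed batch gives RRMSE 0 and
CC 1; an all-zero output gives RRMSE 1 and an undefined correlation, which
is reported as `NA` and excluded from batch means. Benchmark tables report
per-SNR-level means over the deterministic −7…2 dB grid plus their
unweighted mean (equal group sizes make this equal to the pooled mean).

## Training protocol

The dataset pipeline mirrors the reference preprocessing: clean training
segments are shuffled `n_repeats = 10` times and concatenated, each copy
paired with an artifact segment (seeded shuffle, cyclic reuse since artifact
and EEG counts differ) and mixed at an SNR drawn uniformly from −7…2 dB;
validation and test segments are mixed at each of the ten integer SNRs with
deterministic index-cycled pairing. Splits are by clean-segment identity
(default 80/10/10), so no clean segment can leak across splits through the
repetition. Training minimizes MSE between the configured model output and
the standardized clean target with Adam at learning rate $10^{-4}$
($\beta_1 = 0.9$, $\beta_2 = 0.999$), early stopping on validation loss
restores the best epoch. Everything is driven by one seed; two runs with the
same seed are bitwise identical.

## Reference experiment sizes

The package's own experiments (tests and the acceptance script) run on a
compact budget chosen once: 240 clean segments split 200/20/20 with 200
artifact segments, giving 2000 training mixtures and 200-segment evaluation
grids; model $K = 3$ with Net-D depth 3 and channels (4, 8, 16), Net-N
3 × 8, Net-R 2 × 8 (≈ 15k parameters); Adam lr $10^{-4}$, batch 32, 6
epochs, seeds 0–2. Under this budget the unfolded model raises mean test
SNR by ≈ 9 dB over the noisy input on EMG mixtures (median over seeds).
The ablation experiments use ocular artifacts, matching the published
ablation protocol (its ablation table equals the EOG column of its K-sweep
table): there the U-Net clean-signal estimator beats a parameter-matched
plain CNN, and $K = 3$ beats $K = 1$. On EMG mixtures at this reduced
budget the parameter-matched CNN is actually competitive with the U-Net — a
short receptive field suffices for high-frequency bursts — which is why the
artifact type of the ablation matters and is fixed to EOG.

The classical solver's reference experiment decomposes a 32 × 32 rank-2
plus 5%-sparse matrix with $\mu = 0.15$, $\beta = 10$ (tuned once for this
instance family), recovering the low-rank part to relative error
$\le 10^{-2}$ within 500 alternations.

## Numerical notes and limitations

* Window embeddings: the default is the 16 × 32 reshape of a length-512
  segment (columns are consecutive windows), under which any equally spaced
  windowing of a sinusoid spans at most two directions; a Hankel embedding
  with anti-diagonal-averaging inverse is available.
* `classical_denoise()` attributes the quadratic-penalty residual
  $R - D - N$ to the clean part so that $\hat{x} + \hat{n} = y$ holds
  exactly in reshape mode; the residual is threshold-sized, so this choice
  is immaterial for spike attribution.
* Soft/singular-value thresholds follow the standard proximal splitting of
  the penalized objective: $1/\beta$ on singular values, $\mu/\beta$
  elementwise. Stopping is by relative Frobenius change of $(D, N)$
  (default $10^{-7}$).
* Max-pooling resolves ties toward the earlier sample; batch-norm uses
  $\varepsilon = 10^{-5}$; the infinite-SNR case $P_n = 0$ returns `Inf`
  rather than erroring.
* Segment lengths must be divisible by $2^{\mathrm{depth}-1}$ for the U-Net
  variant; arbitrary-length recordings are windowed into non-overlapping
  frames (zero-padded remainder, trimmed on output) by the file interface.
* The comparison baselines of the surrounding literature (separator
  networks, transformer denoisers, ICA-based pipelines) are out of scope;
  the plain-CNN variant exists only as the internal ablation control.
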