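# noise2average

Self-supervised denoising of multi-repetition volumetric MRI, for
neuroimaging researchers who have two or more co-registered acquisitions of
the same anatomy but no clean reference image.

## The method

Given $n$ repetitions $y_k = x + e_k$ with independent zero-mean noise,
averaging alone reduces noise variance to $\sigma^2/n$. This package
implements an iterative residual-learning strategy that does better without
clean data: a 3D convolutional network $f_\theta$ is fine-tuned to map each
standardized repetition to its residual against the repetition average
($\bar y - y_k$ at iteration 1), every repetition is denoised as
$d_k = y_k + f_\theta(y_k)$, and the $d_k$ are averaged into the iteration
output — which becomes the training target of the next iteration. Because
a CNN approximates image structure but not noise, each iteration's output
is, in the ideal case, as clean as an average of $n^{i+1}$ raw repetitions.
Recommended settings: two iterations for repetition pairs, one iteration
for $n > 2$, with an unsupervised MSE (`umse()`) available as a stopping
criterion when no ground truth exists.

The package also provides:

* the classic other-repetition training mode (`noise2noise_run()`) and a
  supervised mode (`supervised_run()`) as baselines, plus corpus
  pretraining (`pretrain_on_corpus()`) for warm-started fine-tuning;
* a compact modified 3D U-Net (stride-1 $3^3$ convolutions, no pooling,
  concatenation skips, zero-initialized residual head) with masked MSE/MAE
  losses, Adam, Monte Carlo 80/20 splits, and blockwise whole-volume
  inference with overlap averaging;
* structural and diffusion-tensor phantom generators with
  Gaussian/Rician noise and residual affine misalignment, so everything is
  testable without downloads;
* a diffusion tensor toolbox: DWI synthesis $S = S_0 e^{-b g^\top D g}$,
  log-linear OLS fitting, FA/MD/AD/RD/V1 metrics, and encoding-scheme
  design by condition-number minimization (six-direction optimum
  $\kappa \approx 1.3228$) and electrostatic-repulsion subset selection;
* masked image-quality metrics (MAE, PSNR, volumetric 3D SSIM) on the
  standard add-3-divide-6 intensity scale, and DTI error reports.

Volumes and masks read/write NIfTI-1 (`RNifti`), direction tables read and
write FSL-style bvec/bval files, and a thin CLI
(`inst/cli/n2a.R`: `simulate`, `pretrain`, `denoise`, `evaluate`) wraps the
exported functions.

## Worked example

```r
library(noise2average)

# 1. simulate two noisy repetitions of a structural phantom (sigma = 0.3)
phantom <- make_structural_phantom(64, seed = 11)
reps <- simulate_repetitions(
  phantom, simulation_config(sigma = 0.3, n_repetitions = 2, seed = 21))

# 2. fine-tune a compact denoiser for two iterations
model <- build_munet(network_config(depth = 4, channels = 8), seed = 31)
states <- noise2average_run(
  reps, model,
  run_config(iterations = 2, epochs_per_iteration = 10,
             block_shape = 32, seed = 41),
  training_config(loss = "mse", learning_rate = 1e-3, seed = 51))

# 3. compare against the ground truth
params <- compute_standardization(phantom$truth, phantom$mask)
for (img in list(single = reps$repetitions[[1]],
                 average = build_iteration_target(reps, 1),
                 iter1 = states[[1]]$output,
                 iter2 = states[[2]]$output)) {
  print(image_similarity(img, phantom$truth, reps$mask, params))
}
```

Output (about two minutes on one CPU):

```
<n2a_metrics_report> MAE 0.03991 | PSNR 26.03 dB | SSIM 0.755
<n2a_metrics_report> MAE 0.02818 | PSNR 29.04 dB | SSIM 0.8526
<n2a_metrics_report> MAE 0.02154 | PSNR 31.31 dB | SSIM 0.9035
<n2a_metrics_report> MAE 0.01839 | PSNR 32.35 dB | SSIM 0.9198
```

Reading the four lines: a single noisy repetition scores 26.0 dB; plain
two-repetition averaging gains ~3 dB (the $\sigma^2/n$ law); the first
denoising iteration beats the average by a further 2.3 dB while only ever
training on the noisy average as target; and the second iteration — which
retrains against the first iteration's output — improves MAE and PSNR
again, mirroring the recommendation of two iterations for repetition
pairs.

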