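# padnet

Unsupervised representation learning for 32x32 RGB images through **perturbed
and adversarial dreaming (PAD)**: a three-phase wake-sleep training loop for
a convolutional encoder/discriminator `E = (E_z, E_d)` and generator `G`,
together with the complete evaluation suite for judging the learned
representations and a set of sleep-pathology ablations.

The model is for computational neuroscientists and representation-learning
researchers who want a compact, fully inspectable implementation of the
hypothesis that NREM and REM sleep phases implement complementary learning
objectives on top of ordinary waking autoencoding:

* **Wake** — a mini-batch `X` is encoded (`Z = E_z(X)`), reconstructed
  (`X' = G(Z)`) and judged (`D = E_d(X)`). The encoder descends
  `L_img + L_KL + L_real` with
  `L_img = (1/b) sum_i ||x_i - G(E_z(x_i))||^2`,
  `L_KL = 1/(2 n_z) sum_j (mu_j^2 + sigma_j^2 - 1 - log sigma_j^2)`
  (batch statistics of the latent code), and
  `L_real = -(1/b) sum_i log E_d(x_i)`; the generator descends `L_img`.
  The latent batch is stored in a two-slot episodic buffer (`Z`, `Z_old`).
* **NREM, "perturbed dreaming"** — the stored `Z` is replayed through `G`,
  the generated images are occluded with random gray patches `Omega`, and
  the encoder alone descends
  `L_NREM = (1/b) sum_i ||z_i - E_z(G(z_i) ⊙ omega)||^2`.
* **REM, "adversarial dreaming"** — images are generated from
  `Z_mix = lam' (lam Z + (1-lam) Z_old) + (1-lam') eps`,
  `eps ~ N(0, I)`; with `L_REM = -(1/b) sum_i log(1 - E_d(G(z_mix,i)))` the
  encoder/discriminator descends and the generator **ascends** (the
  adversarial game is a gradient sign switch, not a separate objective).

Evaluation: linear readout separability (softmax readout `y = W z`, SGD
lr 0.2, 20 epochs), occlusion robustness curves (size-4 squares at
0..100% intensity), PCA projections, intra/inter-class and clean-occluded
latent distance ratios, and the Fréchet distance
`||mu_r - mu_g||^2 + Tr(S_r + S_g - 2 (S_r S_g)^{1/2})` between feature
statistics of real images and NREM/REM dream samples.

## Worked example

```r
library(padnet)

ds <- generate_synthetic(num_classes = 4, n_per_class = 400,
                         n_test_per_class = 100, seed = 42)
cfg <- pad_config(epochs = 30, latent_dim = 24, channels = c(6, 12, 24),
                  seed = 2)
fit <- pad_train(ds$train, cfg)
fit
#> <pad_fit> 750 cycles, 30 epochs

round(colMeans(tail(fit$trace, 25)[, 3:8]), 3)
#>  loss_img   loss_kl loss_real loss_wake loss_nrem  loss_rem 
#>   241.387     1.784     0.437   243.608     3.610     0.551

metrics <- pad_evaluate(fit$params, ds$train, ds$test,
                        intensities = c(0, 30, 50), n_intra = 500,
                        n_inter = 2000, n_pairs = 1000, n_fid = 500, seed = 1)
metrics
#> <pad_metrics>
#>   separability          0.660 (naive baseline 0.250)
#>   occlusion curve       0%=0.66 30%=0.49 50%=0.40 
#>   intra/inter ratio     0.906
#>   clean-occluded ratio  0.465
#>   FID (nrem, rem)       59.04, 13.25
```

Reading the output: the per-cycle loss trace shows the reconstruction loss
(`loss_img`, summed over all 3072 pixels of a sample) shrinking while the
two adversarial losses stay near `-log 0.5 ~ 0.69` — the discriminator and
generator remain in balance rather than one winning. `separability` is the
test accuracy of a linear readout trained on frozen latents (naive baseline
= majority-class frequency); the occlusion curve shows how that accuracy
degrades when test images are occluded with size-4 gray squares; the two
distance ratios summarize latent organization (lower = tighter semantic
clusters / more occlusion-invariant codes); the Fréchet distances measure
how similar NREM and REM dream samples are to real images under a fixed
192-dimensional pixel-block feature embedding (lower = more realistic; use
one embedding consistently — values are not comparable to Inception-based
numbers).

Sleep-pathology ablations use the same machinery:

```r
cfg_worem <- pad_pathology_config("wo_rem", epochs = 30, latent_dim = 24,
                                  channels = c(6, 12, 24), seed = 2)
```

`wo_rem` disables REM, halves the NREM loss and injects `N(0, 0.5 I)` latent
noise into the wake reconstruction; `wo_nrem` drops NREM; `wo_mix` drives
REM from the single current memory; `noise_only_rem` from pure noise;
`swapped_order` runs wake-REM-NREM.

## Command line

```sh
Rscript -e 'quit(status = padnet::pad_cli())' synth --out shapes.rds --seed 1
Rscript -e 'quit(status = padnet::pad_cli())' train --data shapes.rds --out run1 \
    --epochs 30 --latent-dim 24 --channels 6,12,24 --seed 2
Rscript -e 'quit(status = padnet::pad_cli())' evaluate \
    --checkpoint run1/checkpoint.rds --data shapes.rds --out run1/eval
Rscript -e 'quit(status = padnet::pad_cli())' ablate --data shapes.rds \
    --out ablation --seeds 1,2,3 --epochs 30
Rscript -e 'quit(status = padnet::pad_cli())' dream \
    --checkpoint run1/checkpoint.rds --data shapes.rds --out dreams.png --phase rem
```

Every training run writes its resolved configuration, a per-cycle loss-trace
CSV, a checkpoint and NREM/REM dream grids under `--out`.

## Documentation

See the methods vignette (`vignettes/padnet-methods.Rmd`) for the model
equations, parameter table, design decisions (initialization, numerical
guards, randomness), what the synthetic generator does and does not emulate,
and known limitations.
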