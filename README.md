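# fishdeblur

Fine-grained fish species recognition in blurry underwater scenes, on plain
CPU R. Underwater imagery is routinely degraded by two characteristic
nuisances — sinusoidal water-ripple warping and specular light-reflection
spots — which cripple ordinary image classifiers. `fishdeblur` implements a
complete pipeline for studying and mitigating this problem:

* **Noise simulators.** The water-ripple warp displaces each pixel by
  `offset_x = A·sin(2πyF)`, `offset_y = A·cos(2πxF)` (frequency `F`,
  amplitude `A`, modular wrap-around), and the light-reflection operator adds
  seeded Gaussian-falloff bright discs parameterised by physical diameter
  (cm) and intensity (Lux). Standard grids (`D ∈ {0.6, 0.8, 1.0}` cm ×
  `E ∈ {100, 250, 400}` Lux; `(F, A) ∈ {(0.04, 2), (0.06, 6), (0.08, 10)}`)
  expand a dataset into tagged degraded variants.
* **A two-stage diffusion deblurrer (TSD).** A four-level U-Net predicts a
  per-pixel softmax probability map over species; four residual + 2×
  upsampling modules reconstruct the clean image from the map concatenated
  with the degraded input. The Gaussian diffusion machinery —
  `x_t = √ᾱ_t·x₀ + √(1−ᾱ_t)·Z`, the posterior
  `q(x_{t−1}|x_t, x₀)` and the general bridge `q(x_s|x_t, x₀)` in the
  `f/g` scale parameterisation (`f_t = √ᾱ_t`, `g_t = √(1−ᾱ_t)`) — drives
  noise-injection augmentation during training.
* **A learnable channel-attention module (LAM)** — global pooling →
  two fully connected layers with ReLU → softmax channel weights →
  weighted channel fusion — inserted at the three junctions between the four
  stages of a bottleneck ResNet50 classifier (incoming widths 256/512/1024
  at full scale), with an adaptive odd kernel-size diagnostic
  `φ(C) = |log₂(C)/γ + b/γ|_odd`.
* **Dataset construction** in PASCAL VOC form: cleaning by content hash,
  bilinear standardisation to 224×224 RGB, stratified 8:1:1 leave-out
  splitting with round-half-even 10% shares, and a 13-fold augmentation plan
  (2 pans, 2 crops, 3 rotations, 1 mirror, 1 flip, 3 brightness scalings).
* **Metrics**: confusion-count accuracy and top-k accuracy with
  deterministic tie-breaking.
* **A synthetic toy-fish generator** so that every stage — including
  training both networks — runs end-to-end offline on one CPU.

The neural-network substrate (im2col convolutions on BLAS, batch
normalisation, max pooling, Adam, full manual backpropagation) is
implemented inside the package; no deep-learning framework is required.

## Worked example

```r
library(fishdeblur)

# a labelled toy dataset: 5 species, 12 images each, 64 px
man <- gen_toy_dataset(synthetic_spec(5, 12, 64, seed = 3), "raw")
man <- split_manifest(man, seed = 3)
table(man$split)
#> test train   val
#>     5    50     5

# degrade with the mid-grid water ripple and train the deblurrer
np <- ripple_params(0.06, 6)
pairs <- gen_deblur_pairs(synthetic_spec(5, 8, 64, seed = 11), np)$pairs
fit <- train_tsd(pairs, epochs = 25, n_classes = 5, seed = 1)
round(head(fit$history, 3), 4)
#> [1] 0.6658 0.1173 0.0582

# held-out pairs: deblurring beats the degraded input
ho <- gen_deblur_pairs(synthetic_spec(5, 3, 64, seed = 99), np)$pairs
mean(sapply(ho, function(p) image_mse(p$degraded, p$clean)))          # 0.0132
mean(sapply(ho, function(p) image_mse(deblur(p$degraded, fit$model),
                                      p$clean)))                      # 0.0100

# attention classifier on the clean toy data
model <- withr::with_seed(42, build_tiny_classifier(5, input_size = 64))
cls <- train_classifier(man, model,
                        train_config(input_size = 64, epochs = 5,
                                     batch_size = 8, seed = 42))
cls$history$train_acc
#> [1] 20 56 78 90 98        # chance is 20%
```

The first two MSE numbers say the ripple degradation costs 0.0132 mean
squared error per pixel (on the [0, 1] scale) and the trained two-stage
deblurrer recovers about a quarter of it on images never seen in training; the
accuracy trace shows the attention classifier pulling away from the 20%
chance floor within five epochs.

Count reconciliation of the construction protocol against the published
25-species census is exact:

```r
census <- blurryfish_counts()
sum(census$total)                          # 2754 source images
colSums(split_counts(census$total))        # 2202 / 276 / 276
sum(13 * census$total)                     # 35802 after 13-fold augmentation
man2754 <- data.frame(path = sprintf("img_%04d.png", 1:2754),
                      label = rep(census$species, census$total))
nrow(build_noise_variants(man2754, reflection_grid = reflection_noise_grid()))
#> 24786                                    # 9 reflection grids
nrow(build_noise_variants(man2754, ripple_grid = ripple_noise_grid()))
#> 8262                                     # 3 ripple grids
```

A command-line front end (`exec/fishdeblur`) wraps the same functions as
`gen-synthetic`, `build-data`, `add-noise`, `train-tsd`, `deblur` and `demo`
subcommands.

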