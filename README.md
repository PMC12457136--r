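# noisyseg

Noise-robust training for binary (tumour/background) image segmentation in
R, for researchers who have a small set of carefully annotated images and a
much larger set whose masks are *known to be unreliable* — misaligned,
bleeding into adjacent structures, inconsistent, speckled, or cut off — and
who want to use both instead of discarding the unreliable part or letting it
corrupt training.

## What it implements

The training objective combines three mechanisms over a clean subset
`Dc` and a noisy subset `Dn`:

```
L = L_sup(Dc) + β_ada (L_ada(Dn) + β_reg σ) + β_semi (L_semi(Dc) + L_semi(Dn))
```

* **Pixel-wise noise adaptor.** A lightweight second decoder on the shared
  encoder predicts, per pixel, `p(labelled fg | true fg)` and
  `p(labelled fg | true bg)`. The adapted prediction
  `ŷ_ada = ŷ·p(fg|fg) + (1−ŷ)·p(fg|bg)` lives in the *noisy* label space,
  so noisy masks supervise it directly (`L_ada`) while the backbone `ŷ`
  keeps estimating the clean distribution; the shortcut penalty
  `σ = mean((ŷ − ŷ_ada)²)` keeps the adaptor honest. On synthetic data with
  known constant corruption rates, the trained adaptor's mean corruption
  probabilities recover the injected rates — the package's core diagnostic.
* **Multi-stage perturbations + variable teachers.** Consistency training
  with weak geometric / strong photometric / bottleneck-feature
  perturbations, pseudo-labels from an ensemble of mean teachers whose EMA
  updates are stochastically masked per parameter and staggered across
  training stages, and the two-threshold rule
  `y_pseudo = 1(ŷ ≥ τ₁ ∨ (ŷ ≥ τ₂ ∧ y = 1))`.
* **Label-noise simulators.** Symmetric / asymmetric transition matrices,
  per-pixel corruption fields (boundary- and intensity-driven), and five
  structured clinical corruptions (`shift`, `bleed`, `deform`, `speckle`,
  `truncate`), composable into seeded corruption plans.
* **Seeded phantom generator.** 2-D CT-like phantoms (bright organ, darker
  tumour blobs, bright vessel-like confounders excluded from the mask) so
  every mechanism is testable without any external data.
* **Evaluation.** DSC / JSC and their exact complements SVD / VOE, cohort
  means with 95 % t-intervals, paired t-tests; noise-rate and ablation
  study harnesses producing table-shaped CSVs.

The backbone is a compact plain-convolution U-Net with a manual
backpropagation implementation over Rcpp/BLAS kernels (verified against
finite differences in the test suite), sized for CPU-only desk-scale runs.

## A worked example

```r
library(noisyseg)

dir <- tempfile("demo")
train <- generate_dataset(phantom_spec(), n = 16, noise_rate = 0.5,
                          out_dir = file.path(dir, "train"), seed = 1)
val   <- generate_dataset(phantom_spec(), n = 4,  noise_rate = 0,
                          out_dir = file.path(dir, "val"),  seed = 2, split = "val")
test  <- generate_dataset(phantom_spec(), n = 10, noise_rate = 0,
                          out_dir = file.path(dir, "test"), seed = 3, split = "test")

fit <- mpvt(train, val = val, backbone = desk_backbone(),
            control = desk_control(seed = 1))
print(fit)
summarize_scores(evaluate_fit(fit, test))
```

```
Noise-robust segmentation fit
  backbone: depth 3, base width 8; 35547 parameters
  data: 8 clean + 8 noisy training samples
  weights: beta_ada=1 beta_reg=0.1 beta_semi=1; 3 teachers
  final epoch 30: loss 0.5970, validation DSC 94.6
 metric      mean     lower     upper  n
    dsc 94.067498 91.664434 96.470563 10
    jsc 88.967826 84.745944 93.189707 10
    svd  5.932502  3.529437  8.335566 10
    voe 11.032174  6.810293 15.254056 10
```

Half of the 16 training masks were corrupted (label bleed + elastic
deformation + 15 % symmetric speckle), yet the framework reaches a test DSC
of 94.1 on clean ground truth; the same data trains a naive supervised
baseline (every mask taken at face value, `beta_ada = beta_semi = 0`) to
a visibly lower DSC — that contrast is what `noise_rate_study()` and
`ablation_study()` quantify systematically, with 95 % CIs and paired
t-tests. SVD and VOE are exact complements of DSC and JSC, so each table
carries the same information in both error and agreement form.

A thin CLI over the same functions ships in `inst/cli/noisyseg`
(`generate | corrupt | train | eval | experiment`).

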