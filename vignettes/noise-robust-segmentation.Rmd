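---
title: "Learning tumour segmentation from noisy masks: the model behind noisyseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning tumour segmentation from noisy masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(noisyseg)
```

## The problem

Segmentation networks for lesions on CT-like images need large sets of
pixel-accurate masks, and such masks are the expensive part: clinical
annotations are routinely misaligned, bleed into neighbouring structures,
disagree between slices, contain stray marks, or are cut off. Discarding
imperfect cases wastes most of the data; training on them as if they were
correct teaches the network the annotation errors. `noisyseg` implements a
training framework that uses both kinds of data deliberately: a small subset
with trusted masks ($D_c$) and a larger subset with noisy masks ($D_n$).

The total training objective is

$$
L \;=\; L_{sup}(D_c) \;+\; \beta_{ada}\bigl(L_{ada}(D_n) + \beta_{reg}\,\sigma\bigr)
\;+\; \beta_{semi}\bigl(L_{semi}(D_c) + L_{semi}(D_n)\bigr),
$$

with three mechanisms:

1. **Supervision on clean data.** $L_{sup}$ is cross-entropy plus soft Dice
   between the backbone's probability map $\hat y$ and the trusted mask, on a
   weakly augmented view (the same geometric transform applied to image and
   mask).

2. **A pixel-wise noise adaptor on noisy data.** A second, lightweight
   decoder sharing the encoder predicts per pixel the two corruption
   probabilities $p(\tilde y = 1 \mid y = 1)$ and $p(\tilde y = 1 \mid y = 0)$.
   By the law of total probability the *adapted* prediction
   $$\hat y_{ada} = \hat y \, p(\tilde y{=}1 \mid y{=}1) + (1-\hat y)\, p(\tilde y{=}1 \mid y{=}0)$$
   lives in the *noisy* label space, so the noisy mask can supervise it
   directly ($L_{ada}$) while the backbone keeps estimating the clean
   distribution. The shortcut penalty
   $\sigma = \overline{(\hat y - \hat y_{ada})^2}$ stops the adaptor from
   absorbing all supervision and starving the backbone.

3. **Consistency with variable teachers.** Every sample also contributes a
   consistency term: an ensemble of $K$ mean teachers predicts on the weak
   view, a two-threshold rule turns that into a pseudo-label
   $$y_{pseudo} = \mathbf{1}\bigl(\hat y \ge \tau_1 \;\vee\; (\hat y \ge \tau_2 \wedge y = 1)\bigr),$$
   and the student is trained to reproduce it on a strongly perturbed view.
   Teachers track the student by an exponential moving average whose
   per-parameter updates are applied only with probability $m$ (a
   dropout-like mask) and which start at staggered epochs, so the ensemble
   mixes models from different stages of training.

When $\beta_{ada} = \beta_{semi} = 0$ the framework reduces exactly — same
random draws, same trajectory — to a plain supervised baseline, in which
noisy masks (if present) are used as if they were correct. That baseline is
the reference point of the noise-rate study.

## Label-noise models

`noisyseg` simulates every noise family it is meant to survive:

* **Class-level transition noise.** A row-stochastic matrix $p_{ij}$ gives
  the probability that true class $i$ is recorded as class $j$; symmetric
  noise has off-diagonals $\rho/(c-1)$, asymmetric noise separate rates
  $\rho_{01}, \rho_{10}$.
* **Instance- and position-dependent noise.** A `corruption_field` holds
  per-pixel flip probabilities built from covariates: a boundary band
  (annotator uncertainty concentrates at edges) and an intensity-similarity
  term (structures that *look* like tumours attract false annotations). Both
  reduce to per-pixel flip probabilities, which is why one container serves
  both families.
* **Structured clinical corruptions.** `shift` (misalignment), `bleed`
  (morphological dilation into neighbouring structures), `deform` (a seeded
  smooth random warp producing conflicting boundaries), `speckle` (random
  toggled blobs), `truncate` (cut-off labels).

Corruption plans compose steps left-to-right; each step draws its own
substream from the plan seed, so a dataset is a pure function of
`(spec, n, noise_rate, plan, seed)`. The default plan
(`bleed` radius 2 + `deform` + symmetric $\rho = 0.15$) is a stand-in
mixture covering the main families; every experiment accepts any plan.

## The synthetic phantoms

No public dataset accompanies the method, so the package generates its own
study conditions: 64×64 phantoms with a bright elliptical organ
(parenchyma ≈ 0.55), darker circular tumours (≈ 0.30, the mask foreground),
bright tubular vessel confounders (≈ 0.85, *never* in the mask — they exist
precisely so that instance-dependent noise and false-positive behaviour have
a target), background ≈ 0.12, and additive Gaussian acquisition noise
(sd 0.03). Tumours darker / vessels brighter is a fixed convention so the
intensity cue of instance-dependent noise is well defined. Intensities are
quantized to the 8-bit grid at generation time, making file round-trips
exact.

What the phantoms deliberately do **not** emulate: CT physics (beam
hardening, Hounsfield calibration), 3-D context, multi-organ anatomy,
texture. Passing tests on phantoms therefore demonstrates that the
*mechanisms* work — that the adaptor recovers corruption statistics, that
consistency training stabilises a noisy baseline — not that any particular
clinical accuracy would be reached on real CT.

## Defaults and why

| parameter | default | reason |
|---|---|---|
| backbone | depth 4, width 16 (config); depth 3, width 8 for desk runs | plain-convolution U-Net; encoder size is not the contribution |
| $\beta_{ada}, \beta_{reg}, \beta_{semi}$ | 1, 0.1, 1 | supervision-scale adaptor term, light shortcut penalty |
| consistency ramp | sigmoid ramp $e^{-5(1-t)^2}$ over first 30 % of epochs | near-zero early weight; see *Numerical choices* |
| $\tau_1, \tau_2$ | 0.9, 0.4 | $\tau_2$ must sit below an untrained teacher's output so the label clause can bootstrap |
| teachers | $K = 3$, $\alpha = 0.95$, $m = 0.5$, activation at 0, ⅓, ⅔ of epochs | desk-scale step counts; see below |
| optimizer | adaptive moments, lr $10^{-3}$, weight decay $10^{-4}$, accumulation 2 | reference regime; desk schedule uses lr $3\times10^{-3}$, batch 2 |
| Dice smoothing $\varepsilon$ | 1.0 | standard smoothing; CE clip $10^{-7}$ |
| binarization | 0.5 | evaluation threshold on probability maps |

**Desk-scale problem sizes.** The experiment helpers default to 64×64
phantoms, cohorts of 16 training / 4 validation / 10 test images, a
depth-3 / width-8 backbone and 30–60 epochs. These sizes were chosen once so
that a complete study (noise-rate sweep, recovery experiment, full-method
comparison, three seeds each) runs on a single CPU core in minutes; all of
them scale up through the same interfaces.

## Numerical choices that mattered

These three choices were made after observing concrete failure modes; they
are the package's own design calls where the method description is silent,
and each is configurable back to the naive variant.

* **The adaptor channel is cross-entropy only** (`ada_dice_weight = 0`).
  CE against a noisy mask is minimized exactly at the conditional corruption
  probability, which is what the corruption map *is*. The soft-Dice
  gradient on a minority-class pixel is roughly $|\Omega|/|fg|$ times the CE
  gradient and always points toward hard labels; with Dice included the
  adaptor saturates (it reports foreground corruption rates near zero
  regardless of the injected rate) and the probabilistic reading of the map
  is lost. The exported `adaptor_loss()` keeps the CE + Dice contract for
  reference and testing.

* **The consistency channel is cross-entropy only**
  (`semi_dice_weight = 0`). The soft-Dice loss against an *empty*
  pseudo-label is an attractor at the all-background state: its gradient
  grows as predictions shrink, and a desk-scale run can saturate its logits
  irrecoverably (sigmoid exactly 0 ⇒ zero gradient forever) before the
  teachers become informative. Bounded CE consistency has no such attractor.

* **Bootstrappable pseudo-labels and a late ramp.** With $\tau_2$ above an
  untrained teacher's output level, pseudo-labels start empty, and the
  consistency term then *suppresses* foreground formation — a
  self-confirming collapse. $\tau_2 = 0.4$ lets the label clause seed
  pseudo-foreground immediately; the sigmoid ramp keeps the consistency
  weight near zero while supervision establishes the foreground; and the
  teacher EMA decay of 0.95 reflects that a desk-scale epoch has ~8
  optimizer steps (a 0.99 decay would leave teachers at their initialization
  for half the run — full-scale regimes with thousands of steps per epoch
  warrant 0.99).

Other conventions: predictions are clipped to $[\varepsilon_{ce},
1-\varepsilon_{ce}]$ before logs; two empty masks score as perfect agreement
(DSC = JSC = 100) and the event is logged; cohort intervals are
t-intervals over per-case scores (a percentile bootstrap is available);
paired comparisons use the two-sided paired t-test with $p = 1$ for
identical score vectors; confidence intervals are not clipped to
$[0, 100]$.

## Evaluation

Per case: DSC $= 200\,|A\cap B| / (|A|+|B|)$, JSC $= 100\,|A\cap B| /
|A\cup B|$, and their exact complements SVD $= 100 -$ DSC, VOE $= 100 -$
JSC — the complement identities hold per case to $10^{-9}$ and are asserted
throughout the test suite. Scoring is per image against the accurate
(`_truth` sidecar) masks, which are written for every generated sample and
never shown to training for noisy-tagged samples.

## A worked run

```{r example}
library(noisyseg)

dir <- tempfile("demo")
train <- generate_dataset(phantom_spec(), n = 16, noise_rate = 0.5,
                          out_dir = file.path(dir, "train"), seed = 1)
val <- generate_dataset(phantom_spec(), n = 4, noise_rate = 0,
                        out_dir = file.path(dir, "val"), seed = 2,
                        split = "val")
test <- generate_dataset(phantom_spec(), n = 10, noise_rate = 0,
                         out_dir = file.path(dir, "test"), seed = 3,
                         split = "test")

fit <- mpvt(train, val = val, backbone = desk_backbone(),
            control = desk_control(seed = 1), verbose = TRUE)
print(fit)
summarize_scores(evaluate_fit(fit, test))
```

The desk-scale studies are one call each:

```{r studies}
nrs <- noise_rate_study(seeds = 1:3)       # baseline vs label-noise rate
abl <- ablation_study(seeds = 1:3)         # component contributions
```

## Known limitations

* 2-D single-channel images only; no 3-D context, no multi-class heads.
* The backbone is a compact plain-convolution U-Net trained on the CPU; it
  is sized for the phantom task, not for transfer to clinical images.
* Annotator-identity-dependent noise is out of scope; corruption fields are
  binary-class only.
* The recovery diagnostics assume the noisy subset's corruption is
  (approximately) stationary; a plan whose corruption is dominated by
  large-scale structured operators is summarised only coarsely by two mean
  rates.
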