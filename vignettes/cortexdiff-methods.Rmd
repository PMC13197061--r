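---
title: "Anatomy-conditioned spherical diffusion for cortical normative modeling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomy-conditioned spherical diffusion for cortical normative modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Normative modeling asks how far an individual deviates from a healthy
reference distribution, region by region. On the cortex this is complicated
by folding variability: two healthy brains differ in where their gyri and
sulci sit, so comparing a patient's cortical thickness map against registered
healthy maps confounds disease effects with anatomical mismatch. The approach
implemented here sidesteps registration by *generating* the reference: a
conditional denoising diffusion model, trained only on cognitively normal
subjects, produces per-subject pseudo-healthy feature maps that share the
test subject's own gyral/sulcal anatomy, age and sex. Deviations of the
observed map from this personalized reference set become ROI-level
abnormality z-scores, which in Alzheimer's disease track cortical atrophy.

`cortexdiff` implements the full pipeline in R: the icosahedral spherical
domain and its operators, the diffusion model and its spherical UNet
denoiser, pseudo-healthy reconstruction, the abnormality score, a synthetic
cortical cohort generator, map-comparison metrics, and FreeSurfer-format
file I/O.

## The spherical domain

Cortical feature maps live on a sphere obtained by inflating each subject's
white-matter surface. We discretize the sphere as a hierarchical icosahedron:
order $k$ has $10\cdot4^k+2$ vertices, $30\cdot4^k$ edges, $20\cdot4^k$
faces. Full-resolution maps use order 6 (40,962 vertices); synthetic
desk-scale experiments use order 2 (162 vertices).

Three design choices make the hierarchy usable as a CNN grid, none of which
is canonical in the literature, so we fix them explicitly:

* **Orientation and reproducibility.** The base icosahedron has its two
  poles on $\pm z$ and golden-ratio latitude rings; subdivision inserts edge
  midpoints in sorted-edge order. Meshes are therefore bit-reproducible.
* **Prefix ordering.** Parent vertices come first, so the first
  $10\cdot4^{k-1}+2$ vertices of an order-$k$ sphere *are* the order-$(k-1)$
  sphere. Pooling is then literally "keep the prefix" and up-pooling
  "zero-pad the rest" — cheap, exactly adjoint, and free of the grid
  artifacts that neighborhood-averaging pooling introduces into generated
  samples.
* **Ring order and pentagons.** Convolution needs a canonical ordering of
  each vertex's 1-ring. We rotate the vertex to the north pole and sort
  neighbors by azimuth, starting at the smallest, ties broken by index. The
  twelve base vertices have valence 5; their seventh convolution tap repeats
  the center vertex (a "pentagon pad").

`resample_to_icosphere()` moves data between spherical meshes by central
projection and barycentric interpolation (exact for fields linear in the
embedding coordinates within a triangle); nearest-neighbor mode serves label
maps. `make_parcellation()` builds a geodesic-Voronoi partition from
farthest-point-sampled seeds as a synthetic stand-in for an anatomical atlas
such as Desikan–Killiany; its 34-region default matches that atlas's
per-hemisphere region count.

## The diffusion model

The forward process corrupts a clean map $x_0$ through
$q(x_t\mid x_{t-1})=\mathcal N(\sqrt{1-\beta_t}\,x_{t-1},\beta_t I)$, with the
closed-form marginal
$x_t=\sqrt{\bar\alpha_t}\,x_0+\sqrt{1-\bar\alpha_t}\,\epsilon$,
$\bar\alpha_t=\prod_{i\le t}(1-\beta_i)$. We use the cosine schedule
$\bar\alpha_t = f(t)/f(0)$, $f(t)=\cos^2\!\big(\tfrac{(t/T+s)}{1+s}\cdot
\tfrac\pi2\big)$ with offset $s=0.008$ and per-step $\beta_t$ clipped at
0.999; all stored quantities are recomputed from the clipped betas so the
schedule is self-consistent.

The network predicts the **velocity**
$v=\sqrt{\bar\alpha_t}\,\epsilon-\sqrt{1-\bar\alpha_t}\,x_0$, an exact
rotation of $(x_0,\epsilon)$ that is better conditioned than noise
prediction at both ends of the schedule; `x0_eps_from_v()` inverts it
exactly and tests require the round-trip to $10^{-10}$. Training minimizes
the simplified variational objective as a mean-squared error in $v$-space,
with $t$ drawn uniformly — the standard simplification in which the reverse
variance is not learned. The reverse step uses the forward-posterior mean
with fixed variance $\tilde\beta_t=\beta_t(1-\bar\alpha_{t-1})/(1-\bar\alpha_t)$,
adds no noise at $t=1$, and clips the implied $\hat x_0$ to $\pm 6$
standardized units by default (configurable) to keep early steps of the
chain from overshooting.

**Pseudo-healthy reconstruction.** For a test subject, `predict()` noises
the observed map `t_start` steps forward (500 of 1000 at full scale; $T/2$
of the desk-scale $T=250$ schedule — we interpret the step count in the
training schedule's own indices) and denoises it back with the subject's
mask, age and sex fixed, independently $N$ times ($N=10$ by default). The
partial noising destroys fine detail, including disease effects, while the
retained coarse signal and the anatomical conditioning keep the
reconstruction on the subject's own folding pattern.

## The denoiser

A UNet over the icosphere hierarchy: per level two residual blocks of
1-ring spherical convolutions, prefix pooling between levels, zero-pad
up-pooling with skip concatenation on the way up, and single-head
self-attention over vertices at the two coarsest levels (attention cost
grows quadratically in vertex count, which is why it is restricted to the
coarse levels). Full-scale widths are 128/256/512; the desk-scale default
(8/16/32 on an order-2 input) was chosen once as the smallest configuration
that trains to a clearly better-than-baseline denoiser on one CPU in a few
minutes, and is not tuned per experiment.

Conditioning enters two ways, mirroring the model's two condition types:

* **Anatomical.** The binary gyral/sulcal mask is encoded as a $-1/+1$
  channel and concatenated to the noisy input (one-hot for multi-class
  masks). The unconditional ablation simply drops this channel.
* **Demographic + time.** The step $t$ passes through a sinusoidal encoding
  and a two-layer MLP; age (years/100) and sex (0/1) each pass through their
  own small MLP; the three vectors are summed and injected into every
  residual block as a scale/shift (FiLM-style) modulation after the block's
  first convolution. The published description says only that demographic
  embeddings are "added to the time embedding"; the per-covariate MLPs,
  their widths and the scale/shift injection are our concrete choices, all
  exposed in `denoiser_config()`.

Normalization inside blocks is per-vertex channel normalization with learned
affine parameters — group normalization with a single group — chosen because
it is batch-independent, hence deterministic at inference. Initialization is
fan-in-scaled Gaussian, with the output convolution, FiLM projections and
attention output projections zero-initialized so the network starts as the
zero map, which stabilizes early training.

Because no deep-learning framework is available to R, the package carries a
small reverse-mode automatic differentiation engine on dense matrices
(`R/autodiff.R`). The forward pass is written once against its operations:
with plain matrices it computes eagerly (the inference path), with tracked
parameters it records a tape (the training path). Gradients of every
operation, and of the whole UNet loss, are verified against central finite
differences in the test suite. Training uses Adam with cosine annealing; the
desk-scale default peak rate is $2\times10^{-3}$, a standard small-network
setting (the published full-scale configuration trains at $10^{-5}$ for 1000
epochs on GPU hardware; both are configurable).

## Normative scoring

For ROI $i$ with subject ROI-mean $x_i$ and reference ROI-means
$x_{i,1},\dots,x_{i,N}$:

$$Z_i=\frac{x_i-\operatorname{mean}_j x_{i,j}}{\operatorname{std}_j x_{i,j}}.$$

The std uses the unbiased $N-1$ denominator; at $N=10$ the choice is
material, so it is an explicit argument. Scores default to cortical
thickness only, the accepted atrophy biomarker. ROIs with zero reference
spread receive a signed infinite sentinel, are flagged, and are dropped from
classification features. Two reference sets are supported: the model's $N$
reconstructions (`reference = "ddpm"`) and the $N$ age-closest training
subjects (`reference = "template"`), the registration-based baseline.
`classification_eval()` feeds per-subject score vectors to a linear-kernel
SVM under stratified 10-fold cross-validation (kernel and cost exposed; the
published experiments say only "standard SVM", so linear on raw scores is
the default).

## The synthetic cohort generator

The generator defines the study conditions for every test; its defaults are
fixed once and not revisited per experiment. Each subject draws a smooth
folding field $f$ (i.i.d. normal smoothed by 1-ring averaging, 10 rounds,
re-standardized); the gyral/sulcal mask is $f>0$; cortical thickness is

$$\mathrm{CT}=\gamma\,(2\,\mathrm{mask}-1)+\beta_{\mathrm{sex}}\,\mathrm{sex}
-\beta_{\mathrm{age}}\,\tfrac{\mathrm{age}-60}{10}+\sigma\,\eta$$

with smooth noise $\eta$, and the shape-index analog is $\tanh f$ plus
smooth noise. Disease subjects have $\delta$ (AD) or $\delta/2$ (MCI)
subtracted inside three designated ROIs. Defaults
$\gamma=0.5,\ \beta_{\mathrm{age}}=0.1/\mathrm{decade},\
\beta_{\mathrm{sex}}=0.1,\ \sigma=0.3,\ \delta=0.5$ (standardized units)
make the effects detectable at cohort sizes near 100 without being trivial.
Ages are uniform on 55–90 and sexes balanced, an ADNI-like range.

What the generator emulates: mask-correlated features (the signal the
anatomical conditioning exploits), linear demographic structure,
subject-specific anatomy, localized atrophy. What it does not emulate:
biophysically realistic folding geometry, nonlinear aging, measurement
artifacts, scanner effects, or spatial covariance structure beyond smooth
Gaussian fields. Tests passing on this cohort therefore demonstrate that the
machinery is correct and that the pipeline recovers planted effects under
its own assumptions — not that the model captures real cortical statistics.

## Numerical and scale choices

* Desk-scale problem sizes: order-2 sphere, $T=250$, 100 training subjects,
  2000 optimization steps, batch 4, $N=10$ reconstructions at
  $t_{\mathrm{start}}=T/2$. These are the package's own defaults for
  reproducible CPU-scale experiments; order 6, $T=1000$, $t_{\mathrm{start}}
  =500$ and widths 128/256/512 reproduce the published configuration on real
  data.
* The reverse-chain correctness test uses an analytic conditional-Gaussian
  oracle denoiser (for $x_0\sim\mathcal N(m,s^2)$ i.i.d. per vertex,
  $E[x_0\mid x_t]$ has closed form), which checks the sampler independently
  of any trained network.
* Spherical SSIM uses the 1-ring patch as its sliding window — the only
  canonical local neighborhood on the mesh — with the usual constants
  $c_1=(0.01R)^2$, $c_2=(0.03R)^2$.
* The Fréchet distance ships as the generic Gaussian core with a pluggable
  embedding (default: per-ROI mean vectors). The published FID pipeline
  renders surface snapshots through a pretrained 192-dimensional image
  embedder whose identity is not stated; we deliberately do not guess it.
* Degenerate inputs: empty ROIs yield NaN means; zero-spread reference sets
  yield infinite sentinel scores; malformed binary files are rejected with
  byte offsets rather than coerced.

## Known limitations

* The denoiser trains on CPU via the package's own autodiff; it is intended
  for desk-scale spheres (orders 1–4). Order-6 training at published widths
  would require a GPU framework.
* Pseudo-healthy reconstruction inherits the usual partial-noising
  trade-off: too small a $t_{\mathrm{start}}$ preserves disease effects, too
  large discards individual anatomy; the 500-step (half-schedule) default
  follows the published empirical choice and is not re-derived here.
* Only the left hemisphere is modeled; the right can be handled by
  symmetric reuse but has no dedicated support.
* `classification_eval` reports fold-averaged metrics on modest test sets;
  at desk scale its variance across seeds is substantial, and it is meant as
  a direction check, not a benchmark.
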