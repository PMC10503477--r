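---
title: "Methods: separating size from maturation in neonatal piglet gait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separating size from maturation in neonatal piglet gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigletgait)
```

## The problem

Low-birth-weight (SGA) piglets are reported to be less mobile and less
vital than their normal-weight (AGA) littermates during the first days of
life. Any comparison of their locomotion, however, confounds two causes:
SGA piglets are roughly half the body mass of AGA piglets, and smaller
animals necessarily walk with shorter strides, higher frequencies and
lower absolute speeds even when their motor control is identical. This
package implements a pipeline that removes the size axis (dynamic
similarity), quantifies posture and coordination free of size
(Fourier-domain joint kinematics), compares whole force curves
(permutation SPM), and finally asks a trained model the inverse question:
given only how the animal walks, how heavy, large and old do you think it
is?

Because stride-level recordings of this kind are not publicly archived,
the package ships a synthetic cohort generator that embodies the
statistical structure the analyses assume. All tests and the acceptance
script run on generated data; nothing in the package is fitted to
figures of any experimental dataset.

## Dynamic-similarity normalization

Two motions are dynamically similar when one maps onto the other with a
single length factor $\alpha$, time factor $\beta$ and force factor
$\gamma$; under constant gravity, consistency requires
$\beta = \sqrt{\alpha}$ and $\gamma = \alpha^3$. With midstance hip
height $h$ as the functional limb length,

$$\hat V = \frac{V}{\sqrt{hg}}, \qquad \hat L = \frac{L}{h}, \qquad
\hat F = F\sqrt{h/g},$$

and forces in body weights. The identity $\hat V = \hat L \, \hat F$
holds for every internally consistent stride and is enforced to $10^{-9}$
in tests. The scale invariance of every dimensionless output under a
consistent $(\alpha, \sqrt{\alpha}, \alpha^3)$ transform is verified to
$10^{-10}$.

Choices here: $g$ defaults to 9.81 m/s² and is overridable. The hip
height column is taken as given (no proxy reconstruction from marker
data). Relative limb phases are referenced to left-hind touchdown; the
reference limb is a documented convention, not a measurable claim.
Whether "step length" is per-limb or limb-averaged differs between
laboratories, so the stride table carries fore and hind step lengths
separately.

## Joint kinematics in the Fourier domain

Each joint-angle cycle $\theta(t)$ (interior angle, radians, $\pi$ =
fully extended, cycle anchored at limb touchdown) is uniformly resampled
(periodic linear interpolation) and decomposed as

$$c_n = \frac{1}{N}\sum_k \theta(t_k)\, e^{-i 2\pi n k / N},
\qquad n = 0, \ldots, 8 .$$

Eight harmonics describe walking profiles; the Nyquist condition
$N \ge 17$ is enforced. The posture/shape split is

$$\text{mean} = c_0, \qquad
A = \sqrt{2 \sum_{n\ge1} |c_n|^2}, \qquad s_n = c_n / A .$$

$A$ is the RMS oscillation amplitude (a pure cosine of amplitude $a$
gives $A = a/\sqrt2$). This definition, rather than half peak-to-peak,
makes the split exactly affine: $\theta \mapsto s(\theta - \bar\theta)
+ m$ leaves every $s_n$ unchanged, which is tested to $10^{-10}$. The
shape spectrum of a real signal is two-sided ($s_{-n} = \bar s_n$), so
the stored one-sided vector satisfies $2\sum_n |s_n|^2 = 1$. Cyclic time
shifts rotate $s_n$ by $e^{-i2\pi n\Delta}$; no phase normalization is
applied by default, because cycles are already anchored at touchdown —
phase differences between animals are real coordination information, not
nuisance.

The pooled shape block (6 joints × 16 real values = 96 columns) enters a
column-centered PCA without per-column standardization (the coefficients
are already commensurate and unit-free); 12 components are retained as
coordination variables, with a deterministic sign convention
(largest-magnitude loading element positive). Normalized shape values —
not raw coefficients — enter the PCA, so amplitude information lives
exclusively in the posture block.

Group comparisons (6 mean angles, 6 ranges of motion, 12 PCs) use a
Bayesian linear model $y = \mu + \delta\,\mathbb 1[\text{group B}]$ under
a vague normal-inverse-gamma prior, giving a Student-t posterior for
$\delta$ summarized by seeded Monte-Carlo draws. Zero-variance variables
collapse to a point interval and are flagged rather than dropped.

## Permutation SPM for force curves

Stance-phase GRF recordings are linearly interpolated onto 51 nodes (50
intervals) over stance fractions $[0,1]$. Whole curves are compared with
a nonparametric analogue of statistical parametric mapping: a pooled-
variance t statistic per node, a critical threshold equal to the
$(1-\alpha)$ quantile of the permutation distribution of
$\max_t |t|$ under group-label relabeling, and cluster p-values from the
permutation distribution of the maximum suprathreshold cluster extent.
When the number of distinct relabelings is small the test enumerates all
of them and is exact. A random-field-theory implementation would make
Gaussian smoothness assumptions; the permutation construction targets the
same cluster-level inference while remaining fully self-contained, and
its cluster-wise false-positive rate is verified empirically (100 null
replicates × 1000 permutations) in the test suite.

Note one deliberate property choice: as an injected effect grows,
suprathreshold clusters can merge, so the *number* of clusters is not
monotone in effect size; the total suprathreshold extent and the smallest
cluster p-value are, and those are the tested monotonicity properties.
Stance halves are also supported (`split_stance_halves()`), with the
midstance node assigned to both halves so each half is a closed interval.
Medio-lateral forces are out of scope throughout.

## Muscle capacity and allometry

PCSA = mass / (density × fibre length) with density 1060 kg/m³; per-limb
extensor PCSAs are summed and multiplied by a 0.3 MPa muscle stress;
capacity is reported in body weights. Under isometric growth PCSA scales
as $BM^{2/3}$, so capacity in BW falls as $BM^{-1/3}$ — the generator
reproduces this exactly at zero noise and the tests assert it.

Huxley's model $\text{part} = a\,BM^b$ is fitted in log space by OLS:
closed-form, exactly recovering noise-free power laws, with a
normal-theory 95% CI on $b$ from the slope standard error (the evaluation
method for the exponent is not standardized in the literature; the
normal-theory slope CI is the conventional choice). A raw-space
Levenberg–Marquardt fit is available behind `method = "raw"` for
sensitivity analysis; plain Gauss–Newton stalls on zero-residual data,
which is why the raw path uses `minpack.lm`.

## Bayesian trait models

The feature vector has 34 entries: sex, 9 dimensionless spatiotemporal
variables (Froude speed, relative stride length, fore/hind relative step
lengths, relative frequency, fore/hind duty factors, two relative
phases), 12 postural variables (6 mean angles, 6 amplitudes) and 12
coordination PCs, with the PCA loadings frozen on the training strides.
Which nine spatiotemporal predictors enter is a genuine design opening;
the set above covers speed, geometry, timing and interlimb phasing while
staying fully dimensionless, and is documented so it can be changed.

The model is an identity-link Gaussian linear model with standardized
predictors and a conjugate normal-inverse-gamma prior: coefficients
$N(0, 1)$ on the standardized scale, intercept $N(0, 2^2)$ (i.e. the
target mean ± two target sds), residual variance Inv-Gamma(3, 2). The
posterior and the Student-t posterior predictive are closed form, so a
fitted model is exactly reproducible — no Monte-Carlo tolerance is
needed — and predictions are invariant to affine rescaling of any raw
feature column (tested to $10^{-8}$). A sampling-based variant with a
half-normal scale prior was considered and rejected: on this model class
it changes posteriors negligibly while costing reproducibility and run
time. Central 90% predictive intervals are the default report; their
empirical coverage on well-specified held-out data is verified at
90% ± 3pp on 500 strides.

The "age-stall" experiment freezes SGA maturation at 4 h while AGA
animals mature normally, trains the age model on AGA strides and counts
how often older SGA strides are read as younger. Its default
configuration zeroes the static SGA knee/tarsal offsets: those offsets
are age-independent posture differences which would masquerade as an age
signal and confound the maturation effect the experiment isolates. The
magnitude of the behavioural stall in real animals is not something this
package asserts; it is an exposed parameter, and the reported fraction is
a measured output.

## The synthetic cohort generator

The generator's defaults are the study conditions: 14 AGA + 11 SGA
piglets followed at 0–96 h postpartum (longitudinal design) or 50 AGA + 8
SGA at 1–10 h (cross-sectional kinematics design); AGA birth mass
normal around 1.4 kg, SGA around 0.7 kg truncated below the 0.8 kg
category threshold (≈50% gap); exact isometric segment scaling
($\ell \propto BM^{1/3}$); band-limited joint cycles built in the
coefficient domain (so round-trip exactness holds even with noise);
double-hump vertical GRFs whose stance-time-weighted means close the
four-limb support balance at 1 BW; knee/tarsal SGA offsets of −11° and
−6°; lognormal 5% noise on body-part masses around $0.41\,BM^{1.02}$ and
$0.38\,BM^{1.16}$.

Postural maturation is a saturating exponential
$M(t) = p\,(1 - e^{-t/\tau})$ with $\tau = 8/\ln 10 \approx 3.47$ h, so
90% of the plateau is reached by 8 h. The headline postural change —
a 28% rise in midstance hip height — is measured between the 1 h and 28 h
observations, not from birth; since $M(1\,\text{h})$ is already ≈ 25% of
the plateau, calibrating the *measured window increase* to 28% requires a
plateau of

$$p = \frac{g}{m(t_2) - (1+g)\,m(t_1)} \approx 0.412,
\qquad m(t) = 1 - e^{-t/\tau},$$

which `calibrate_maturation()` computes (a naive plateau of 0.28 would
yield only a ≈19.6% measured increase). Hip height is
$h = k\,BM^{1/3}(1 + M(t))(1 - \text{flexion penalty})$, with a 6%
persistent flexion penalty for SGA animals and $k = 0.10$ m·kg$^{-1/3}$
(giving a ≈0.14 m mature hip height for a 1.4 kg piglet, a realistic
neonatal-pig magnitude). Strides are drawn in dimensionless form (Froude
speed 0.35 at maturity with a 25% deficit at birth, relative stride
length 1.15, duty factor 0.65, lateral-sequence phases 0.5/0.25/0.75) and
mapped to absolute units through $h$, which makes zero-noise cohorts
exactly dynamically similar across body sizes — the property the
normalization module is tested against.

One root seed drives named substreams (piglets, strides, joint traces,
GRFs, muscles, energetics), so adding a stage never perturbs earlier
draws and equal config + seed gives byte-identical CSVs.

What the generator does **not** emulate: multibody dynamics, suckling
competition, within-litter correlation structure, marker/digitization
error models, medio-lateral forces, or individual real animals. Passing
tests therefore demonstrate that the pipeline recovers known structure
under its stated assumptions — not that those assumptions hold in any
particular barn.

## Numerical choices and degenerate inputs

* Fourier resampling is periodic linear interpolation; coefficients of a
  downsampled single-harmonic trace are preserved to interpolation order
  $O(h^2)$ (≈ $5\times10^{-5}$ when going from 100 to 64 samples), which
  is why exact round-trip guarantees are stated only for traces sampled
  on their own grid.
* Constant traces: amplitude is clamped to zero (and the shape vector
  with it) when $A$ is at floating-point noise level, avoiding 0/0 shape
  ratios.
* PCA on rank-deficient input simply returns fewer informative
  components; identical rows give all-zero scores.
* Zero-variance variables in group comparisons collapse to point
  intervals and are flagged `degenerate`.
* `normalize_stride_table()` drops rows with missing or non-positive hip
  height with a counted warning rather than failing the batch.
* The SPM resampler is idempotent on conforming grids and preserves
  trapezoid means of smooth curves to $O(\text{grid}^2)$.

## Problem sizes used in the shipped tests

The default test suite runs cohorts of 7–58 piglets (up to 450 strides),
200 allometric replicates, 100 SPM null replicates × 1000 permutations,
and 500 held-out strides for coverage — sizes chosen to give stable
Monte-Carlo estimates of each property while keeping a full run in tens
of seconds. All fixtures are generated in code at run time.
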