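---
title: "Circular tone spaces, perceptual circularity, and mixture models of auditory reproduction error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular tone spaces, perceptual circularity, and mixture models of auditory reproduction error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circtone)
```

This vignette is the package's account of its own methods: the models it
implements, the parameters that matter, what the synthetic-data generators
do and do not emulate, and the numerical and design choices that were
genuinely open.

## 1. The circular Shepard-tone space

A Shepard tone complex is a sum of sinusoids at octave spacings whose
amplitudes follow a fixed bell-shaped spectral envelope. Because every
component has an octave neighbor fading in as it fades out, the complex has
a definite pitch *chroma* but an ambiguous pitch *height*; sweeping the
fundamental through one octave returns to a perceptually identical sound.
That closure is what lets a one-octave range serve as a 360-degree circular
response dimension.

The degree-to-frequency convention is

$$f(d) = 278.4375 \times 2^{(d-1)/360} \ \text{Hz}, \qquad d \in [1, 360],$$

i.e. degree 1 anchors the base fundamental and each degree multiplies
frequency by $2^{1/360}$; degree 360 sits one step *below* the octave, so
the step from 360 back to 1 equals every other step. Real-valued degrees
are allowed (continuous report). This convention reproduces every entry of
the published tone table to two decimals (441.14 Hz at 240°, 555.80 Hz at
360°, and so on); the alternative anchoring sometimes quoted (279.2109 Hz
at 1°) matches none of the tabulated values and is not a $2^{k/360}$
multiple of the base, so the table's convention is the one implemented.

**Components and envelope.** For a fundamental $f$, the components are all
$f \cdot 2^k$ (integer $k$) inside the half-open band $[30, 16000)$ Hz —
half-open because the canonical worked example for a 500 Hz fundamental
includes 31.25 Hz but not 16 kHz. Amplitudes follow
$\cos^2\!\big(\pi (\ell - c) / (2h)\big)$ where $\ell = \log_2 f$ and $c$,
$h$ are the midpoint and half-width of the log band. The envelope is
*fixed over the band*, not centered on the fundamental: a
fundamental-centered envelope would make degree 360 audibly different from
degree 1 and destroy the circularity the space exists to provide. The
amplitude profile therefore changes continuously across the 360-to-1 wrap,
which the test suite asserts.

**Remaining synthesis choices.** Component phases are all zero (sine
phase), which keeps output deterministic; the ear is insensitive to the
relative phase of components an octave apart at these durations. On/off
ramps are 10 ms raised-cosine, the conventional click-prevention window.
Peak amplitude is normalized to 0.99. All in-band components are kept; the
envelope itself drives edge components to sub-threshold amplitude, so no
separate threshold parameter is needed. Audio is written as 16-bit PCM
mono WAV at 44.1 kHz. For recognition-task stimuli, `dmst_tone_set()`
builds 12 semitone-spaced pure tones anchored at 1000 Hz; anchoring at
1000 Hz means tone 13, not tone 12, closes the octave at 2000 Hz — twelve
tones at factor $2^{1/12}$ cannot both start at 1000 and end at 2000, and
the anchored reading preserves the stated spacing.

## 2. Quantifying perceptual circularity

The pipeline turns trial-level similarity ratings into a single circularity
number:

1. **Exclusion.** Participants whose mean rating on identical-pair trials
   is below 4 (on the 0–5 Likert scale) cannot discriminate the tones and
   are dropped.
2. **Aggregation.** Ratings of each unordered pair are averaged regardless
   of presentation order, giving a symmetric matrix per participant.
3. **Reverse coding.** Group dissimilarity is $5 - \bar{s}$, the scale
   maximum minus the mean similarity. (Averaging before or after this
   linear recoding is equivalent; the package averages first.)
4. **Embedding.** Metric MDS by SMACOF stress majorization: classical
   scaling (`stats::cmdscale`) initializes, Guttman transforms iterate to
   a relative stress tolerance of 1e-9 with a 300-iteration cap, and
   stress-1 is reported. The majorization loop is implemented in the
   package; classical scaling serves as an independent cross-check in the
   tests on exactly embeddable inputs.
5. **Alignment and combination.** When two participant sets rated
   interleaved tone subsets sharing three anchor tones 120° apart, the
   second configuration is mapped onto the first by the least-squares 2-D
   affine transform fitted on the anchors (exact for three non-collinear
   anchors; reflections allowed, since MDS orientation is arbitrary), and
   anchor duplicates are averaged.
6. **Closure and scoring.** Points ordered by *stimulus* degree — known by
   design, and more robust than ordering by embedded angle when noise
   perturbs the shape — are interpolated coordinate-wise by a periodic
   cubic spline in the degree parameter (`stats::spline`,
   `method = "periodic"`), sampled at 1000 points, and scored with
   $C = 4\pi A / P^2$ (shoelace area, summed segment perimeter). Both the
   splined and the raw polygon $C$ are reported.

$C$ is invariant to rotation, translation, reflection and uniform scaling,
and bounded by 1 (isoperimetric inequality); a regular $n$-gon scores
$(\pi/n)\cot(\pi/n)$, which the tests verify to 1e-9 against the shoelace
route. Doubling the spline sampling changes $C$ by under 1e-4, so 1000
samples is comfortably converged. Self-intersecting paths are not expected
from valid data and are handled with a warning plus absolute signed area
rather than failure; zero-area input is an error. A value of 0.9 is the
conventional threshold for "nearly perfect" circularity — a regular
hexadecagon already scores 0.99.

## 3. Mixture models of circular reproduction error

Errors are signed wrapped angles $x \in (-180°, 180°]$ (the boundary maps
to +180). The standard mixture holds that a response is either a noisy
read-out of the stored target (von Mises around 0 with circular SD
$\sigma$) or a memoryless guess (uniform), with guess rate $g$:

$$f(x; g, \sigma) = (1-g)\,\phi\big(x, \kappa(\sigma)\big) + g \tfrac{1}{2\pi}.$$

The swap model adds responses centered on non-probed items at relative
positions $x_m$, with swap rate $\beta$:

$$f(x; g, \sigma, \beta) = g\tfrac{1}{2\pi} + (1-g-\beta)\,\phi\big(x,\kappa(\sigma)\big) + \tfrac{\beta}{m}\sum_i^m \phi\big(x_m, \kappa(\sigma)\big).$$

With $\beta = 0$ the swap model reduces pointwise to the standard mixture,
which the tests assert to 1e-12, and both densities integrate to 1 over
the circle to 1e-8.

**The $\kappa(\sigma)$ map.** Circular SD converts to concentration by the
wrapped-normal correspondence $\bar R = \exp(-\sigma_r^2/2)$,
$\kappa = A_1^{-1}(\bar R)$ with $A_1(\kappa) = I_1(\kappa)/I_0(\kappa)$,
the convention of the established memory-modeling toolboxes. $A_1^{-1}$
is computed numerically (Fisher's piecewise approximation as a Newton
start, refined to 1e-10; exponentially scaled Bessel functions avoid
overflow), and the roundtrip is exact to better than 1e-6. Beyond roughly
150° the map saturates toward $\kappa = 0$.

**Fitting.** Maximum likelihood with multi-start Nelder–Mead on
transformed parameters: $g$ through a logistic map, $(g, \beta)$ through a
softmax onto the simplex $g + \beta \le 1$, and $\sigma$ boxed to
$[0.5, 100]$ degrees by a logistic map. Six grid starts cover the
parameter space; the best final likelihood wins. The fitted likelihood is
never below the likelihood at the generating parameters on the same data
(a test invariant), fits are permutation-invariant, and estimation error
shrinks with $n$. Fits need at least 20 errors (50 for swap);
all-identical errors produce a boundary fit with a warning. `fit_mixture()`
returns a classed object with the usual `print`, `summary`, `coef`,
`logLik`, `predict`, `residuals`, `simulate` and `plot` methods.

**Simulation.** `simulate_standard()` / `simulate_swap()` sample the
mixture exactly: a component label per trial, uniform draws for guesses,
Best–Fisher rejection sampling for von Mises noise, the swap component
centered on a uniformly chosen non-target. Everything is reproducible
under a seed.

## 4. What the synthetic generators emulate — and what they do not

`gen_similarity_study()` emulates the two-set similarity design: nine
tones per set on a 24° grid (sets interleaved, three shared anchors 120°
apart), eight ratings per unordered pair plus two self-comparisons per
tone, 14 participants per set with two per set planted to fail the
exclusion rule — 28 in, 24 retained, matching the reference design. The
mean rating declines linearly with circular distance,
$\mu(\Delta) = a - b\Delta$ with $a = 4.274$, $b = 0.01226$ — the line
through the two usable published means (3.98 at 24° and 1.92 at the far
pairs); Gaussian noise (SD 0.7) is added and the result rounded and
clamped to the integer scale. Self-similarities are Normal(4.8, 0.3),
clamped.

Two honest caveats. First, positions 168° and 192° are *both* 168° of
circular distance from 360° (circular distance caps at 180°), so a
generator whose mean is a function of circular distance necessarily gives
those pairs one common mean; the two different published values for them
(2.32 and 1.92) reflect sampling variability that a symmetric generator
cannot and should not reproduce. The tests assert the attainable means and
the symmetry itself. Second, integer rounding is a coarse quantizer: with
the noise term switched off entirely it collapses the scale to three
levels and flattens the recovered shape ($C \approx 0.75$), which is a
property of quantization, not of the space. The generator therefore has a
`discretize` switch; noise-free validation runs use real-valued ratings
(the pipeline accepts any ratings in $[0, 5]$), while the default noisy
generator leaves discretization on — the noise dithers the quantizer, as
in real data, and the full default study recovers $C \approx 0.96$.

The generators do not emulate reaction times, adaptation or masking,
serial-position perceptual effects, or any participant-level
heterogeneity in the mixture parameters: passing tests show the pipeline
recovers what was planted under the stated statistical structure, not that
human data will be as well-behaved.

`gen_reproduction_study()` emulates the delayed-estimation session: 4
blocks of 50 trials per participant, equal trial counts per set size in
random order, targets uniform on 1–360°. Set-size-1 errors come from the
standard mixture at the published set-size-1 estimates (guess 18%, SD
29.1°); set-size-2 trials receive one uniformly placed non-target and
errors from the swap model at the published decomposition (guess 18%,
swap 11%, SD 30.65°); the probed position is uniform. These defaults are
the study conditions, not tuning knobs.

## 5. Problem sizes and reproducibility

The recovery studies simulate 3000 trials per round and average estimates
over 20 seeded rounds — enough for the mean guess rate to stabilize within
about half a percentage point and the mean SD within a few tenths of a
degree, while a full suite run stays under a minute. The acceptance script
derives every stream from one `--seed`, and all generators take explicit
seeds; identical seeds give byte-identical outputs, which the tests check
end to end.

## 6. Known limitations

* The envelope question — whether the original generator fixed the
  spectral envelope over the band or tied it to the fundamental — cannot
  be settled from the published description alone; the fixed-envelope
  reading is implemented because it is the one consistent with a circular
  percept and with the classic construction.
* Metric (ratio) SMACOF is the only MDS flavor offered; ordinal MDS and
  3-D embeddings are out of scope.
* The similarity-vs-distance law is modeled as linear because only two
  published distance means constrain it; an exponential decay would fit
  the same two points and differ in between.
* Per-participant fitting is supported (`fit` CLI, `--by participant`),
  but small per-participant trial counts make single-participant swap
  fits noisy; pooled fits are the default.
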