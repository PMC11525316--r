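# circtone

Tools for auditory working-memory research with circular stimulus spaces:
Shepard-tone synthesis, quantitative assessment of perceptual circularity,
and von Mises mixture modeling of circular reproduction errors.

## The problem

Continuous reproduction ("delayed estimation") tasks drove a decade of
progress in visual working memory: a feature is drawn from a perceptually
circular, uniform space (color angle, orientation), reproduced on a
continuous dial, and the error distribution is decomposed by mixture models
into memory states. Audition has lacked an equivalent space. Shepard tone
complexes — sums of octave-spaced sinusoids under a fixed bell-shaped
spectral envelope — supply one: they carry a clear pitch *chroma* but an
ambiguous pitch *height*, so a one-octave sweep of the fundamental wraps
seamlessly back onto itself, turning pitch into a 360° circle.

`circtone` implements the full method stack for working with such a space:

1. **Synthesis** (`tone_space()`, `shepard_tone()`, `write_wav()`). Degree
   *d* of the circle maps to fundamental
   *f*(*d*) = 278.4375 · 2^((*d*−1)/360) Hz, so each degree step is a factor
   2^(1/360) and 360° sits one step below the octave. Components are all
   octave transpositions inside [30, 16000) Hz, weighted by a fixed
   cos² envelope in log₂ frequency, renormalized, ramped, and written as
   16-bit PCM WAV.

2. **Circularity assessment** (`circularity_report()` and its stages).
   Trial-level pairwise similarity ratings (Likert 0–5) are screened by a
   self-similarity exclusion rule, aggregated to symmetric per-participant
   matrices, reverse-coded into group dissimilarities, embedded in 2-D by
   metric MDS (SMACOF stress majorization), affine-aligned across
   participant sets via shared anchor tones, closed with a periodic cubic
   spline, and scored with the circularity quotient

   > C = 4π · Area / Perimeter²,

   which is 1 for a perfect circle, (π/n)·cot(π/n) for a regular n-gon
   (0.99 for a hexadecagon), and ≥ 0.9 is used as the threshold for "nearly
   perfect" circularity.

3. **Mixture models of reproduction error** (`fit_mixture()` and the
   `mixture_fit` methods). Signed wrapped errors x ∈ (−180°, 180°] are fit
   by maximum likelihood under the standard mixture

   > f(x; g, σ) = (1−g)·φ(x; κ(σ)) + g/2π

   (φ a von Mises density centered on the target, g the guess rate) and the
   swap model

   > f(x; g, σ, β) = g/2π + (1−g−β)·φ(x; κ(σ)) + (β/m)·Σₘ φ(x−xₘ; κ(σ)),

   which adds responses centered on the m non-probed items (swap rate β).
   κ(σ) uses the wrapped-normal correspondence κ = A₁⁻¹(exp(−σ²/2)).

4. **Synthetic data** (`gen_similarity_study()`,
   `gen_reproduction_study()`). Seeded generators emulate both study
   designs — ratings whose mean declines with circular distance, and
   reproduction trials drawn from the mixtures — so the entire pipeline is
   testable without participants.

5. **Command line** (`run_cli()`, `inst/cli/circtone`): subcommands
   `synth`, `circ`, `fit`, `simulate`, `report`.

## Worked example

```r
library(circtone)

sp <- tone_space()
shepard_tone(240, sp)
#> Shepard tone at 240 degrees (fundamental 441.14 Hz)
#>   9 octave components in [55.14, 1.412e+04] Hz; 22050 samples at 44100 Hz

# a full synthetic similarity study through the circularity pipeline
ratings <- gen_similarity_study(seed = 11)
circularity_report(ratings)
#> Circularity analysis of a similarity-rating study
#>   participants retained : 24 (excluded: P01, P02, P15, P16)
#>   MDS stress-1 per set  : 0.0931, 0.0871
#>   circularity C         : 0.956 (splined), 0.948 (polygon)

# swap-model decomposition of synthetic two-item reproduction errors
trials <- gen_reproduction_study(seed = 11)
ss2 <- subset(trials, set_size == 2)
fit_swap(wrap_angle(ss2$response_deg - ss2$target_deg),
         wrap_angle(ss2$nontarget_deg - ss2$target_deg))
#> Swap mixture model fit (n = 1800)
#>   guess rate g : 0.148
#>   swap rate b  : 0.117
#>   circular SD  : 31.82 degrees (kappa = 3.840)
#>   log-likelihood: -2347.64
```

The report says: of 28 simulated raters, the 4 planted poor discriminators
were excluded; the recovered perceptual space is nearly perfectly circular
(C above the 0.9 threshold); and the two-item error distribution decomposes
into ≈15% random guesses, ≈12% responses to the wrong item, and on-target
responses with ≈32° of circular spread — close to the generator's planted
values (18%, 11%, 30.65°).

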