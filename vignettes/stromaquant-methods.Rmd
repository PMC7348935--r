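---
title: "Quantifying engineered airway stroma: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying engineered airway stroma: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromaquant)
```

stromaquant quantifies 3D bioengineered connective-tissue models of the
airway stroma — cell-seeded micro-tissues and the disc-shaped tissues formed
by fusing them — along four complementary axes: how much collagen the cells
deposited (SHG bright-pixel fraction), how coarse the collagen network is
(GLCM correlation length), how the tissue is built at the cell level
(nuclei counts, protein area per cell, micro-tissue diameter), and how stiff
it is (spherical nano-indentation modulus). A transcriptomic post-processing
arm (expression filtering, fold-change/FDR thresholding, and the concordance
partition of two contrasts) and one-way ANOVA with Tukey HSD complete the
stack. Every input class has a synthetic generator with exact ground truth,
so the whole pipeline is testable without any proprietary raw data.

This vignette explains the models behind each stage, the tunable parameters
and their defaults, what the generators do and do not emulate, and the
design decisions taken where the methodology was genuinely open.

## Collagen fraction

The collagen fraction of a second-harmonic-generation (SHG) image is the
percentage of bright pixels in a region of interest:

$$\mathrm{CF}\,(\%) = \frac{N_c}{N_b + N_c} \times 100,$$

with $N_c$ the pixels at or above an intensity threshold ("collagenous") and
$N_b$ the rest. The package accepts an ROI mask and a separate exclusion
mask (typically the micro-scaffold signal, which is not collagen); exclusion
is an input, never inferred, because scaffold appearance varies with the
imaging setup. The threshold method is deliberately explicit: the default is
Otsu's histogram threshold (256 bins over the observed intensity range), a
fixed numeric value can be forced, and the value actually applied is always
returned — reproducibility by logging rather than by guessing a particular
software's default. A constant image has no Otsu threshold and errors
instead of returning an arbitrary split.

`collagen_fraction()` is monotone non-increasing in a fixed threshold, stays
in $[0, 100]$, and conserves pixels ($\mathrm{CF}(\ge t) + \mathrm{CF}(< t)
= 100$); the test suite asserts all three.

## GLCM correlation length

Texture coarseness is measured with the correlation feature of the
gray-level co-occurrence matrix. The image is linearly quantized to $G$ gray
levels (default $G = 64$; the value is configurable and recorded because
plugin conventions differ). For an offset $(d_x, d_y)$ the GLCM collects the
joint frequencies $p(i, j)$ of level pairs at that offset over all in-bounds
pixel pairs; by default the reversed pairs are counted too (symmetric GLCM),
which makes the correlation independent of the offset sign — the natural
choice when distances are reported unsigned. The correlation

$$C = \sum_{i,j} \frac{(i - \mu_i)(j - \mu_j)\,p(i,j)}{\sigma_i \sigma_j}$$

is exactly the Pearson correlation of the quantized levels over the
pixel-pair sample, and the tests verify that identity against brute-force
pair enumeration at $10^{-10}$ tolerance.

`correlation_curve()` evaluates $C(d)$ for $d = 1 \dots d_\max$ (default
100 px) along the horizontal and vertical offsets, normalizes each
direction's curve by its $d = 1$ value, and averages the two directions.
Averaging before fitting is the symmetric pooling choice; per-direction fits
remain available via the `direction` argument.

The correlation length $\lambda$ is the scale parameter of an exponential
decay fitted by nonlinear least squares on the linear scale (large-$d$
values can be slightly negative, which rules out log-space fitting):

$$C(d) = A\,e^{-d/\lambda}.$$

The amplitude is fitted rather than pinned at 1. A curve normalized to its
first distance equals $e^{-(d-1)/\lambda}$, i.e. $A = e^{1/\lambda}$;
forcing $A = 1$ inflates $\lambda$ by roughly $1/\lambda$ in relative terms,
which is material for fine textures (about +20% at $\lambda = 5$ px) and
negligible for coarse ones. With $A$ free, recovery on synthetic fields is
unbiased across $\lambda \in \{5, 10, 20, 50\}$ px (median within ~6% on
1024² fields in the acceptance suite), and an exact unnormalized exponential
$e^{-d/35}$ is recovered with $A = 1$, $\lambda = 35$. A fit whose $\lambda$
reaches the bound $10\,d_\max$ is flagged non-decaying and reports no
length — white noise lands here or at $\lambda \le 2$ px.

**Known limitation.** Only the two axis directions are sampled, as is
conventional for this feature. A strongly oriented straight-fiber texture
whose axis coincides with a sampling direction yields a non-decaying curve
in that direction and an inflated average $\lambda$; the ordering tests
therefore sample texture orientations away from the image axes. Real
collagen is curvilinear and rarely globally axis-aligned, but images of
strongly aligned samples should be interpreted with this in mind.

## Morphometry

Nuclei are counted as 8-connected components of the thresholded DAPI
channel with area at least `min_area` (default 20 px², a speck filter).
8-connectivity matches the common particle-analysis convention. Touching
nuclei merge into one component and are counted once: no watershed split is
attempted, because no separation rule was part of the quantification being
reproduced, and silent over-segmentation is worse than a documented
undercount. Counting is invariant to affine intensity rescaling when the
threshold is rescaled identically.

Protein per cell is the thresholded fluorescent area in µm² (pixel count
times `pixel_size`²) divided by the nuclei count; a zero count is an error,
not an infinity. Micro-tissue diameter is the equivalent circular diameter
$2\sqrt{A/\pi}$ of the largest thresholded component — the natural scalar
for near-spherical micro-tissues — with the maximum Feret diameter
available behind `method = "feret"` for elongated objects. All areas are
kept in px² internally and converted by `pixel_size`² only at the reporting
boundary; coordinates are 0-based `(row, col)`.

Replicate fields of view aggregate as mean ± sample SD ($n - 1$); a single
value reports `NA`, not 0.

## Spherical nano-indentation

A displacement-controlled indenter drives a spherical probe (radius $R$,
default 53.5 µm) on a cantilever (stiffness $k$, default 4.53 N/m) into the
sample to ~10 µm depth. The piezo travel $z$ splits into cantilever
deflection $P/k$ and true indentation $h$:

$$h = (z - z_0) - P/k,$$

with $z_0$ the contact point. Load and depth are converted to indentation
stress and strain through the Hertzian contact radius $a = \sqrt{Rh}$:

$$\sigma_{ind} = \frac{P}{\pi a^2}, \qquad
  \varepsilon_{ind} = \frac{4}{3\pi}\,\frac{h}{a}\,\frac{1}{1 - \nu^2},$$

definitions chosen so that their ratio reduces exactly to the Hertz relation
$P = \tfrac{4}{3}\,\tfrac{E}{1-\nu^2}\sqrt{R}\,h^{3/2}$: for a
linear-elastic sample $\sigma_{ind}/\varepsilon_{ind} = E$ at every depth
(the tests assert constancy to $10^{-6}$ relative on exact curves). The
modulus is the slope of a zero-intercept least-squares fit of
$\sigma_{ind}$ on $\varepsilon_{ind}$ over the depth range — using the whole
record is robust to load noise — with the pointwise ratio (mean ± SD)
available as `method = "pointwise"`. Both $E$ and the reduced modulus
$E^* = E/(1-\nu^2)$ are reported, since instrument software differs in which
it prints. The Poisson ratio defaults to 0.5 (incompressible soft tissue)
and is configurable; only the loading segment is analyzed, and viscoelastic
or adhesive models are out of scope.

**Contact detection** is the one step with no canonical recipe, so it is
deliberately conservative and fully reported. A short running mean smooths
the load; the leading 10% of samples (≥ 5) provide baseline statistics; the
candidate contact is the first sustained crossing of
`baseline mean + 5 × baseline SD`. The crossing is then back-extrapolated to
zero load through the contact mechanics itself, in two steps: on a Hertzian
segment $(P - \text{baseline})^{2/3}$ is linear in the deflection-corrected
travel $x = z - P/k$, so a line fit gives a starting estimate of $z_0$ as
its x-intercept; that estimate seeds a least-squares fit of
$P = C\,(x - z_0)_+^{3/2}$ on the raw loads, where the noise is additive and
unweighted. On noiseless curves this recovers the offset to machine
precision; under 2% load noise the full pipeline recovers $E$ with ~0.7%
median error (acceptance bound: 5%). A curve that never leaves the baseline
band raises a no-contact error; one that begins at or after contact is
capped at its first sample with a warning.

Internally everything is converted to SI, so supplying (µm, µN) or (m, N)
changes nothing.

## Transcriptome post-processing

The package consumes per-gene differential-expression tables (gene id,
log2 fold change, Benjamini–Hochberg FDR) rather than refitting the
negative-binomial model — model fitting belongs to the established DE
packages; what is implemented here is the downstream decision logic.

*Filtering*: a gene is removed when it is simultaneously weakly expressed
(CPM ≥ 1 in fewer than `n_min` samples) and multi-mapping dominated
(multi-mapping read percentage > 20%). "Simultaneously" is read as a
conjunction — removal requires both clauses — with the OR reading available
behind `logic = "or"` since the phrasing admits either. `n_min` has no
universal default and must be supplied; the smallest group size is the
usual choice. The filter is idempotent by construction and the tests assert
it on a six-gene truth table covering all clause combinations.

*Thresholding*: up-regulated means FDR < 0.05 and logFC > 0 (strictly
greater than the cutoff when a |logFC| cutoff such as 2 is added); down is
symmetric. A gene significant by FDR with logFC exactly 0 is flagged and
assigned to neither set.

*Concordance partition*: comparing the thresholded sets of two contrasts
(each normalized to its own control) yields seven disjoint categories —
up/down specific to each contrast, concordant up/down, and discordant
(significant in both with opposite signs). The partition's invariants are
structural: the categories are pairwise disjoint, cover the union of both
DEG sets, and the totals are sums of their parts. Gene ids match exactly
after whitespace trimming and case folding; no alias resolution is
attempted.

## Group statistics

`anova_tukey()` computes fixed-effects one-way ANOVA from between/within
sums of squares and all-pairs Tukey HSD p-values from the studentized-range
distribution with the Tukey–Kramer standard error
$\sqrt{\tfrac{MS_W}{2}(1/n_i + 1/n_j)}$ for unequal group sizes, flagging
significance at 0.05 and 0.01. For two groups the F statistic equals the
squared pooled t statistic and the p-values agree to $10^{-8}$; on random
data the adjusted p-values match the standard `TukeyHSD()` reference within
0.005, and they never undercut the unadjusted pairwise p. The all-identical
degenerate case reports F = 0, p = 1; internally-constant but different
groups report p = 0.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its parameters including the seed
(bit-identical reruns, caller's RNG untouched) and carries its ground truth
on the object.

- **Fiber networks** (`sim_fiber_image()`): straight fibers with Gaussian
  cross-section, von Mises orientations (κ = 0 chaotic, large κ aligned),
  additive Gaussian background. The truth mask marks pixels whose noiseless
  intensity exceeds half the single-fiber peak. Straight fibers suffice to
  control width and orientation for ordering tests; they do not reproduce
  curvilinear collagen, fiber crossings' SHG interference, or optical
  sectioning.
- **Correlated fields** (`sim_correlated_field()`): Gaussian fields with
  exponential (Matérn ν = ½) covariance synthesized spectrally, giving exact
  control of the target correlation length; a length ≥ half the image side
  triggers a non-resolvability warning. Periodic wrap-around is the price of
  the spectral route and is negligible for λ ≪ image size.
- **Nuclei images** (`sim_nuclei_image()`): non-overlapping disks via
  rejection sampling with a 2 px edge clearance so the rasterized disks stay
  8-disconnected; an unplaceable configuration raises a capacity error
  rather than silently placing fewer. Real DAPI fields have touching nuclei,
  intensity gradients, and debris; passing the exact-count tests therefore
  bounds algorithmic error, not biological segmentation difficulty.
- **Indentation curves** (`sim_indentation_curve()`): exact Hertz loading on
  the true depth, piezo travel assembled as offset + depth + deflection,
  optional Gaussian load noise as a fraction of peak load. No adhesion,
  drift, or viscoelastic relaxation.
- **DEG tables** (`sim_deg_tables()`): a pair of tables with exactly
  specified category structure; FDR ranges for significant and null calls
  must not straddle the significance cutoff, otherwise the ground truth
  would be ambiguous and the spec is rejected.
- **Count matrices** (`sim_count_matrix()`): negative-binomial counts with
  log-uniform gene means and uniform multi-mapping percentages — enough
  structure to exercise the filter, with no attempt at realistic
  mean–dispersion trends.

Because the tests run against these generators, a green suite demonstrates
that the measurement code is correct on data whose truth is known; it does
not certify performance on real micrographs, where thresholding and contact
geometry carry additional, data-dependent uncertainty.

## Numerical choices and problem sizes

Quantization uses equal-width bins over `[min, max]` with the top edge
closed; Otsu maximizes between-class variance over 256 bins and returns the
lower edge of the first bright bin so that `>=` reproduces the binary split.
The exponential and contact-point fits use Levenberg–Marquardt
(`minpack.lm`) with bounded parameters; correlation-length fits start from
the first 1/e crossing. Component labelling builds an 8-neighbour pixel
graph and takes its connected components. Sums of squares are computed in
double precision with no Welford pass — group sizes here are small.

The acceptance suite sizes its simulations to the precision each claim
needs: 1024² fields (10 seeds per correlation length) for λ recovery, 256²
fiber images for ordering, 200-sample indentation curves (20 noise seeds per
modulus), and 1000 random category structures for the partition
invariants.

## Reproducible runs

`run_pipeline()` executes a YAML-configured sequence of stages into a
results directory with one manifest recording the package version, every
seed, and every threshold actually applied, plus per-stage CSV/JSON outputs
and a run log. Identical configs produce identical outputs except the
manifest timestamp; the test suite asserts this determinism contract.
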