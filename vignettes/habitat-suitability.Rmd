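---
title: "Building habitat suitability criteria for macroinvertebrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building habitat suitability criteria for macroinvertebrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hscurves)
```

## The problem

Habitat suitability modelling asks which values of a physical habitat
parameter — water flow velocity, depth, substrate — an organism group
prefers, so that flow scenarios can be scored by the habitat area they
leave suitable. For benthic macroinvertebrates the raw data are
microhabitat samples: at each sampling point the hydraulics are measured,
the substrate is classified, and the invertebrates are counted and
identified. `hscurves` converts such samples into final habitat
suitability curves (HSCs) for the whole community and for functional
feeding groups (FFGs), with two methodological safeguards built in:
use is always corrected for availability, and field campaigns carried
out at different discharges are analysed separately before being
combined.

## Curves and their assumptions

For one parameter and one group, three binned curves are built:

* the habitat availability curve (HAC), `P[E](i) = a_i / Σ a_i`, where
  `a_i` is the sampled habitat area in bin `i`. When per-sample areas
  were not measured every sample counts 1 m², and the HAC becomes the
  sample-frequency distribution of available habitat. Whether surveyed
  "availability" is area or frequency is a genuine ambiguity of the
  method; the package defaults to equal effort and documents the choice
  rather than guessing areas.
* the habitat utilization curve (HUC), `P[E/F](i) = u_i / Σ u_i`, where
  `u_i` is the summed standardized abundance in bin `i`;
* the habitat preference curve (HPC), `P_r(i) = P[E/F](i) / P[E](i)`.

Each curve is rescaled by its maximum into a suitability index
`SI ∈ [0, 1]`. Preference-based (category III) criteria assume organisms
had free and equal access to all sampled habitat; that assumption fails
when data from different discharges are pooled naively, which is why the
pipeline analyses campaigns separately first.

Abundance is standardized per campaign — each sample's group abundance
is divided by the campaign's maximum — so a productive campaign cannot
drown out a lean one when data are eventually pooled. Standardization is
applied to the per-sample group total, not per taxon.

The bimodality diagnostic `huc_hac_excess()` reports bins where
availability exceeds use. A trough flanked by such bins was sampled but
little used, so a bimodal curve reflects true preference rather than a
failure to sample intermediate habitat.

## Numerical choices

* **Bins.** Continuous parameters use half-open bins `[lo, hi)` with the
  last bin closed, preventing double counting at shared edges. Default
  width is 0.05 m/s for velocity and, by analogy, 0.05 m for depth; both
  are configurable. Edges always start at 0 and end at the data maximum
  rounded up to the next edge. Substrate uses the six-category code list
  (`a`, `c`, `ae`, `ce`, `e`, `f`), configurable for other rivers.
* **Masking, not imputing.** Bins with zero availability have no defined
  preference; they are carried as `NA` with a `defined` mask, never as
  SI = 0. Imputing zero would falsely brand unobserved habitat as
  unsuitable.
* **ANOSIM.** Clarke's R on Bray–Curtis dissimilarities of
  ln(1+count)-transformed data, with average ranks for ties and the
  `(b+1)/(m+1)` permutation p-value, which cannot report p = 0 and
  matches the convention of reporting p = 0.002 at 999 permutations when
  a single permutation ties or beats the observed statistic. The
  denominator of R is `n(n-1)/4`, the value for which perfectly
  separated groups give exactly R = 1. For small n the test enumerates
  all distinct label assignments and reports an exact p instead. A
  constant dissimilarity matrix yields R = 0 with a warning. Counts
  (not per-area densities) enter the transform; sampled area affects
  only the availability curve.
* **Bray–Curtis degenerate pair.** Two all-zero samples have an
  undefined ratio; the package defines their dissimilarity as 0 with a
  warning, a case only synthetic or heavily filtered data produce.
* **K coefficient.** `K_i = (0.4 n_i + 0.3 H_i + 0.2 EPT_i + 0.1 α_i) /
  K_max`, with `K_max` the maximum over the whole combined dataset, so
  exactly one microhabitat scores 1. Components enter unscaled, as the
  coefficient is defined, although density `α_i` (individuals/m²) can
  dominate numerically; `normalize_components = TRUE` rescales each
  component by its dataset maximum first for users who want commensurate
  contributions. `EPT_i` counts individuals, not taxa — related indices
  sometimes use richness, so the choice is worth knowing. Descriptions
  of the coefficient in the applied literature occasionally attribute
  the largest weight to the EPT term; the weights implemented here are
  exactly (0.4, 0.3, 0.2, 0.1) on (n, H, EPT, α), as the defining
  equation states. An empty
  microhabitat scores 0 on all components (Shannon diversity included).

## Combining campaigns

Final HSCs must honour both the utilization and the preference curve:
per campaign and bin the candidate SI is `max(si_huc, si_hpc)`. Across
campaigns two strategies are offered, because the final step of curve
synthesis is, in field practice, expert judgment that the package makes
explicit and reproducible:

* `pointwise_max` — the per-bin maximum across campaigns, masked bins
  treated as absent;
* `envelope_fill` (default) — `pointwise_max`, then SI = 1 on every bin
  between the first and last bin reaching `fill_threshold` (default
  0.8). When each campaign peaks at a different velocity because the
  available flows differed, the organisms evidently tolerate the whole
  intervening range; the filled plateau expresses exactly that widened
  range of suitability. The threshold 0.8 marks a bin as a genuine
  campaign optimum rather than noise; at 1.0 the strategy degenerates
  to bridging only exact optima.

Both strategies are idempotent, and `envelope_fill` never falls below
`pointwise_max`. `envelope_fill` is refused for substrate: categorical
bins have no order along which to bridge.

## The synthetic generator

Because microhabitat field datasets are rarely deposited, the package
ships a generator (`default_scenario()`, `generate()`) whose defaults
emulate a two-campaign survey of a sandy lowland stream: 20 samples at
medium flow and 30 at low flow, with the low-flow campaign's velocity
and depth availability shifted downward; a 21-taxon roster spanning all
FFGs, with Chironomidae and Simuliidae dominant and six EPT taxa;
bimodal community preference over velocity and depth; and a narrow
filter-feeder velocity preference centred at 0.30 m/s. Velocity and
depth availability are truncated normals — simple, bounded and
sufficient to create the availability/use offsets the analysis relies
on. Counts are negative binomial with dispersion 2.0 (field
macroinvertebrate counts are overdispersed; `dispersion = Inf` gives the
Poisson limit), with mean proportional to the taxon's group suitability
evaluated *pointwise* at the sampled habitat, so the generator shares no
binning code with the estimators it validates.

What the generator does not emulate: spatial autocorrelation among
neighbouring microhabitats, taxon interactions (food-web coupling of
filter feeders and predators, competition), hydraulically structured
availability (riffle/pool sequences), or measurement error in the
hydraulic variables. Passing recovery tests on synthetic data therefore
demonstrates that the estimators invert the generative model they
assume, not that field data meet those assumptions.

## Validation problem sizes

The test suite recovers a known single-bump velocity optimum (centre
0.30 m/s) to within one bin in at least 90% of 50 replicates at 200
samples per campaign, and reproduces the qualitative ordering that
filter feeders have the narrowest velocity suitability in at least 80%
of replicates. ANOSIM calibration uses 200 null datasets at the default
survey size (50 samples) with 199 permutations each; exactness of the
small-sample path is checked against exhaustive enumeration up to n = 7.
Curve tallies are cross-checked against loop-based reference
implementations on datasets of up to 20 samples.

## Known limitations

* Univariate curves assume velocity, depth and substrate act
  independently; real preferences are for joint habitat types, so the
  curves are a first-order summary.
* The FFG projection gives a taxon's full count to every group it
  belongs to; groups therefore overlap and their curves are not
  independent evidence.
* Availability-as-frequency (the equal-area default) and
  availability-as-area give different HACs when sampling effort varied;
  supply measured `area_m2` whenever it exists.
* The K coefficient mixes components on very different scales; its
  unscaled form is faithful to its definition but sensitive to the
  density term, and it ignores availability entirely, so discrepancies
  against preference curves are expected, especially for small groups.
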