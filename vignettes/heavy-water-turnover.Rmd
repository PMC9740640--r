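---
title: "Estimating protein turnover from heavy-water labeling: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating protein turnover from heavy-water labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hwturnover)
```

## The kinetic model

Heavy-water labeling replaces a fraction of body water with D₂O. Peptides
synthesized during labeling incorporate deuterium at exchangeable hydrogen
sites, shifting intensity from the monoisotopic peak M0 into heavier mass
isotopomers. The observable we track is the monoisotopic relative isotope
abundance over the six retained isotopomers,
$\mathrm{RIA} = M_0 / \sum_{i=0}^{5} M_i$, whose time course under one-pool
first-order turnover is

$$I_0(t) = I_0^{asymp} + \left(I_0(0) - I_0^{asymp}\right)\,e^{-kt}.$$

Assumptions worth stating explicitly:

* **Single pool, instantaneous precursor.** Deuterium equilibrates with
  body water within hours of starting labeling — fast compared with protein
  lifetimes of days to weeks — so a single exponential suffices and no
  precursor-delay compartment is modeled.
* **Known endpoints.** Both asymptotes are treated as known, not fitted:
  $I_0(0)$ comes from the natural isotope distribution of the peptide's
  elemental composition, and the plateau from the body-water enrichment
  $p_w$ and the exchangeable-hydrogen count $N_{EH}$ via
  $I_0^{asymp} = I_0(0)\,\big((1-p_w)/(1-p_H)\big)^{N_{EH}}$. This leaves
  $k$ as the only free parameter, which keeps fits identifiable even with
  few time points.
* **First-order decay of the unlabeled fraction.** The fractional
  synthesis $FS(t) = (I_0(0)-I_0(t))/(I_0(0)-I_0^{asymp})$ then equals
  $1 - e^{-kt}$ identically, which we exploit both for protein-level
  display and as an internal consistency test.

## Isotope patterns and the labeling mixture

Natural isotope patterns are aggregated (unit-mass-binned) distributions
obtained by convolving per-element isotope vectors for C, H, N, O and S,
truncated to six isotopomers and renormalized over the retained peaks. The
engine uses exponentiation-by-squaring of each element's single-atom
polynomial with truncation at six coefficients; the first six coefficients
of a truncated product are exact, so truncation drops tail mass without
corrupting the retained peaks. The test suite checks the engine against an
independent atom-by-atom full-length expansion oracle at $10^{-12}$.

A partially labeled peptide pool is modeled as a two-component mixture: a
fraction $fs$ of the pool carries the plateau-labeled pattern and $1-fs$
the natural pattern. The plateau pattern is the natural pattern convolved
with a binomial deuterium-incorporation distribution over $N_{EH}$ sites at
per-site probability $(p_w - p_H)/(1 - p_H)$. Two numerical choices matter
here:

* **Real-valued $N_{EH}$.** Residue-level exchangeable-hydrogen counts are
  empirical averages, so $N_{EH}$ is not an integer. We use generalized
  binomial weights via the gamma function, zeroing terms beyond
  $j > N_{EH}$ (which would otherwise alternate in sign). The zero-order
  weight $(1-p)^{N_{EH}}$ — the quantity the plateau formula needs — is
  exact by construction.
* **Renormalize before mixing.** The truncated plateau pattern is
  renormalized to sum 1 *before* the mixture is formed. Both mixture
  components then live on the same six-isotopomer simplex, every
  isotopomer share is exactly linear in $fs$, and the monoisotopic share of
  a simulated time course follows the decay model without truncation
  drift. Mixing unnormalized components instead would bend the trajectory
  by the truncated tail mass (up to $\sim 10^{-3}$ for high-$N_{EH}$
  peptides) and bias recovered rates by up to a percent.

The truncated tail is kept as an attribute of every pattern. For peptides
with $N_{EH} \lesssim 5$ and small compositions the tail is below
$10^{-6}$ and the six-isotopomer plateau share agrees with the closed form
to that precision; for typical tryptic peptides ($N_{EH} \approx 10$–$20$)
the tail reaches $10^{-4}$–$10^{-2}$ and the two differ accordingly.

**Plateau convention.** Because the RIA is defined over six retained
isotopomers, the asymptote the *measured* RIA approaches is the
six-isotopomer plateau share, not the untruncated closed form. The
pipeline therefore defaults to `plateau = "pattern"` (the monoisotopic
share of the fully labeled pattern); `plateau = "closed_form"` applies the
analytic expression instead. The difference is invisible for low-$N_{EH}$
peptides and up to $\sim$1 % in fitted $k$ for the highest-$N_{EH}$ ones.

Constants are data, not code: `isotope_constants()` holds the IUPAC
natural abundances, $p_H = 1.15\times 10^{-4}$, the ¹³C–¹²C isotopomer
spacing (1.0033548 Da — deuterium-induced spacing differences are far
below the ppm tolerances at peptide masses), and `residue_table()` the
residue compositions and Commerford-style $N_{EH}$ values used in the
heavy-water turnover literature. Both can be overridden by argument or
plain-text config, since published $N_{EH}$ tables differ at the second
decimal and no single set is canonical.

## Quantification

For each peptide and run, the six targets $m/z_0 + i\,\Delta/z$ are
integrated over MS1 scans within a retention-time window around the anchor
(the identification RT, or the mapped donor apex for MBR transfers), with
a ±ppm window per isotopomer. Elution bounds extend outward from the M0
apex while the 3-point-smoothed M0 signal stays at or above 5 % of the
apex — a deliberately simple, symmetric and testable rule, since the
underlying algorithm is not otherwise constrained. Abundances are sums
over the bounded scans, so integration is linear in intensity and the RIA
is invariant to uniform intensity scaling; fitted rates inherit that
invariance.

Key parameters, with defaults chosen as round numbers in the ranges
practitioners use (none is prescribed by the method itself): mass accuracy
`ppm_tol = 10` ppm, `rt_window = 1.0` min, `mbr_rt_window = 1.0` min, ion
score ≥ 20, expectation ≤ 0.05, peptide/protein identification consistency
≥ 1 run, `min_ndp = 3` points per fit.

Degenerate inputs are signalled, not patched: a peptide with no detectable
M0 anywhere in the window yields an absent data point (never an imputed
zero); a zero isotopomer total makes the RIA undefined and the point is
dropped; a series with $I_0(0) \le I_0^{asymp}$ (no labeling contrast) is
refused.

The interference guard is the absolute isotope-profile deviation
$\sum_i |p_i^{theo} - p_i^{obs}|$ evaluated at the unlabeled time point; we
report it per peptide rather than attempting deconvolution of co-eluting
species.

## Match between runs and RT alignment

DDA identification is semi-stochastic, so peptides routinely lack MS/MS
identifications in some runs. For such runs the package transfers the
quantification: the donor is the run with the strongest quantified signal
for the peptide, its apex RT is mapped into the target run, and extraction
proceeds in the MBR window with the result flagged `mbr`. The RT mapping
is a monotone piecewise-linear function fitted by isotonic regression on
the apex RTs of peptides identified in both runs, interpolating linearly
between anchors and extrapolating by the boundary offset; with fewer than
three shared anchors it degrades to the identity with a warning. This
anchor-based mapping is an approximation to alignment on raw spectral
profiles; it is exact for affine drifts and tracks smooth nonlinear drifts
to within the scan spacing, which is sufficient at the 1-minute MBR
windows used here.

MBR points are included in fits by default (`use_mbr = FALSE` excludes
them) but never count toward identification-consistency thresholds — they
are quantifications, not identifications.

## Fitting and statistics

The residual sum of squares in $k$ is minimized over $[0, 10]$/day with
L-BFGS-B from three starts (0.01, 0.1, 1/day) and polished with a
derivative-free bracket search; the procedure is deterministic and the
multi-start guards against the flat gradient at large $kt$. The 95 %
confidence interval is the linearized Wald interval
$k \pm 1.96\,\hat\sigma/\lVert J\rVert$ with $J$ the curve's gradient in
$k$; with one parameter and $\ge 3$ points this matches the usual
nonlinear-regression practice. Reported GOF statistics use the standard
definitions ($R^2 = 1 - SS_{res}/SS_{tot}$, RMSE with denominator $n$,
Pearson correlation of observed vs fitted). The reported SD is the
*residual* standard deviation $\sqrt{SS_{res}/(n-1)}$ — the rate
estimate's own uncertainty is already carried by the CI, so duplicating it
would be redundant.

Protein rates are medians of peptide rates (mean of the central two for
even counts) — robust to a single aberrant peptide by construction. An
optional `r2_floor` excludes poor peptide fits from the median; it
defaults to off so that the protein rate never silently depends on a GOF
threshold. The normalized protein abundance divides the protein's average
monoisotopic abundance by the median over experiments of each experiment's
median base-peak intensity (scans without signal carry no base peak and
are excluded from the per-experiment median).

## The synthetic generator

`simulate_experiment_set()` writes one mzML/mzid pair per labeling time
point. Defaults mirror a month-long murine study: twelve time points (0,
1, 2, 3, 6, 7, 9, 13, 16, 21, 24, 31 days) and body-water enrichment
0.046. Each run's MS1 scans contain, per peptide, the six-isotopomer
envelope of the mixture model at $fs = 1 - e^{-kt}$ under a Gaussian
chromatographic profile (SD 0.08 min), with optional multiplicative
intensity noise and ppm jitter; mzid files carry Mascot-style score and
expectation terms, and selected identifications can be dropped per run to
exercise MBR. The default panel spans $k$ from 0.02 to 0.6/day — slow to
fast turnover at liver-like rates — at three abundance scales.

The generator emulates: envelope evolution consistent with the decay model
(by construction, see the mixing note above), chromatographic peak shape,
scan discretization, intensity noise, mass error, and missing
identifications. It deliberately does **not** emulate co-eluting
interferences, chimeric spectra, profile-mode peak shape beyond a simple
Gaussian, charge-state or missed-cleavage heterogeneity, false
identifications, or intensity-dependent (shot-noise) error. Passing
end-to-end tests therefore demonstrates correctness of the numerical
chain — extraction, RIA, fitting, aggregation, reporting — not robustness
to every pathology of real chromatography; the profile-deviation statistic
and the plots are the tools for judging those on real data.

Fixture scale in the test suite is deliberately small (3–15 peptides, 12
runs, ~340 scans per run) so the full suite runs in seconds while still
covering every pipeline stage; the acceptance script uses the full 3 × 5
panel.

## Known limitations

* Sequence-only compositions: no post-translational modifications, no
  elements beyond CHNOS.
* One-pool kinetics only; tissues with delayed precursor equilibration
  would need a two-compartment extension.
* The mzid dialect is Mascot-style (ion score / expectation value); other
  engines' scoring terms are not mapped.
* No de novo feature detection: quantification is strictly targeted at
  identified (or MBR-transferred) peptides.
* Exact numeric agreement with other implementations is not claimable
  where their residue-level $N_{EH}$ tables or $p_H$ constants are
  unpublished; both are configurable here for that reason.
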