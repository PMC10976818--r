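---
title: "Quantifying molecular deuteration by isotopologue deconvolution"
author: "DeuteR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying molecular deuteration by isotopologue deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DeuteR)
```

## The problem

Deuterated small molecules — tracers, NMR and neutron contrast agents,
deuterated drugs — are rarely isotopically pure.  A nominally
perdeuterated compound with $N$ labile positions is really a mixture of
*isotopologues*: species carrying $i = 0, \dots, N$ deuterium.  Electrospray
high-resolution mass spectrometry separates these species by roughly
$m(\mathrm{D}) - m(\mathrm{H}) \approx 1.00628$ Da per exchanged position,
so a single spectrum contains the full composition — except that every
isotopologue also carries its own *natural* isotope envelope
($^{13}$C, $^{81}$Br, $^{2}$H in the residual protium positions, ...),
which smears each species across the channels of its higher-deuterated
neighbours.  Reading channel intensities at face value therefore
overestimates high-deuterium content whenever the natural envelope is
non-trivial.

DeuteR treats the measurement as a convolution and inverts it.

## Model

Let $y_i$ be the probability of the isotopologue with $i$ deuterium, and
let $h$ be the isotopic pattern of the *fully deuterated* adduct ion,
binned onto the ~1.006 Da channel grid starting at its base peak.
Because every isotopologue shares essentially the same natural-isotope
envelope, the extracted channel signals $x$ satisfy

$$ x \;=\; y * h , $$

a discrete convolution: $h$ acts as the point-spread (response) function
that blurs the isotopologue distribution.  The distribution is recovered
by division in the frequency domain,

$$ y \;=\; \mathcal{F}^{-1}\!\left( \mathcal{F}(x) / \mathcal{F}(h) \right), $$

taking the first $N + 1$ real components and clipping small negative
ripples to zero.  The headline statistic is the percent of the expected
deuterium content,

$$ \%D \;=\; \frac{100}{N} \sum_{i=0}^{N} i \, y_i , $$

computed over the normalised retained states — deliberately *not* a bulk
H/D ratio: the denominator is the deuterium count of the formula the user
supplies.

The pipeline (`deuterate()`) composes: read spectrum → select/apply
adduct → predict the isotopic pattern → (optional realignment) → build
target grid → extract signals → deconvolve → probability cutoff → %D.

## Isotopic patterns

Patterns are computed by convolution of per-element multinomial
distributions using a pinned CIAAW/IUPAC isotope table (`isotopeTable()`),
with `"D"` a pseudo-element of pure $^2$H.  Natural hydrogen keeps its
0.0115% deuterium component, so residual protium positions contribute
their (tiny) natural $^2$H satellites.  Numerical choices:

* peaks closer than $10^{-3}$ Da are merged abundance-weighted — fine
  structure below that spacing is irrelevant to $\pm 0.5$ Da windows;
* combination states below $10^{-6}$ relative abundance are pruned (below
  instrument dynamic range), and the pattern renormalised so abundance is
  conserved exactly;
* element powers are built by repeated squaring of the single-atom
  pattern, keeping intermediate pattern sizes small;
* ions subtract one electron mass per positive charge (and add per
  negative) and divide by $|z|$ — required at the mass accuracy where a
  0.5 mDa error is visible.

## The target grid and extraction

Channels $0..N$ sit at the base-peak m/z of each isotopologue of the
adduct, spaced by $(m_D - m_H)/|z|$.  The grid then continues above the
fully deuterated base peak with *tail* channels at the positions of the
response pattern's clusters, down to 0.1% relative abundance, so the full
envelope of the fully deuterated species is measured — without the tail
the division above would be inverting a truncated convolution.

Signals are extracted from each channel's $\pm 0.5$ Da window (data
points are assigned to their nearest channel, ties to the lower channel,
making boundary behaviour deterministic).  Two modes are provided:

* **`area`** (default): trapezoidal integration across the window.  This
  is exact for the convolution model regardless of whether fine structure
  is resolved.  At realistic peak widths the $^{81}$Br satellite of state
  $i$ sits 14.6 mDa below the base peak of state $i+2$; a resolving
  instrument separates them, and a maximum-point reading then reports
  only the larger of the two where the model needs their sum.  Window
  integration is immune to this.
* **`height`**: the maximum data point in the window.  Preferable for
  centroided data, and for noisy profile data: integration accumulates
  the (non-negative) noise baseline across the whole 1 Da window, while
  the maximum samples it once.  In simulations with 1% relative noise,
  height extraction recovers %D with bias below 0.2 points where area
  extraction is biased several points low.

Both modes are scale-invariant: multiplying all intensities by a constant
leaves the distribution and %D unchanged.

## Deconvolution and its fallback

Fourier division is the method's definition and is used by default.  If
any Fourier component of $h$ has magnitude below $10^{-12}$ the division
is refused with an explicit error rather than silently regularised — a
silent deviation would change reported numbers.  A non-negative
least-squares solve of the same banded linear system
(`method = "nnls"`, via `pracma::lsqnonneg`) is available as the
fallback; on well-posed noiseless systems the two agree to better than
$10^{-4}$ per channel (this is a standing test).

## The probability cutoff

Spectra of heavily deuterated molecules span a wide mass range, exposing
the low-deuterium channels to contaminants and lower-mass adducts.  The
automatic cutoff removes the low tail: the retained region starts at the
lowest state $c$ whose two immediately lower states each carry less than
1% of total probability while states $c..N$ carry more than 10%;
probabilities for the rule are evaluated on $y$ normalised over all
$N+1$ states (the thresholds are percentages of the whole), negatives are
clipped before the rule, and the retained states are renormalised
afterwards.  Placing the cutoff at the *lowest* state satisfying the rule
— rather than scanning downward from $N$ and cutting at the first
sub-1% pair encountered — matters: a downward scan would amputate real
0.1–0.3% states at the foot of a smooth binomial-like envelope, while the
upward placement removes only a genuinely dead (or contaminated) low
tail.  A manual override accepts a deuterium count or an m/z value
(mapped to the lowest channel at or above it).

## Adduct handling and auto-selection

Adducts follow the electrospray grammar `[nM+X]z+` / `[nM-X]z-` with
condensed-formula gains and losses, so fragment species such as
`[M-C5D7O2+CH3CN]+` are expressible.  When no adduct is given, the most
intense point within the union of the candidates' expected deuteration
windows (D0..DN base peaks $\pm 0.5$ Da) is located and the candidate
whose fully deuterated monoisotopic m/z lies closest is chosen.  This is
a starting point, not an identification: for a sample at low deuteration
the strongest peak sits several channels below the perdeuterated mass,
where a deuterium-loss adduct explains the spectrum equally well in pure
mass terms.  Results carry an `autoAdduct` flag and the report says
"verify".

One related choice: the formula is taken at face value.  Whether labile
O–H/N–H positions written as D should count toward $N$ is the user's
call; the package does not second-guess the formula.

## Calibration realignment

A miscalibrated axis is absorbed by grid-searching a single global offset
in $[-0.5, +0.5]$ Da (0.005 Da steps) that maximises the
abundance-weighted sum of spectrum heights near the predicted peaks, each
height down-weighted linearly with distance from its predicted position
(triangular kernel, 0.05 Da half-width).  The kernel matters: a flat
window scores every offset that keeps the apex inside the window equally,
so its argmax is a plateau edge rather than true alignment.  Offsets
beyond the cap cannot be distinguished from alignment onto the
neighbouring channel of the ~1.006 Da comb (aliasing); the cap warning
fires only when the best in-range score sits at the boundary.

## The exchange simulator

`exchangeDistribution()` models back-exchange from a perdeuterated
molecule with first-order kinetics on site classes: class $c$ retains
deuterium with probability $p_c = e^{-k_c t}$, the shared time solved
numerically so the mean retained fraction equals the requested overall
retention; the deuterium count is then the convolution of per-class
binomials.  The distribution is analytic — the only stochastic element in
a rendered fixture is detector noise — so simulation targets are exactly
reproducible.  A single class reduces to Binomial($N$, retention)
exactly, and the mean is conserved to $10^{-9}$ by construction.

The canonical study conditions used throughout the tests: methyl (CD$_3$)
positions exchanging 2.18$\times$ faster than methylene (CD$_2$)
positions, run to 60% overall retention — hexane-d14 as classes (6, 8)
and 1-bromohexane-d13 as classes (3, 10), with the faster rate on the
methyl class.  The kinetic literature value fixes the ratio but not the
class assignment; the assignment is configuration, so either orientation
can be simulated.

`renderSpectrum()` draws the full mixture pattern
$\sum_i y_i \cdot \mathrm{pattern}(\text{isotopologue}_i + \text{adduct})$
— every isotopologue with its complete natural isotope structure — as
Gaussians of width $\sigma = 0.01$ Da sampled every 0.002 Da (sharp
HRMS-like peaks, $R \approx 10^4$ at m/z 100), height proportional to
abundance, with optional relative Gaussian noise (clipped at zero:
intensities are non-negative) and a constant m/z offset.  Defaults are
noiseless with seed 1.

What the simulator does *not* emulate — and therefore what passing tests
do not demonstrate about real data: chromatographic co-elution and
contaminant peaks, detector saturation and dead time, mass-dependent
calibration drift (the offset is constant), resolution varying with m/z,
and isotope effects on ionisation efficiency.  The cutoff rule in
particular is exercised only lightly by clean synthetic spectra.

## Worked example

```{r example}
dist <- exchangeDistribution(c(6, 8), c(2.18, 1), retention = 0.6)
spec <- renderSpectrum("C6D14", "[M+H]+", dist)
res <- deuterate("C6D14", spec, adduct = "[M+H]+")
res
head(reportTable(res))
```

The bromine case shows why deconvolution exists: on 1-bromohexane-d13 the
$^{81}$Br satellites inflate the high-deuterium channels, and raw channel
signals read several points high while the deconvolved result stays on
the simulated truth:

```{r bromine}
distBr <- exchangeDistribution(c(3, 10), c(2.18, 1), retention = 0.6)
specBr <- renderSpectrum("C6D13Br", "[M+H]+", distBr)
percentD(suppressWarnings(deuterate("C6D13Br", specBr, adduct = "[M+H]+")))
percentD(suppressWarnings(deuterate("C6D13Br", specBr, adduct = "[M+H]+",
                                    deconvolve = FALSE)))
```

## Problem sizes and known limitations

The test-suite simulations use C6D14 and C6D13Br profile spectra of
roughly $10^4$ points (16–20 Da at 0.002 Da steps), deconvolution systems
of up to ~30 channels, and 20-seed noise replicates; each pipeline run
takes well under a second, keeping the whole suite fast while exercising
every stage end to end.

Limitations: one compound per spectrum (no mixture resolution), no
charge-state deconvolution, no baseline subtraction, no site-specific
(per-position) assignment — the method quantifies *how many* positions
retain deuterium, not *which*.  Fourier division amplifies noise at
frequencies where $|\mathcal{F}(h)|$ is small; for noisy spectra prefer
height extraction and, if the response is near-singular, the NNLS
fallback.
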