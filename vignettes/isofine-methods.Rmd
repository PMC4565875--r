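---
title: "Isotopic fine structure: moments, entropy, counting, and resolution limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotopic fine structure: moments, entropy, counting, and resolution limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isofine)
```

## The problem

A molecule built from C, H, N, O, P and S is not one species but a mixture
of isotopologues. Grouped by total neutron count these form the aggregated
isotope distribution (peaks ~1 Da apart); within one aggregated variant the
isotopologues differ by a few mDa or less — the isotopic fine structure.
`isofine` characterizes both levels for arbitrarily large formulas and
quantifies when, and why, the fine structure stops being resolvable:
cluster overlap, thermodynamic mass uncertainty, peak-density limits, and
ion-counting statistics.

## Aggregated moments by generating-function convolution

The aggregated distribution is the coefficient sequence of
$Q(I)=\prod_e\big(\sum_i a_{ei} I^{d_{ei}}\big)^{n_e}$, with $a_{ei}$ the
isotope abundances and $d_{ei}$ the neutron offsets. Rather than only
tracking probabilities, every coefficient is a 3-vector
$(\sum_k p,\ \sum_k p\,\tilde m,\ \sum_k p\,\tilde m^2)$ over the fine
peaks that would fall at that neutron index. Products of independent parts
convolve these vectors (masses add, probabilities multiply), so per-element
single-atom vectors raised to the atom count by repeated squaring give, for
every variant $j$: the probability $q_j$, center mass $E(m_j)$, and
variance $\mathrm{Var}(m_j) = E(m_j^2) - E(m_j)^2$ — exactly, and with cost
polynomial in molecule size (no fine-structure enumeration).

**Numerical design.** At 200 kDa a center mass of $2\times10^5$ Da and a
variance of $10^{-4}$ Da$^2$ differ by 19 orders of magnitude, so the raw
second-moment subtraction would be meaningless in double precision. All
masses are therefore accumulated as offsets relative to the per-variant
affine reference $\text{monoisotopic} + j\,(m_{^{13}\mathrm{C}} -
m_{^{12}\mathrm{C}})$; offsets stay of the order of the fine-structure
spread, the reference is exact, and the subtraction loses nothing. The
exhaustive-enumeration oracle in the test suite confirms agreement to
better than $10^{-9}$ relative error, and the 222 kDa poly-averagine
reproduces $\sigma = 0.026$ Da.

**Entropy needs lumping.** The fine peaks are *isotope-count classes*, not
labeled-atom configurations: two atoms of the same element are
interchangeable. For $q_j$, $E(m_j)$ and $\mathrm{Var}(m_j)$ this is
irrelevant — all configurations that merge into one class share a mass, so
atom-by-atom powering is exact. The entropy accumulator
$\sum_k p_k(-\log p_k)$ is different: $-\log p$ of a merged class is not
the sum of configuration terms. The package therefore builds, per element,
the exact vector of multinomial composition probabilities (a vectorized
expansion over heavy-isotope compositions, using sequential binomial
factors in the log domain) and convolves those *element-level* vectors,
where $-\log p$ is genuinely additive across elements. The identity
$H(j) = \big(\sum_k -p_{jk}\log p_{jk}\big)/q_j + \log q_j$ then yields the
per-variant entropy. A homoatomic molecule such as C$_{12}$ correctly gets
$H(j)=0$ for every variant.

**Window and truncation.** The $j$ window defaults to mean
$\pm\,12$ envelope standard deviations of the closed-form neutron-count
distribution, extended until the requested coverage (default
$1-10^{-12}$) is met. For very large molecules the *measured* defect
$1-\sum_j q_j$ is dominated by floating-point accumulation
($\sim10^{-12}$ at 450 kDa), so window growth stops once a Bernstein bound
on the true right-tail mass falls below tolerance; an explicit `j_max`
overrides the window entirely. Truncation is one-sided and exact: computed
coefficients are unaffected by discarded ones.

**Decompositions.** Total variance splits as
$\sum_j q_j\mathrm{Var}(m_j) + \sum_j q_j (E(m_j)-\bar m)^2$
(within-variant + between-variant), and equals the closed form
$\sum_e n_e\mathrm{Var}_e(\text{isotope mass})$ by independence of atom
masses — an internal consistency check that holds to $<10^{-9}$ into the
megadalton range. Total entropy splits analogously as
$\sum_j q_j H(j) + \big(-\sum_j q_j\log q_j\big)$. Entropies are reported
in nats by default (`unit = "bits"` rescales); the natural-log convention
matches the divergence formulas below.

## Counting and enumerating fine peaks

Two fine peaks are distinct iff any element's isotope counts differ.
Counting them is a bounded money-exchange problem: heavy isotopes are
coins with denominations equal to their neutron offsets —
$\{^{13}\mathrm{C},{}^2\mathrm{H},{}^{15}\mathrm{N},{}^{17}\mathrm{O},
{}^{18}\mathrm{O},{}^{33}\mathrm{S},{}^{34}\mathrm{S},{}^{36}\mathrm{S}\}
= \{1,1,1,1,2,1,2,4\}$ — and each element's heavy counts are jointly
bounded by its atom count. `count_fine_peaks()` builds per-element
bounded-composition polynomials by a dynamic program over (neutrons, atoms
used) — every coin is worth at least one neutron, so the atoms-used
dimension is also bounded by $j$ — and convolves them across elements.
Counts are accumulated in doubles, hence exact below $2^{53}$
($\approx 9\times10^{15}$), far beyond any case of practical interest
(the 222 kDa poly-averagine has $\sim2\times10^{10}$ fine peaks at
$j=142$, computed in milliseconds).

`enumerate_fine_peaks()` lists the actual isotopologues with exact masses
(monoisotopic + sum of isotope mass deltas — again no large-number
cancellation) and multinomial probabilities. Enumeration walks
element-by-element neutron allocations with branch-and-bound pruning
against `min_prob * q_j`, using per-element best-composition bounds and a
max-plus suffix table, so the pruning bound is exact and only sub-threshold
branches are discarded. Most fine peaks of a large molecule are far too
small to observe; the relative floor reflects that while keeping the
retained probability (`captured`) explicit.

## Spread and spacing

The heaviest fine variant of a cluster packs all extra neutrons into
deuterium, the lightest into $^{15}$N, because these have the extreme
mass-per-additional-neutron ratios; the closed-form maximum spread is
$j\,(\mu_{2H}-\mu_{15N}) \approx j \times 9.24$ mDa. When the formula
lacks enough H or N atoms ($j > \min(w, x)$) the attainable spread is
smaller; `mode = "bounded"` computes the exact atom-bounded optimum with
max-plus/min-plus dynamic programs (exact, unlike a greedy fill, and
verified against full enumeration). Mean spacing divides a width estimate —
either the closed-form spread or a $k\sigma$ width with $\sigma$ from the
generating-function variance — by the exact peak count. Both conventions
are exposed because they answer different questions (the spread covers
vanishingly small extreme peaks; a few-$\sigma$ width covers where the
probability actually lives); no particular printed spacing value is wired
in.

## Resolution limits

**Cluster overlap.** Across protein-like compositions the fine-structure
variance of the most abundant variant grows linearly with its mass. The
package pins the empirical protein model
$\mathrm{Var}(m_a) = 1.503\times10^{-6} + 3.077\times10^{-9}\,m_a$ (Da$^2$),
a DNA scaling of $1.68\times10^{-9}\,m_a$ and a virus scaling of
$2.4\times10^{-9}\,m_a$ (their approximate mean) as constants; they are
deliberately not refit at run time, since the database-scale regression
behind the protein coefficients is outside the package's scope.
Self-consistency is tested instead: variances computed directly for
poly-averagines between ~22 and ~444 kDa fit a line whose slope lands
within a few percent of the pinned value. Solving
$\text{intercept} + \text{slope}\,m = \sigma^2$ at the default threshold
$\sigma = 0.5$ Da gives the overlap onset, ~81.25 MDa for proteins: beyond
it, adjacent ~1 Da-spaced clusters overlap substantially no matter the
resolving power.

**Thermorelativistic uncertainty.** An isolated ion in a canonical
ensemble at temperature $T$ has internal-energy fluctuations
$\sigma_E = \sqrt{k_B T^2 C}$, equivalent through $E = mc^2$ to a mass
uncertainty $\Delta m = \sigma_E/c^2$. The heat capacity is modeled as
$C = f\,N_{\text{atoms}}\,k_B$ with $f = 3/2$ (equipartition) and
$T = 300$ K by default; both are explicit configuration because the
appropriate $f$ for a macromolecular ion is genuinely debatable
(vibrational modes are partially frozen at room temperature). With these
defaults a 31,147-atom poly-averagine gives
$\Delta m = 6.0\times10^{-9}$ Da ($1.0\times10^{-35}$ kg): two orders of
magnitude larger than that molecule's mean fine-peak spacing, so most of
its fine structure is unresolvable even by a hypothetical
infinite-resolution instrument. $\Delta m$ scales as
$\sqrt{N_{\text{atoms}}}$ and linearly in $T$. Physical constants are
CODATA values pinned in `thermo_config()`.

**Ion counting.** `sample_ions()` draws a finite number of ions over fine
peaks (multinomially, seeded) and reports occupancy: 200,000 ions over two
million equal peaks give a mean occupancy of exactly 0.1 and leave over
90% of peaks empty — not enough to characterize a fine-structure profile
regardless of resolution.

## Shape and normality

`render_profile()` convolves stick spectra with Gaussians (area = stick
probability; FWHM given directly or as mass/R; conversion
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$), conserving unit area to
$10^{-6}$. For the normality analysis, the enumerated fine structure P of
a variant and a normal Q with the variant's generating-function mean and
variance are discretized on shared equal-width bins (default 1000, spanning
the fine support plus one bin-width margin — the binning range convention
is a package choice); both are expressed as virtual counts
(`count_scale`, default $10^6$) and a single pseudo-count is added to every
bin so Q is strictly positive. Then
$D_{KL}(P\|Q)=\sum_i P(i)\ln(P(i)/Q(i))$, $H(P)$ and the cross-entropy
$H(P,Q) = H(P) + D_{KL}(P\|Q)$ (an identity that holds to $10^{-12}$ by
construction) quantify the divergence from normality. The default P is
deterministic (enumeration, not sampling), which removes run-to-run
spread; `mode = "sample"` draws `count_scale` ions from the fine structure
first to emulate a finite-ion measurement, with a seed. Across
poly-averagines of increasing size (the test suite uses 100, 400 and 1600
units, i.e. ~11 to ~178 kDa, enumerated at a fixed relative floor of
$10^{-6}$) $D_{KL}$ falls steeply — the fine structure of heavy molecules
is well approximated by a normal, while small molecules are distinctly
non-normal.

## Data, fixtures and the synthetic family

The isotope table is pinned in `inst/extdata/` (AME atomic masses, IUPAC
2005 representative abundances — the vintage of the classic
ultrahigh-resolution pattern calculators; the 2013 re-evaluation shifts
N and S abundances in the fourth decimal, enough to move a knife-edge mode
such as the 444 kDa poly-averagine's $j^\ast$ between 276 and 277). It is
validated on load (abundances sum to 1 within $10^{-9}$, offsets start at
0 and increase strictly) and can be replaced per analysis via
`isotope_table(path)`; every output records the table's provenance.

Poly-averagines — the averagine unit
C$_{4.9384}$H$_{7.7583}$N$_{1.3577}$O$_{1.4773}$S$_{0.0417}$ scaled by
`n_units` and rounded half-up per element — serve as the synthetic family
of protein-like test molecules (2000 units ≈ 222 kDa, 4000 ≈ 444 kDa).
They emulate average elemental composition only: real proteins deviate in
composition (notably S content), carry modifications, adducts and charge,
none of which are modeled. Passing tests on poly-averagines therefore
demonstrate the machinery on realistic *compositions*, not agreement with
any particular protein's measured spectrum. `make_fixtures()` writes the
formulas and enumerated fine structures as deterministic TSVs.

## Problem sizes and limitations

Test and example computations use desk-scale inputs: the oracle suite
enumerates every isotopologue of a deterministic roster of ~460 small
CHNOS formulas; the scaling check spans 22–444 kDa poly-averagines; the
normality trend enumerates up to ~6×10⁴ pruned fine peaks. Known
limitations: no adducts, charge states or m/z conversion; no
isotope-labeled reagents; no instrument modeling beyond Gaussian peak
shapes (FT apodization, space charge, transient decay and similar effects
are out of scope); fine-peak counts above $2^{53}$ are rounded doubles;
and the variance-scaling coefficients are pinned empirical constants whose
provenance (a large protein-database regression) is documented rather than
reproduced.
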