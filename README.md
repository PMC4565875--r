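# isofine

Tools for characterizing the **isotopic fine structure** of large molecules
and the physical limits it imposes on mass-spectrometric resolution.

At moderate resolving power the isotope pattern of a protein appears as
peaks spaced ~1 Da apart. Each of those peaks is an *aggregated isotopic
variant*: the set of all isotopologues sharing the same number of extra
neutrons *j* relative to the monoisotopic species. At very high resolving
power each aggregated variant splits into a dense *fine structure* of
isotopologue peaks with slightly different masses. `isofine` answers, for a
molecule C\_v H\_w N\_x O\_y P\_t S\_z, questions such as: how probable is
each aggregated variant, how wide and how complex is its fine structure,
how many fine peaks does it contain, and at what molecular weight do the
fine-structure clusters of adjacent variants blur into each other — no
matter how good the instrument is.

## The model

For a formula with element counts (v, w, x, y, z), the aggregated
distribution is the coefficient sequence of the probability generating
polynomial

    Q(I) = prod_e ( sum_i a_ei I^(d_ei) )^(n_e) = sum_j q_j I^j,

where `a_ei` and `d_ei` are the abundance and neutron offset of isotope `i`
of element `e`. `isofine` convolves per-element coefficient vectors that
simultaneously carry `sum p`, `sum p*m`, `sum p*m^2` and `sum -p*log p` per
neutron index, so for every variant j it obtains — without ever enumerating
the fine structure —

* the probability `q_j`,
* the center mass `E(m_j) = sum_k m_jk p_jk / sum_k p_jk`,
* the variance `Var(m_j) = E(m_j^2) - E(m_j)^2`, and
* the information-theory entropy
  `H(j) = (sum_k -p_jk log p_jk)/q_j + log q_j`,

plus the ANOVA-style decompositions of total variance and entropy into
within-variant (fine structure) and between-variant (aggregated) parts.
Masses are accumulated as offsets from `monoisotopic + j * (m13C - m12C)`,
which keeps the variance subtraction numerically safe into the megadalton
range.

Around that core sit:

* **exact fine-peak counting** — a bounded money-exchange problem over the
  heavy-isotope neutron denominations {13C,2H,15N,17O,18O,33S,34S,36S} =
  {1,1,1,1,2,1,2,4}, solved by per-element bounded-composition polynomials;
* **fine-structure enumeration** with branch-and-bound pruning and exact
  multinomial probabilities in the log domain;
* **spread and spacing estimates** — the closed-form maximum spread
  `j * (mu_2H - mu_15N)` and the exact atom-bounded optimum;
* **resolution-limit models** — the linear variance-vs-mass scalings for
  proteins/DNA/viruses with the overlap-onset solver, and the
  thermorelativistic mass uncertainty `dm = sqrt(k_B T^2 C)/c^2` of an
  isolated ion;
* **shape analysis** — Gaussian profile rendering at finite FWHM/resolving
  power, 1000-bin discretization with pseudo-counts, and
  entropy/cross-entropy/Kullback–Leibler divergence of the fine structure
  against a moment-matched normal;
* **ion-counting statistics** — seeded multinomial sampling of finite ion
  numbers over fine peaks with occupancy reports.

## Worked example

```r
library(isofine)

agg <- aggregated_distribution("C2934H4615N781O897S39")  # bovine serum albumin
most_abundant_variant(agg)
#> [1] 42
agg[agg$j == 42, ]
#> # A tibble: 1 x 6
#>       j      q center_mass variance  sigma entropy
#>   <int>  <dbl>       <dbl>    <dbl>  <dbl>   <dbl>
#> 1    42 0.0571      66432. 0.000245 0.0157    7.37
```

The most abundant variant of BSA carries 42 extra neutrons and 5.7% of the
total probability; its fine structure is only ~16 mDa wide (1 sigma) yet
has entropy 7.4 nats — on the order of e^7.4 ≈ 1600 effectively distinct
fine peaks.

```r
resolvability_report(averagine_formula(2000))
#> formula C9877H15517N2715O2955S83, j = 138, q_j = 0.032
#> sigma = 0.0263 Da, spread = 1.28 Da, n_fine_peaks = 1.6e10
#> spacing_spread = 7.9e-11 Da, dm_Da = 6.0e-9, spacing_spread_over_dm = 0.013
```

For a ~222 kDa poly-averagine the mean gap between fine peaks
(spread/count, ~8e-11 Da) is nearly two orders of magnitude smaller than
the thermorelativistic mass uncertainty at 300 K (6.0e-9 Da): most of the
fine structure is unresolvable by any instrument.

A thin CLI wraps the same functions:

```sh
exec/isofine count --formula C2H2N2O2S2 --j 2     # 17 fine peaks
exec/isofine limits --model protein               # overlap onset ~81.25 MDa
exec/isofine aggregated --formula C2934H4615N781O897S39 --out bsa.tsv
```

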