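---
title: "Soil-to-crop heavy-metal transfer and dietary risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soil-to-crop heavy-metal transfer and dietary risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytorisk)
```

# The problem

Vegetables grown near artisanal gold mining can take up mercury, lead and
arsenic from the soil. Whether that matters for the people eating them
depends on a chain of quantities: how much of the soil burden is
*bioavailable* (sequential-extraction fractions and the Risk Assessment
Code), how efficiently the plant moves metal from soil to root
(bioconcentration factor, BCF) and from root to shoot (translocation
factor, TF), how much ends up in the edible fruit, and what chronic daily
dose that implies for a consumer (EDI, CDI) relative to toxicological
reference values (RfD, CSF, BMDL, PTWI) and food-standard limits (MAC).
`phytorisk` implements this chain end to end, with analytical QC
(detection limits, CRM recovery, censoring) and a synthetic-study
generator so every stage can be validated against known ground truth.

# Models and conventions

## Soil side: RAC

For each metal the first two sequential-extraction fractions are treated
as bioavailable — water-soluble and stomach-acid-soluble (Bloom scheme,
Hg) or exchangeable and carbonate-bound (Tessier scheme, Pb/As) — and

$$\mathrm{RAC} = F_1 + F_2 \quad (\%)$$

is classified into environmental-risk bands. Published threshold lists
for these bands frequently contain gaps and overlaps between the "low",
"medium" and "very high" entries; `classify_rac()` therefore uses
contiguous half-open bands that partition $[0, 100]$ with inclusive lower
edges:

| band | interval (%) |
|---|---|
| no_risk | [0, 1) |
| low | [1, 10) |
| medium | [10, 30) |
| high | [30, 50) |
| very_high | [50, 100] |

Band edges are configurable via `rac_bands()` so a literal published
threshold set can be restored; every value maps to exactly one band and
classification is monotone in RAC. Fractions are stored as percentages,
not proportions, because that is the scale on which they are reported and
summed. Regulatory soil screening (`screen_soil_limits()`) uses a strict
`>` on the upper permissible bound: a total exactly at the limit is
compliant, which is the conservative reading of "exceeded" absent an
explicit convention.

## Plant side: BCF, TF, pigments

$$\mathrm{BCF} = \frac{[\text{metal in roots}]}{[\text{metal in soil}]},
\qquad
\mathrm{TF} = \frac{[\text{metal in leaves}]}{[\text{metal in roots}]}$$

both on mg kg$^{-1}$ dry weight. BCF uses the *initial* (pre-cultivation)
soil total by default — that is the denominator under which the bundled
study's uptake table reproduces — with the timepoint selectable in
`bcf_tf_table()`. A species is a *non-accumulator* for a metal when every
computed factor is below 1. Ratios are kept at full precision internally
and rounded to 2 decimals only at report time (`report_ratio()`).

Censored ("< LOD") tissue values propagate as **NC** (not computable,
`NA` in R) rather than being substituted: a censored root makes both BCF
and TF non-computable, and report renderers print the literal string
`"NC"`. An LOD/2 substitution mode exists for sensitivity analysis in
`risk_table(censored_policy = "half_lod")` but is never the default,
because substitution silently converts a bound into a number.

Leaf pigments use the Lichtenthaler 80%-acetone equations
(`pigments()`): chlorophyll a $= 12.25A_{663} - 2.79A_{647}$, chlorophyll
b $= 21.50A_{647} - 5.10A_{663}$, total chlorophyll
$= 7.15A_{663} + 18.71A_{647}$, carotenoids
$= (1000A_{470} - 1.82\,\mathrm{Chl}_a - 85.02\,\mathrm{Chl}_b)/198$.
The total-chlorophyll coefficient set is algebraically the sum of the a
and b sets ($12.25-5.10 = 7.15$, $21.50-2.79 = 18.71$), so
`chl_total == chl_a + chl_b` holds identically — asserted as a property
test. A negative pigment concentration is physically impossible; results
are returned unclamped with `valid = FALSE` so a bad extract stays
diagnosable instead of being silently zeroed.

Leaf area uses the punch method: total dry weight scaled by the
area-to-weight ratio of punched disks, with the default disk area 5.72
cm$^2$ (the rounded area of a 2.7 cm diameter punch; $\pi \cdot 1.35^2 =
5.726$, the rounded constant is retained deliberately).

## Dietary risk

With food intake rate FIR (g day$^{-1}$, converted to kg), body weight BW
(kg), exposure frequency EF (d yr$^{-1}$), duration ED (yr) and averaging
time AT (d):

$$\mathrm{EDI} = \frac{\mathrm{FIR} \times C}{\mathrm{BW}}, \quad
\mathrm{CDI} = \frac{\mathrm{EDI} \times \mathrm{EF} \times \mathrm{ED}}{\mathrm{AT}}, \quad
\mathrm{THQ} = \frac{\mathrm{CDI}}{\mathrm{RfD}}, \quad
\mathrm{HI} = \sum_i \mathrm{THQ}_i, \quad
\mathrm{ILCR} = \mathrm{CDI} \times \mathrm{CSF}$$

Defaults (35.7 g day$^{-1}$ — 250 g week$^{-1}$ —, 70 kg, 365 d yr$^{-1}$,
70 yr, 25550 d) describe a chronic adult consumer; because
$365 \times 70 = 25550$ exactly, CDI equals EDI to machine precision
under the defaults, and the implementation computes the EF·ED/AT factor
as a single scalar so the identity is exact. HI sums only computed THQs
(NC metals excluded, not imputed as zero); HI < 1 is negligible.

**ILCR unit modes.** The dimensionally standard USEPA form multiplies a
CDI in mg kg$^{-1}$ day$^{-1}$ by the slope factor. The reference risk
table this package reproduces, however, is only recovered when the CDI
enters the product on the µg scale: for Pb at 0.090 mg kg$^{-1}$,
$0.0459 \times 0.0085 = 3.90\times10^{-4}$, whereas the mg-scale product
is $3.90\times10^{-7}$ — a factor-1000 gap that moves the result across
two classification bands. Both modes are implemented:
`unit_mode = "paper_compat"` (the default, for reproduction runs) and
`"strict_mg"` (recommended for de-novo assessments). The relation
`strict_mg == paper_compat / 1000` is asserted as a property test, and
the discrepancy is documented here rather than hidden in either mode.

**MOE.** For genotoxic carcinogens without a health-based guidance value,
$\mathrm{MOE} = \mathrm{BMDL}/\mathrm{EDI}$ per benchmark endpoint (both
µg kg$^{-1}$ BW day$^{-1}$), rounded to the nearest integer for report
(32.7 → 33, 10.89 → 11). MOE < 10 flags concern (EFSA threshold); values
in $[10, 15)$ additionally carry a `near_threshold` flag — a package
choice, since "close to the boundary" is qualitative in the sources; 1.5×
the threshold is the cutoff used.

**Weekly intake.** $7 \times \mathrm{EDI}$ compared against the PTWI
where one exists (4 µg kg$^{-1}$ BW week$^{-1}$ for Hg). MAC screening
uses strict exceedance; equality is compliant; censored concentrations
are compliant-by-default with a distinct `censored_compliant` status.

## Analytical QC

LOD = 3·sd and LOQ = 10·sd of a method-blank series, using the sample
(n−1) standard deviation — the sources are silent on the estimator and
n−1 is standard analytical practice. The blank count is data, not a
constant (soil methods commonly use 7 blanks, plant methods 10), so
`detection_limits()` takes whatever series is supplied; LOQ/LOD is 10/3
exactly for any series. Censoring bands are half-open with inclusive
lower edges: value < LOD censored, [LOD, LOQ) semi-quantitative, ≥ LOQ
quantitative; a value exactly at the LOD is semi-quantitative. Negative
instrument readings (blank-corrected noise) censor with a warning.

# The synthetic-study generator

`synthetic_config()` / `generate_study()` emulate a distance-gradient
screen-house study: 3 sites at 0.6, 3 and 10 km from the source, 3
replicate plants per site, metals Hg/Pb/As, 4 fruit harvests. Soil totals
default to a realistic mining gradient (Hg 22.13/5.38/2.05, Pb
1997/186/57, As 37.5/15.7/7.9 mg kg$^{-1}$) and may instead follow
$c_0 e^{-k d}$. True uptake factors default to non-accumulator magnitude
(BCF 0.30/0.15/0.10, TF 0.07/0.04/0.04 for Hg/Pb/As).

Noise is **multiplicative lognormal with unit mean** at coefficient of
variation `noise_cv`: concentrations are positive and replicate
uncertainties in this field scale with the mean, so a CV — not an
additive SD — is the natural parameter. The default CV of 0.1 sits in the
middle of the 2–20% relative SDs typical of replicate trace-metal
measurements. With $\sigma^2 = \log(1+\mathrm{CV}^2)$ and meanlog
$-\sigma^2/2$, the noise has expectation exactly 1, so ratio estimators
(BCF, TF) are recoverable without bias correction; parameter recovery is
asserted exact at CV = 0 and within 3 standard errors at CV = 0.2 with 50
replicates. Stem concentrations are generated as an independent partition
of root (organ orderings vary between sites in real data; no fixed
ordering is imposed), and fruit as a partition of the expected leaf
concentration. Values below the matrix LOD are emitted as censored
records, and the censoring frequency matches the analytic lognormal
exceedance probability (property-tested). Leaf-extract absorbances are
obtained by inverting the pigment equations (a 2×2 linear solve plus the
carotenoid equation); any non-negative pigment triple is feasible because
the inversion matrix has non-negative adjugate entries. The generator
writes real CSV files (`write_study()`) so the file-based pipeline is
exercised end to end, and output is byte-identical under a fixed seed.

What a green synthetic test does **not** establish: the generator has no
spatial transport, no temporal soil dynamics, no plant growth, no
between-organ correlation beyond the partition structure, and lognormal
noise cannot produce the occasional gross outliers of real instrument
data. It validates the arithmetic chain and the censoring logic, not the
biology.

# Bundled example study and known irreproducibilities

`example_study()` ships a small real-world-shaped dataset (sweet pepper
on three gold-mining-impacted soils; see `NOTES.md` in the directory for
table-by-table provenance). Running `run_full_pipeline()` on it
reproduces the published uptake and risk tables cell for cell, with three
documented exceptions that are data inconsistencies in the source
tables, not computational choices:

* **Harvest C2 at S2 (THQ Hg).** The source risk table prints 0.119 for
  C2 and 0.085 for C4, yet the concentration table records the same
  value, 0.05 ± 0.01 mg kg$^{-1}$, for both harvests; 0.119 requires
  0.07. A deterministic pipeline cannot print both. The acceptance test
  asserts the printed value faithfully and that single expectation is
  expected to fail.
* **Hg BCF at S3.** Printed as 0.47 while the printed inputs give
  0.95/2.05 = 0.4634 → 0.46; presumably computed from unrounded inputs.
  Excluded from golden checks.
* **Site-level Hg EDI at S2.** The stated 0.037 µg kg$^{-1}$ BW
  day$^{-1}$ is not the mean of the four harvest concentrations (which
  gives 0.0344); the averaging rule is unknown. The weekly-intake check
  therefore starts from the stated EDI rather than re-deriving it.

# Numerical and degenerate-input choices

* Censored values never become numbers implicitly; every consumer
  branches on the flag.
* `concentration_change()` reports percent change as undefined (with a
  flag) when the baseline is 0 rather than emitting Inf.
* Constant blank series give LOD = LOQ = 0 with a warning, not an error:
  a perfectly stable blank is degenerate but interpretable.
* MOE at EDI = 0 is `Inf`, reported as no-concern.
* Report rendering (`render_value()`): `NA` → `"NC"`, 0 → `"0"`,
  magnitudes below 0.01 in scientific notation with three significant
  digits (`"3.90E-04"`), otherwise three significant figures — the
  conventions of published risk tables. JSON summaries carry the same
  pre-rounding numbers as the rendered tables (single source of truth).

# Limitations

Deterministic point-estimate exposure only (no Monte Carlo), single
pathway (ingestion of one commodity), no speciation adjustment for As,
adult body weight only (child sensitivity enters solely through the
children's BMDL endpoint), and the accumulator rule is the simple
below-1 criterion without hyperaccumulator thresholds.
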