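---
title: "Methods: dietary heavy-metal risk assessment for farmed fish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary heavy-metal risk assessment for farmed fish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(troutrisk)
```

## Scope and setting

`troutrisk` implements the exposure-assessment workflow used to screen
human health risk from consuming fish raised in metal-impacted rivers. The
reference design is the monitoring campaign on the Tishgo River (central
Peruvian Andes, downstream of the abandoned La Oroya smelter): three river
sectors (upper, middle, lower course), three matrices per sector (rainbow
trout muscle in mg/kg wet weight, water in mg/L, sediment in mg/kg as
reported), four elements (As, Cu, Pb, Zn), and twelve replicates per cell.
All machinery is generic over that design: the element registry is
extensible and every parameter of the risk chain is explicit and
overridable.

## The deterministic risk chain

For a consumer of body weight $BW$ (kg) eating fish at an ingestion rate
$IR$ (kg/day), the estimated daily intake of an element with mean muscle
concentration $MC$ (mg/kg) is

$$EDI = \frac{MC \cdot IR \cdot EF \cdot ED}{BW \cdot AT}
        \cdot ADAF \cdot AR_m ,$$

with exposure frequency $EF$ (days/year), exposure duration $ED$ (years),
averaging time $AT$ (days, default $EF \cdot ED$, at which the frequency
terms cancel), the adult age-dependent adjustment factor $ADAF = 1$, and
the element's gastrointestinal absorption efficiency $AR_m$ (Pb 0.33,
As 0.75, 1 otherwise). The estimated weekly intake is $EWI = 7 \cdot EDI$.

The non-carcinogenic screen is the target hazard quotient

$$THQ = \frac{EF \cdot ED \cdot FIR \cdot C \cdot 10^{-3}}
             {RfD \cdot BW \cdot AT},$$

where $FIR$ is the fish ingestion rate in g/day and the $10^{-3}$ is its
gram-to-kilogram conversion; $AR_m$ deliberately does **not** enter the
quotient — it belongs to the absorbed-intake path ($EDI$, and through it
the cancer risk) only. The hazard index $HI = \sum_i THQ_i$ is an exact
sum; $THQ$ or $HI > 1$ flags potential non-carcinogenic effects over a
lifetime.

The carcinogenic screen multiplies intake by the cancer slope factor:

$$CR = \frac{EF \cdot ED \cdot CSF \cdot EDI}{AT} \cdot 10^{-3},
\qquad TCR = \sum_i CR_i ,$$

with $TCR$ classified against the conventional acceptability band
$[10^{-6}, 10^{-4}]$ (closed at both ends). The trailing $10^{-3}$ in $CR$
has no clean dimensional reading; the package keeps it in the default
`"as_printed"` mode for fidelity to the source methodology and exposes an
`"unscaled"` mode that omits it, recording the mode in every output. Both
modes are reported by the acceptance script so the three-orders-of-
magnitude sensitivity is always visible.

### Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `IR` | 0.34 | kg/person/day | acceptable ingestion rate for the study population |
| `FIR` | 340 | g/day | same quantity on the gram scale used by THQ |
| `EF` | 365 | days/year | year-round consumption |
| `ED` | 74.8 | years | average life expectancy |
| `BW` | 60 | kg | adult body weight |
| `AT` | `EF * ED` | days | chronic (non-carcinogenic) averaging time |
| `ADAF` | 1 | — | adult consumer |
| `ARm` | Pb 0.33, As 0.75, else 1 | fraction | gastrointestinal absorption |
| `RfD` | As 3e-4, Cu 4e-2, Pb 3.5e-3, Zn 3e-1 | mg/kg-bw/day | USEPA IRIS oral reference doses |
| `CSF` | As 1.5, Pb 0.0085 | (mg/kg-day)^-1 | USEPA IRIS slope factors |

The reference doses are a design choice: the source methodology cites the
IRIS database but does not print its RfD values, and no standard RfD set
reproduces the hazard quotients in the published sector table from the
published concentrations (we verified this by back-solving). The package
therefore treats that published table ([`reference_hazard_table()`]) purely
as an internal-consistency surface — its hazard index must equal the sum
of its quotients — and keeps every parameter explicit rather than
hard-coding a reconciliation. Published weekly-intake comparison values
(PTWI/PTDI) are referenced but not printed in the source methodology, so
no compliance table is implemented.

## Bioaccumulation factors

$BCF = C_{muscle}/C_{water}$ and $BSAF = C_{muscle}/C_{sediment}$ are
plain quotients. `factor_profile()` forms one ratio per replicate pair,
matching samples by replicate id within a sector — the only auditable
pairing rule for co-located sampling — and reports both the median of
per-pair ratios and the ratio of cell medians, which generally differ.
Zero denominators are domain errors, never silent infinities. BCF divides
mg/kg by mg/L, so its "dimensionless" value follows the customary L/kg
convention. Published factor distributions for this system are sometimes
labelled with "%", although the defining quotients are raw ratios (the
lower-course Zn medians give $2.51/0.05 = 50.2$, not a percentage); the
package reports raw ratios and treats such labels as cosmetic.

## Monte Carlo exceedance estimation

Concentration uncertainty is propagated by simulation: each carcinogen's
muscle concentration gets a non-negative distribution fitted to the cell's
(mean, sd), each of `n_draws` concentration vectors is pushed through the
chain, and the exceedance probability $\Pr(TCR > \text{threshold})$ is
estimated with its binomial standard error $\sqrt{p(1-p)/n}$ and
percentile summaries at the chosen confidence level (default 0.95,
10,000 draws).

Numerical choices:

* **Family.** Default lognormal with exact moment matching
  ($\sigma_{\log}^2 = \log(1 + cv^2)$), because concentrations are
  positive and right-skewed and the underlying field data are reported as
  non-normal. A zero-truncated normal parameterized by the pre-truncation
  mean/sd is the alternative; truncation biases its realized mean upward,
  which is documented rather than corrected. A zero sd degenerates to a
  point mass.
* **Reproducibility.** One seeded stream per simulation; draws are
  generated element-major in a fixed element order, and the caller's RNG
  state is restored afterwards, so a seed pins results bit-for-bit across
  platforms. Per-sector simulations use consecutive derived seeds.
* **Correlation.** Elements are independent by default (no inter-element
  correlation is established for this system); a Gaussian-copula rank
  correlation knob is exposed for sensitivity analysis.
* **Threshold.** Default $10^{-4}$, the upper bound of the acceptability
  band; `threshold_sweep()` covers the whole band because which bound
  defines "exceedance" in published headline percentages for this system
  is not stated. A published lower-course exceedance figure of 1.27%
  cannot be tied to a specific configuration (family, threshold bound,
  and $CR$ scale mode are all unstated), so the package asserts
  distributional properties — seed determinism, monotone sweeps,
  degenerate step behaviour, agreement of the simulated mean with the
  deterministic chain (the chain is linear in concentration) — and
  reports the sweep under both scale modes next to any external figure
  rather than claiming to reproduce it.

## Nonparametric statistics

Sector differences use the Kruskal–Wallis rank test (tie-corrected H,
chi-squared reference with $k-1$ df). Comparison with a regulatory
maximum limit uses the one-sample Wilcoxon signed-rank test on
(value − ML): values exactly at the limit are dropped, the exact
distribution is used for $n \le 25$ (feasible at the study's $n = 12$;
ties fall back to the corrected normal approximation), and the
significant-exceedance flag mirrors the asterisk convention of monitoring
tables (one-sided "greater" by default; two-sided available, and every
report names the choice). Cross-matrix association uses Spearman's rho
with average ranks, aligning records by (sector, replicate id) and
pooling sectors ($n = 36$) to produce a single whole-river panel; per-
sector panels are available. Raw p-values are reported to match field
practice; the long-format correlation output also carries a
Benjamini–Hochberg column for transparency.

## The synthetic-data generator

`generate_concentrations()` emulates the study: per (sector, matrix,
element) cell it draws replicates from a distribution matched to the
cell's target mean and sd, with `generator_targets()` defaulting to the
published descriptive statistics of the study area (the published "±"
dispersion is read as a standard deviation — the most common convention,
though the source does not define it; this is documented prominently).
Defaults are lognormal, 12 replicates, all draws strictly positive.
`inject_exceedance_pattern()` multiplies selected cells by the minimum
factor pushing their median strictly above 1.2 × ML, is idempotent, and
leaves all other cells untouched — useful for constructing datasets with
a known exceedance fingerprint.

What the generator does *not* emulate: spatial or temporal
autocorrelation, inter-element correlation (beyond the optional copula
knob shared with the simulator), censored values or non-detects (rejected
at ingest), and measurement error structure. Tests passing on synthetic
data therefore demonstrate correctness of the computational chain under
the study's marginal summaries, not robustness to those real-data
features.

With the default targets, a large-replicate synthetic dataset reproduces
the published limit-exceedance fingerprint (water As in the lower and
middle course; water Pb everywhere; sediment As and Zn everywhere;
sediment Pb in the lower and upper course) because every flagged cell
sits well above its limit relative to its spread, while unflagged cells
sit at or below theirs. Mean recovery at 10,000 replicates per cell is
accurate to a fraction of a percent for most cells; note that for the
highest-dispersion cells (cv near 1) a 1% band is only on the order of
one Monte Carlo standard error at that size, so single-run sample means
can land just outside it.

## Degenerate inputs and tie-breaks

Medians use the midpoint of the two central order statistics for even n.
Empty groups, empty hazard/risk vectors, all-values-at-limit Wilcoxon
inputs, unpaired replicates, unknown cells, negative concentrations and
zero denominators are all explicit, named errors. The TCR band
classification is closed: exactly $10^{-6}$ or $10^{-4}$ counts as
"within band".

## Problem sizes

The test suite exercises the study design at its native size (12
replicates per cell; 432 records), uses 10,000 draws for simulation
checks, 10,000 replicates per cell for generator-recovery checks, 2,000
permutations for p-value calibration, and $10^5$–$10^6$ draws for
distribution-moment checks; the full suite runs in well under a minute.

## Worked example

```{r example}
x <- generate_concentrations(seed = 7)
fit <- dietary_risk(x)
summary(fit)
sim <- simulate(fit, nsim = 2000, seed = 7)
as.data.frame(sim)
```
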