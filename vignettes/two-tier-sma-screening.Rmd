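---
title: "Two-tier SMA screening: model, decision rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tier SMA screening: model, decision rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smnscreen)
library(dplyr)
```

## The screening problem

Spinal muscular atrophy (SMA) is, in more than 95% of cases, caused by a
homozygous deletion of exon 7 of *SMN1*. The near-identical paralog *SMN2*
differs in exon 7 by a single C-to-T substitution; its copy number modifies
disease severity but cannot compensate for *SMN1* loss. Because treatment
works best presymptomatically, newborn-screening programs need a fast,
cheap first-tier test on dried-blood-spot (DBS) punches that flags absent
*SMN1*, followed by a confirmatory quantitative test.

`smnscreen` implements such a two-tier workflow as executable, testable
code, together with a synthetic-data generator that emulates the data the
assays produce. The package is a simulation laboratory for the *decision
procedure*: every rule is deterministic and exercised end to end without
any instrument data.

## Tier 1: the melt-curve model

A single fluorescent probe hybridizes to asymmetrically amplified exon-7
amplicons of both genes. Three duplex species can form, each melting at its
own temperature:

* *SMN1* at 63 °C (perfect match, designed to be the hottest peak),
* *SMN2* at 56 °C (one mismatch),
* a synthetic quantity ("Q") fragment at 49 °C (many mismatches).

Each well's fluorescence is modelled as

$$F(T) = q(b)\Big[F_0 + A_1\,\sigma\!\big(\tfrac{T_{m1}+\delta - T}{w}\big)
 + A_2\,\sigma\!\big(\tfrac{T_{m2} - T}{w}\big)
 + A_Q\,\sigma\!\big(\tfrac{T_{mQ} - T}{w}\big)\Big] + \varepsilon,$$

with $\sigma$ the standard logistic function, $w$ the shared transition
width, $\delta \le 0$ an optional probe-region variant shift, and
$\varepsilon$ i.i.d. Gaussian reading noise. In $-\mathrm{d}F/\mathrm{d}T$
each transition is a logistic density with closed-form peak height
$A/(4w)$ at $T_m$ — the analytic oracle used throughout the tests.

Two modelling commitments shape everything downstream:

* **Plateau amplitudes.** Asymmetric PCR is driven to completion, so the
  probe-bound genomic amplitude is split between the genes by their copy
  *ratio*: $A_1/A_2 = c_1/c_2$ with
  $A_1 + A_2 = A_\mathrm{tot}\,D/(D+k)$ for input DNA $D$. Absolute copy
  number never reaches the noiseless curve — genotypes (1,1) and (2,2)
  are *identical* by construction. This is what makes the assay blind to
  carriers with common ratios, a regulatory requirement, and it is tested
  as an exact invariant.
* **Q competition.** The Q fragment takes the complementary amplitude
  $A_Q = A_\mathrm{tot}\,k/(D+k)$. With $k = 0.7$ ng and a nominal
  saturated-punch yield of 10 ng, the Q peak strictly dominates only below
  roughly 1–1.4 ng, i.e. ~10% of a normal yield, making it a pure
  input-DNA alarm.

Blood quenches the Cy5 fluorophore; oversaturated spots are modelled by
$q(b) = \exp(-\gamma \max(0, b-1))$ with blood load $b$ ($1$ = saturated).
`input_range_experiment()` reproduces the two qualitative signatures:
taller Q peaks with increasing dilution, and a globally weaker signal for
oversaturated spots despite more DNA.

### Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `transition_width_c` | 1.2 | °C | typical width of a probe-melt transition |
| `amplitude_total` | 1 | a.u. | fluorescence unit; everything scales with it |
| `q_competition_k` | 0.7 | ng | Q dominates below ~10% of a saturated yield |
| `quench_coefficient` | 0.7 | — | halves the signal at double blood load |
| `curve_noise_sd` | 0.005 | ×amplitude | reading noise (see below) |
| `temp_step_c` | 0.2 | °C | instrument-like acquisition density |
| `dna_meanlog`, `dna_sdlog` | log 10, 0.3 | ng | punch-yield lognormal (CV ≈ 30%) |
| `blood_load_min/max` | 0.85–1.05 | — | screening cards are near-saturated |

The DNA-yield and blood-load distributions are not published anywhere; the
defaults above are one-time choices of what a screening lab would consider
a well-behaved card stream, and both are fully configurable.

### Derivative estimation

The derivative is estimated with a Savitzky–Golay differentiation filter.
Its design is a bias–variance compromise with a hard bias constraint: the
tests require windowed peak heights within 2% of the analytic $A/(4w)$
over transition widths 0.8–1.6 °C. A numerical scan of filter orders and
supports on the 0.2 °C grid shows that order-2 filters cannot satisfy the
bias constraint with any worthwhile noise reduction (an order-2, 1 °C
filter has white-noise gain 1.58 per °C; widening it to 2.4 °C cuts the
gain to 0.37 but attenuates a $w = 0.8$ peak by 11%). An **order-5 filter
over 4.4 °C** attenuates that worst-case peak by only ~1.1% while reducing
noise gain to 0.70 — about 3× less derivative noise than the narrow
order-2 filter. High order over wide support is the standard trick for
derivative filters that must preserve peak amplitude.

With that filter, 0.5% reading noise leaves ~0.35% (of amplitude) noise on
the derivative. The SD074 threshold control's *SMN1* peak measures
$A_\mathrm{tot}/6 \cdot 1/(4w) \approx 3.3\%$ of amplitude, i.e. ~9× the
derivative noise — a "low but clearly visible" peak, as a threshold
control must be. At 1% reading noise that margin would drop to ~2σ against
the presence threshold and plate QC would fail stochastically, which is
why 0.5% is the default study condition.

### Peak calling

Three disjoint windows are searched: *SMN1* [61, 65] °C, *SMN2* [54, 58]
°C, Q [47, 51] °C. The *SMN1* window is deliberately asymmetric: any
sequence variant under the probe can only *lower* the melting temperature,
so a tight lower edge at −2 °C pushes variant-shifted peaks out of the
window and fails safe towards referral, never towards a missed case.

Within a window the caller takes the tallest **interior local maximum** as
the apex. A window whose maximum sits on an edge with no interior local
maximum is the monotone shoulder of a neighbouring transition (the
logistic tails of a 1.2 °C transition still contribute ~1% of amplitude
4.5 °C away) and is flagged `non_apical`, i.e. absent.

A peak is `present` when its height exceeds
$\max(5 \times \text{noise floor},\; 0.12 \times \text{tallest window
maximum})$. The noise floor is the filter's noise gain times a robust
estimate of the reading noise (median absolute first difference of $F$
over window-free temperatures), which makes every call equivariant under
rescaling of the fluorescence. The relative term exists because shoulder
leakage scales with *signal*, not noise: blanks carry a full-amplitude Q
transition whose tail in the *SMN2* window would otherwise beat any purely
noise-based threshold. Both factors are configurable; the referral set can
only grow as the presence factor is tightened, which is tested as a
monotone-safety property.

### First-tier decision rules

Per specimen well, in order:

1. Q height strictly above both SMN heights → **RETEST** (too little DNA);
   an all-absent peak set → **RETEST** (failed reaction).
2. *SMN2* present and *SMN1* absent → **SECOND_TIER** (putative
   homozygous deletion).
3. *SMN2* present and *SMN1* height ≤ the plate's SD074 reference (mean of
   its two SD074 *SMN1* peaks) → **SECOND_TIER**. The SD074 control DNA
   carries *SMN1*:*SMN2* = 1:5, so this comparison embodies "an
   *SMN2*:*SMN1* ratio of five or more qualifies"; the comparison is
   inclusive because a ratio of exactly five qualifies.
4. Otherwise **NORMAL**.

Plate QC gates everything: both blanks must be Q-dominant with no SMN
peaks, both SD075 positive controls must lack *SMN1* while showing *SMN2*,
and both SD074 controls must show both peaks with *SMN1* < *SMN2*. A
failed plate is excluded wholesale.

Retested wells are re-simulated as fresh reactions (new punch, new DNA
draw). Wells still uninterpretable after `max_retest_rounds` (default 2)
escalate to **SECOND_TIER**: in a screening context, persistent ambiguity
must resolve towards confirmation, never towards a missed case.

## Tier 2: MLPA copy numbers

Probe heights follow $h_p = s\,k_p\,c_p(1+\epsilon_p)$ — per-sample scale,
fixed per-run probe efficiency, target copy number, multiplicative noise
(CV 5% by default). The synthetic panel has 2 probes per SMN gene per exon
(7 and 8) and 10 two-copy reference probes; the real kit's exact panel is
proprietary, so this is an explicitly synthetic stand-in with the same
structure.

Normalization is a two-stage median scheme (a documented, deterministic
replacement for the vendor's proprietary software): divide by the sample's
median reference-probe height (cancels $s$), then by the median of that
statistic across ≥ 3 known-normal calibrators (cancels $k_p$). A probe
ratio $r$ then estimates $c_p/2$; per gene the median over its 4 probes is
doubled and rounded to an integer. Combined ratios farther than 0.2 (ratio
scale) from every half-integer band centre are flagged ambiguous and the
reaction is repeated once, mirroring the screening workflow in which
ambiguous copy-number results trigger an MLPA retest. Error magnitudes
scale with copy number while the band does not, so ambiguity concentrates
at 3–4 copies — the same place real MLPA retests concentrate.

A sample is `confirmed_positive` exactly when *SMN1* is unambiguously
called at 0 copies; on noiseless data tier-1 referral with reason
`SMN1_ABSENT` and MLPA confirmation agree sample-for-sample, and this
concordance is measured (not assumed) on every simulated cohort.

## The validation experiment

`run_validation()` chains everything: cohort → plates → curves → peaks →
QC → first-tier calls → retest resolution → MLPA on *all* samples →
metrics against generator truth. The default composition is the published
validation cohort's genotype cross-tabulation (422 samples, 47 of them
lacking *SMN1* exon 7):

```{r}
validation_composition() |> summarise(samples = sum(n),
                                      sma = sum(n[smn1_copies == 0]))
```

```{r, eval = FALSE}
res <- run_validation(seed = 1)
glance(res)
```

Sensitivity and specificity are scored against the generator's deletion
truth (`smn1_copies == 0`); `concordance` is the agreement between tier-1
positivity and MLPA confirmation. Problem sizes are chosen so a full run
(452 wells × 151 temperature points, 425 MLPA profiles) takes a few
seconds, and the Monte-Carlo recovery experiment (500 profiles) well under
a minute.

## What the generator does and does not emulate

Emulated: copy-ratio amplitude structure, Q-fragment competition, blood
quenching, probe-variant Tm shifts, plate layouts with control wells,
reading noise, MLPA probe structure with realistic noise, and the
screening cohort's genotype composition.

Not emulated: instrument-specific raw formats and drift, baseline slopes
and dye bleed-through, true thermodynamic Tm prediction from sequence
(primer/probe sequences are unpublished), inter-operator variation of the
original visual-inspection protocol, and non-deletion SMA alleles'
molecular detail. A pathogenic point mutation on a retained *SMN1* copy is
representable (`smn1_functional_copies < smn1_copies`): the melt profile
is normal by design and the pipeline reports the case as a *designed
miss* — first-tier screens of this type are expected to miss the 2–5% of
SMA cases not caused by the exon-7 deletion, and the simulation reproduces
that limitation rather than hiding it.

Consequently, passing tests demonstrate that the *decision logic* is
correct and fail-safe under the modelled physics and noise — they do not
certify performance on real instrument data.

## Numerical and degenerate-input choices

* Temperature grid 45–75 °C at 0.2 °C; curves shorter than the filter
  support are rejected.
* A flat (or constant) curve yields zero heights and no presence calls; an
  exact-zero threshold is avoided with a scale-equivariant numerical
  epsilon.
* Q-height ties with SMN peaks do not trigger retests (strict maximum
  rule); ties are measure-zero under noise.
* `round(2r)` banker's-rounding edge cases are measure-zero and further
  guarded by the ±0.2 ambiguity band.
* Blanks carry genotype (0,0) with zero DNA; viability checks apply only
  to wells containing DNA.
* All randomness flows from one integer seed through salted sub-streams
  (cohort, curves, retest rounds, MLPA batches), so identical inputs give
  byte-identical outputs; manifests record seed and configuration.
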