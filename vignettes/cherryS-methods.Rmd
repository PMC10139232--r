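---
title: "Methods: one-tube S-allele and MGST genotyping in software"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-tube S-allele and MGST genotyping in software}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cherryS)
```

## The assay in one paragraph

Sweet cherry (*Prunus avium*) carries a gametophytic self-incompatibility
system: a pollen grain is rejected when its S-haplotype matches either pistil
S-allele. Mutations inactivating the pollen determinant SFB create the
self-compatible alleles S3′, S4′ and S5′, and a transposon-like insertion in
the MGST promoter is associated with partial self-compatibility. The assay
this package implements multiplexes 27 primers in one PCR and reads the
products on a four-dye capillary: the blue (6-FAM) channel carries the
universal S-RNase intron-1 fragments plus the SFB markers that separate SC
from SI alleles, red (PET) carries allele-specific confirmation fragments,
green (VIC) carries the three MGST promoter alleles, and yellow (NED) carries
a single-copy *PaveIF-1A* fragment used as a diploid calibrator. A genotype
call is therefore a pure function of a peak table — (dye, size, height)
triplets — and of the panel constants, which is exactly the function this
package computes.

## Panel model

Fragment bins are keyed by **observed** sizes, not sequence lengths:
fluorescently labeled fragments migrate 0–7 nt short of their sequence
length (about 5 nt for 6-FAM and VIC, 2 for NED, 0–2 for PET), and the
caller consumes mobility-affected sizes. Expected (sequence) sizes are kept
on each bin for the in-silico PCR module. Alleles that were published with an
expected size only (S10, S24, S28–S31, S34, S38) receive *provisional* bins
at `expected + channel offset`; any call that touches one carries a
`PROVISIONAL_BIN` flag because the true observed position may differ by the
offset window (±2 nt).

The default bin tolerance is **0.45 nt**. The closest pair of bins in the
panel is S5′/S5 at 384/385 nt, 1 nt apart, so any tolerance below 0.5 nt
separates them; 0.45 leaves a small guard band below the ambiguity midpoint.
A consequence worth stating: with the tolerance strictly below half the
minimum bin separation (a precondition `bin_peaks()` enforces), a peak
equidistant from two bins within tolerance cannot exist — the midpoint of
the closest pair is exactly half their separation away. The ambiguity branch
in the matcher is therefore purely defensive, and a midpoint peak is left
unassigned rather than guessed.

Two bins aggregate alleles the capillary cannot separate: S14/S23 (identical
S-RNase protein, three intronic differences; same expected size) and S21/S25.
These are single composite labels throughout. The panel's **supported** set —
the genotypes the simulator and the exhaustive round-trip sweep cover — is
the 14 SI allele classes that appear in a single-allele row of the published
fragment table with an observed size (S1, S2, S3, S4, S5, S6, S7, S9, S12,
S13, S14/S23, S16, S22, S54) plus the three SC alleles. The S21/S25 bin is
recognized and reported when a peak lands in it, but since neither
constituent allele was ever characterized individually in fragment analysis,
it is treated as detect-only rather than as a supported simulation target.

## Caller rules

Peaks are matched to the nearest same-channel bin within tolerance; the
tallest peak in a bin wins and the rest are kept as shoulders, which absorbs
the double-peaked amplicons some PCR chemistries produce. Allele inference
then applies the assay's interpretation matrix:

* **S3 vs S3′** — both produce the 227 nt S-RNase fragment; only intact S3
  SFB yields the 122 nt fragment. 122+227 is a confirmed S3; 227 alone is
  S3′, but never better than *candidate*: an S3 whose SFB amplification
  failed is observationally identical, which is why the wet protocol insists
  on primer-mix pretesting. The caveat rides along in the call's note.
* **S4 vs S4′** — the 4 nt SFB deletion shifts 181 to 177; 443 is the shared
  S-RNase fragment. All three fragments together are the S4S4′ heterozygote.
* **S5 vs S5′** — 385 vs 384 in the blue channel (the 1 nt pair), with the
  83 nt SFB fragment corroborating S5 only.
* **Confirmation pairs** — S1, S2, S7, S9, S12 each need their universal blue
  and specific red fragment for a *confirmed* call; one without the other is
  *unconfirmed* and flagged. S6 and S24 share the red confirmation bin
  (expected 225 nt from the same primer); the blue fragment separates them,
  with S24 living on a provisional bin adjacent to S22's, so a peak in the
  S22 bin accompanied by the S6/S24 red pattern (and no S22 confirmation) is
  read as a candidate S24.
* **S13 and S54** escape the universal primers entirely and are called from
  their single specific red fragments.

Genotype assembly expects exactly two S-alleles. Three or more flags
`TOO_MANY_S_ALLELES`; zero or an unresolvable one flags `ONE_S_ALLELE`. The
self-compatibility interpretation is `self_compatible` exactly when the
genotype contains S3′, S4′ or S5′; `partial_sc_associated` when it does not
but MGSTins is present; `undetermined` when a `S?` placeholder or an
indeterminate dosage remains; `self_incompatible` otherwise.

## Dosage: resolving the single-allele cases

Four patterns are qualitatively ambiguous: S3 alone (S3S3′ vs S3Sx), S3′
alone, S4′ alone, S5′ alone — in each, a hidden second allele invisible to
the universal primers (written `S?`) would mimic the SC-relevant genotype.
The assay resolves them quantitatively: with PaveIF-1A fixed at two copies
per diploid genome, the control-normalized height of a fragment indicates
its copy number.

The published calibration gives, for each informative peak-height ratio, the
group mean ± SD in the two-copy and one-copy cohorts. For a new sample the
package computes each ratio, converts it to a z-score against each group,
combines z-scores across ratios by root mean square (simple and symmetric;
the correlation between ratios sharing a peak is ignored, which makes the
combined z slightly conservative), and picks the hypothesis with the
smallest combined z. If every hypothesis is more than `z_cut = 3` combined
SDs away the case is *indeterminate*. The published work reports group-level
t-tests rather than a per-sample rule; the nearest-group-in-SD-units rule
and the `z_cut` default are this package's construction.

Three design extensions were needed to make the decision rule total:

* **The true S3 homozygote.** The published contrast is S3S3′ vs S3Sx, but
  S3S3 produces the same 227 dosage as S3S3′ and differs only in the SFB-122
  ratios. The S3-only scenario therefore carries a third hypothesis with
  model-derived expectations (all fragments at two copies), and the
  control/122 ratio — non-informative for the published two-group contrast —
  is admitted when it separates this hypothesis.
* **Generic homozygotes.** A single detected S1 (say) is either S1S1 or
  S1S?. No table exists for these, but the efficiency model gives the
  expected control/fragment ratio directly: `1/e_f` at two copies versus
  `2/e_f` at one, with a relative SD of 0.15 assumed for model-derived
  hypotheses. The same model classifies MGST zygosity from a single green
  bin when `mgst_dosage = TRUE`.
* **MGST-normalized ratios are conditional.** The alternative normalizers
  that divide by (or into) the MGSTwt peak assume a diploid single-allele
  MGST signal; when the run shows two different green bins each is present
  in one copy, so those ratios are skipped with a note.

The S5′-only scenario has no published calibration; it reuses the S3′
calibration shape on the 384 nt bin and every decision through it carries a
provisional warning.

## The synthetic-data generator

`simulate_run()` implements the height model the dosage analysis assumes:
each fragment implied by the genotype (copy number = number of contributing
allele copies; control fixed at 2) emits a peak with

```
height = base_height * (copies * e_f)^gamma * L,
size   = bin_observed + N(0, size_sd)
```

where `e_f` is the fragment's relative amplification efficiency and `L` is
lognormal with unit mean and coefficient of variation `cv` (meanlog
−½·log(1+cv²), sdlog √log(1+cv²), so heights are unbiased). Defaults:
`cv = 0.15`, `size_sd = 0.15` nt, no dropout, no double peaks, `gamma = 1`.
The double-peak artifact, when enabled, is a +1 nt shadow at 60% of the
parent height.

**Efficiencies** are fitted from the calibration tables. Under the model the
log of every predicted group-mean ratio is linear in `gamma` and in
`z_f = gamma·log(e_f)`, so all entries fit by weighted least squares
(weights 1/CV², the delta-method precision of a log mean) with the control
fixed at 1. The strict-proportionality global fit (`default_efficiencies()`)
reproduces every published group mean within 15% (worst entry ≈ 11%). The
residual misfit is informative: the published two-copy/one-copy mean pairs
are not exactly 2:1 (e.g. 2.25/1.30 ≈ 1.73), and the same normalized ratio
differs between cohorts (1.17 vs 1.30 for control/227). Strict
proportionality cannot absorb either. Allowing a sub-linear copy-response
exponent — `height ∝ (copies·e)^gamma`, the signature of a saturating
multiplex PCR — and fitting per calibration table brings every predicted
mean within ~3% of print (fitted `gamma` ≈ 0.90, 0.77, 1.00 for the three
tables). `gamma` stays at 1 everywhere except where a fit to a specific
table asks otherwise.

**The dosage validation study** (`simulate_dosage_study()`) mirrors the
published design: 30 samples per cohort, the masked genotype against a
heterozygote prototype chosen as in the published comparison figures (S3S3′
vs S1S3; S3′S3′ vs S3′S4; S4′S4′ vs S3S4′), MGSTwt/MGSTwt throughout. Each
scenario is simulated with that table's fitted efficiencies and exponent,
per-peak CV calibrated as the table's median printed ratio CV divided by √2
(the CV of a ratio of two independent lognormals), and a sizing SD of
0.05 nt — instrument-grade precision, since sizing scatter is not the
phenomenon under study and a 0.15 nt SD would occasionally throw a peak out
of its 0.45 nt bin. Because both cohorts share one efficiency set, ratios
whose copy numbers cancel (control/122, MGST/control, 443/177) have exactly
equal group means in the generator, matching the published non-significant
t-tests, while the copy-number-informative ratios separate by the published
margins.

**What the generator does not emulate:** stutter and minus-A artifacts,
pull-up between dye channels, size-standard miscalibration, inter-run drift,
template-quality effects, and true biological S-allele diversity beyond the
panel. Passing the simulate→call round trip therefore shows the decision
logic is internally consistent with the published interpretation matrix and
calibrations — not that every real-world trace will be called correctly.

## Numerical and design choices, collected

| Choice | Value | Why |
|---|---|---|
| bin tolerance | 0.45 nt | below the 0.5 nt ambiguity midpoint of the S5/S5′ pair |
| noise floor | 50 RFU | typical analysis threshold; configurable |
| control floor | 100 RFU | a control below this is flagged `CONTROL_LOW` |
| `z_cut` | 3 | per-sample decision rule constructed from group statistics |
| model-hypothesis SD | 0.15 × mean | matches the mid-range of published ratio CVs |
| F-test alpha | 0.05 | classical pooled-vs-Welch gate |
| in-silico defaults | 2 mismatches, 3 protected 3′ bases | reproduces the S5-primer logic: a 3′-terminal mismatch plus a near-3′ destabilizing mismatch predict no S5′ amplification |
| sweep / study sizes | 153 genotype pairs × 6 MGST; 30 per cohort | the full supported cross with repetition; the published cohort size |

Degenerate inputs: empty peak lists are legal (failed runs) and produce a
`S?/S?` call with flags; zero-variance groups fall back to Welch with a
note; a missing control disables dosage rather than guessing; unknown dyes,
alleles and fragments raise errors naming the offender.

## Known limitations

* S3′ can never be *confirmed*, only a candidate — an inherent limit of an
  absence-based marker, inherited from the assay design.
* The S24/S22 disambiguation rests on provisional bin positions; a real S24
  observation should be used to pin its observed size (the panel JSON makes
  this a one-line edit).
* The dosage rule assumes the sample was amplified under the same conditions
  as the calibration cohorts; per-laboratory recalibration of the tables is
  expected, and the panel JSON carries the calibration constants for that
  purpose.
* The in-silico module predicts amplification from mismatch counts only; no
  melting temperature, dimer or secondary-structure modeling.
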