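---
title: "Comparing hand-swab STR profiles: counting rules, interpretation and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing hand-swab STR profiles: counting rules, interpretation and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strwash)
```

## The problem

Touch DNA — corneocytes, nucleated epithelial cells and cell-free DNA
deposited through skin contact — is routinely recovered from hands and
handled objects. Whether a usable STR profile results depends on the
donor's shedder status, on prior activities, and on interventions such as
handwashing. `strwash` provides the analysis layer for two-condition
within-subject experiments on this question: each subject contributes a
buccal-swab reference genotype and one evidence swab per condition (here,
palms swabbed before washing, `HSWW`, and immediately after washing with
antibacterial soap followed by alcohol sanitizer, `HSWA`).

## Counting rules

All counting runs over the 23 autosomal loci of the Fusion 6C panel.
Amelogenin and the three Y-STRs are validated, carried through the I/O and
reported in the per-locus detail, but excluded from every tally — sex
markers would otherwise inflate counts asymmetrically between male and
female subjects.

For one evidence/reference pair: expected `E` counts distinct reference
designations per locus (heterozygote 2, homozygote 1); detected `D` counts
reference alleles present in the evidence at the same locus; drop-in `I`
counts evidence alleles the reference lacks, including alleles at loci
where the reference has no genotype; drop-out is `O = E − D` by
definition, and recovery is `R = 100 D / E` (an empty reference is an
error — `R` is undefined at `E = 0`). Allele identity is exact string
equality of trimmed designations: `13.3` never matches `13`, and no
numeric tolerance is applied. Peak heights play no role in comparison —
any analytic-threshold filtering is assumed to have happened upstream in
the typing software.

Two conventions here were genuinely open and are fixed as follows. First,
when a locus already fully matches the reference and carries additional
alleles, *every* non-reference allele counts as drop-in (there is no cap
at a locus); this is the only reading under which a heavily mixed sample
can show a drop-in count approaching a full second profile. Second, a
reference homozygote detected as its single allele scores 1 (not 0.5) in
the per-locus score — the 0.5 score is reserved for a heterozygote losing
exactly one allele.

## Profile interpretation

A profile with fewer than 10 typed autosomal loci is *inconclusive*; the
boundary is strict, so exactly 10 typed loci is interpretable. A profile
showing three or more allelic signals at two or more loci is a *mixture*;
otherwise it is *single source*. Mixture detection needs only allele
counts, never heights.

The strong-contributor rule asks whether one or two peaks dominate every
typed locus by a height ratio of at least 3:1. We read "at each locus"
conservatively: a single failing locus vetoes the designation. Per locus
the selection is adaptive between one and two alleles: a pair is preferred
(a diploid contributor carries up to two alleles), falling back to the
single tallest peak when only it dominates. Concretely, with peaks sorted
descending `h1 ≥ h2 ≥ h3 …`: a one-peak locus passes trivially; a two-peak
locus selects `{1}` if `h1 ≥ 3 h2` and `{1, 2}` otherwise (passing
trivially); with three or more peaks, `{1, 2}` is selected if
`h2 ≥ 3 h3`, else `{1}` if `h1 ≥ 3 h2`, else the locus fails. A strict
"always the top two" rule was rejected because it cannot recover a major
contributor who is homozygous at a locus where the minor contributes
distinct alleles — the adaptive rule recovers the true major genotype
exactly in the noise-free 10:1 limit, which the test suite asserts. Height
ties break by allele designation so extraction is deterministic, and the
whole rule is invariant to rescaling heights by a positive constant.

## Group statistics

Recovery percentages are kept at full precision; only *reported* medians
are truncated — floored, not rounded — to two decimals. Truncation is the
convention that reproduces the bundled study's published group medians
(3.43, 9.58, 42.67 where rounding would print 3.44, 9.59, 42.68), and it
is applied uniformly. A half-ulp guard (`floor(round(100 x, 9)) / 100`)
keeps binary floating-point noise from flooring values that land exactly
on a hundredth.

Box-plot summaries use quartiles by linear interpolation of order
statistics (position `p (n − 1) + 1`, `quantile` type 7) and whiskers at
the most extreme observations within 1.5 IQR of the quartiles. The
quartile convention is stated because published box plots are rarely
bit-reproducible across software.

Two-sample comparisons use Student's *t*-test in all three variants —
pooled (equal variance), Welch, and paired (the design is within-subject,
so pairing is defensible) — via `stats::t.test`. The bundled study's
report prints all three side by side: the variant behind its originally
reported p-values is not documented, and on the bundled percentages the
three variants give 1.42e-6, 1.39e-5 and 9.73e-6 respectively for the
overall pre- vs post-wash contrast, all significant at α = 0.05 but none
exactly the value printed in the source report's text. No variant is
therefore asserted against a printed p-value; the significance *claims*
(which comparisons fall below 0.05) are asserted instead, and they hold
under every variant.

The normality screen is a one-sample Kolmogorov–Smirnov test against a
normal with the sample's own mean and standard deviation, using the
asymptotic p-value. With estimated parameters this is the Lilliefors
situation and the p-value is anti-conservative (biased toward declaring
normality); it is labelled as such in the report and used only as the
conventional screening step, never as a gate.

## The bundled study and its one discrepancy

The packaged dataset is count-level: per-sample E, D and I for both
conditions, and the post-wash locus score matrix (26 STR loci × 12
samples, female Y-STR cells absent). Full genotypes and peak heights were
never published, so the comparison engine cannot be re-run on the real
samples; it is exercised on simulated profiles instead, and the two
packaged tables are cross-validated against each other: for every sample,
the score-implied bounds `n0.5 + n1 ≤ D ≤ n0.5 + 2 n1` hold.

One published value does not follow from the published counts: the male
pre-wash median. The six male pre-wash percentages derived from the count
table have median 89.33 (truncated; 89.34 rounded) under any standard
median convention, while the accompanying text reports 84.34. The
reproduction report derives 89.33 and flags the comparison `MISMATCH`
deterministically — reproducing the discrepancy honestly rather than
matching the printed value. The related textual claim "11/12 post-wash
samples under nine alleles" is likewise consistent with the counts only if
read as "nine or fewer"; it is recomputed as the unambiguous statements
(4 samples at zero, 5 under five, one each at 6, 9 and 15).

## The simulator

The generator emulates the study design, not the chemistry. Reference
genotypes are drawn per locus from an allele-frequency model — by default
uniform over 8 synthetic alleles per locus, since no population table is
required for calibration work; real frequency tables can be supplied. Two
draws per autosomal locus (collapsing to a homozygote when identical, so
with 8 equifrequent alleles the mean expected count is
23 (2 − 1/8) = 43.125), one Y draw for males, amelogenin X,X or X,Y.

Evidence generation retains each reference allele independently with
probability `min(1, p_detect × shedder multiplier)`; heterozygote allele
detections are independent (no height-correlated dropout — a documented
simplification). Sporadic drop-in is Poisson with mean `dropin_rate`,
placed at uniform autosomal loci with alleles redrawn on collision with
the reference; a second full contributor is *not* modelled as drop-in but
via `make_mixture`, which unions contributor alleles and makes expected
peak height proportional to the summed mixing ratios of the carriers.
Retained peaks get lognormal heights with mean `height_mean` (1000 RFU)
and coefficient of variation `height_cv` (0.2, a typical
capillary-electrophoresis replicate CV; 0 switches noise off for exact
limit tests).

Scenario defaults fix the two conditions: pre-wash `p_detect = 0.8` with
`dropin_rate = 2` (the typical unwashed subject recovers about 80% of
alleles and shows a couple of foreign alleles), post-wash
`p_detect = 0.04` with no drop-in — a near-total collapse. The post-wash
value is a scenario parameter chosen to emulate the washed condition, not
an estimate of any published quantity. Shedder multipliers default to
1.15 / 1 / 0.6 (high / intermediate / low), clamped so the effective
probability never exceeds 1; subjects are assigned classes uniformly at
random unless specified. All randomness flows through R's global RNG,
seeded once per study, so an identical seed reproduces the entire study.

What passing simulation tests shows — and does not. The simulator
reproduces the *structure* of the study (condition separation, drop-in
rates, mixture height ratios) and calibrates the pipeline
(parameter-recovery within 0.05 at 100 subjects; mean recovery within 2
points of `100 p_detect`; 10:1 mixtures yielding the major genotype in
nearly all seeds). It does not emulate stutter, degradation, inhibition,
quantitation error or time-since-washing dynamics, so passing tests
validate the counting and interpretation arithmetic, not any claim about
real-world washing efficacy.

## Numerical and testing choices

Problem sizes in the test suite are chosen to bind the stochastic
assertions tightly while keeping a full run around three minutes: 1 000
random small profiles against a brute-force (locus, allele)-enumeration
oracle; 2 000 reference draws for the mean expected count (tolerance
±0.2); 500 replicate swabs for mean recovery (±2 points); 20 seeds × 100
subjects for parameter recovery (±0.05); 100 seeded mixtures for
major-contributor recovery (≥95). Degenerate inputs error early and
explicitly: empty references, zero-variance normality input, E = 0
records, malformed genotype rows (reported with their line number).

## Limitations

Count-level fixtures mean the real study's comparison stage cannot be
re-executed, only its downstream statistics. The mixture machinery targets
two-person mixtures; no deconvolution of three or more contributors, no
probabilistic genotyping, and no likelihood-ratio framework is attempted —
the 3:1 rule is a deterministic screen, not a weight-of-evidence
statement.
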