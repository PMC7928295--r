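---
title: "Trivalent segregation and the interchromosomal effect: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trivalent segregation and the interchromosomal effect: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robseg)
```

## The biological model

A Robertsonian translocation fuses the long arms of two acrocentric
chromosomes (13, 14, 15, 21, 22) into a single derivative. The carrier is
balanced, but at meiosis I the derivative and its two normal homologues pair
as a *trivalent*, which can resolve three ways:

* **alternate** — both normal chromosomes to one pole, the derivative to the
  other: gametes are normal or balanced;
* **adjacent** — the derivative plus one normal chromosome together: gametes
  disomic or nullisomic for one translocation chromosome;
* **3:0** — all three elements to one pole: doubly disomic or doubly
  nullisomic gametes.

Counting both poles this enumerates exactly eight gamete karyotypes
(2 alternate, 4 adjacent, 2 three-to-zero), which `gamete_products()`
materialises as signed dosage deviations `(d_a, d_b)` of the two
translocation chromosomes. After fertilisation by a euploid gamete the same
deviations appear in the embryo, so a trophectoderm copy-number profile
identifies the segregation product directly: `classify_segregation()` maps
`(0,0)` to alternate, a single ±1 to adjacent, and double deviations to the
3:0 bucket.

Two identifiability limits shape the data model. Normal and balanced embryos
have identical copy-number profiles, so alternate products are reported as a
single `normal_or_balanced` class. And a deviation pattern such as `(+1,−1)`
is not among the eight meiotic products; rather than discard such embryos we
bin them with 3:0 in a `three_to_zero_other` category, which keeps the
three-way partition exhaustive over classifiable embryos and matches how
segregation tables are conventionally printed.

The *interchromosomal effect* (ICE) hypothesis is that the trivalent
disturbs disjunction of the chromosomes **not** involved in the
translocation. `classify_ice()` therefore categorises each embryo from its
non-translocation chromosomes only (for controls, from all chromosomes):
`aneuploid` if any constitutional whole-chromosome or segmental imbalance is
present, otherwise `mosaic` if any mosaic call exceeds the calling
threshold, otherwise `normal`. The carrier-vs-control contrast is a set of
stratified 2×2 comparisons (`ice_contingency()`).

## The karyotype dialect

Embryo profiles travel as compact strings:
`"<modal>,<sex>[,+N|-N|mos±N(f)|seg±N ...]"`, e.g. `47,XX,+13` or
`46,XY,mos+16(0.35)`. Deliberate properties:

* the modal count must equal 46 plus the summed constitutional deviations —
  the parser rejects inconsistent strings rather than silently trusting one
  field over the other;
* mosaic fractions are decimals with exactly two digits, avoiding percent
  signs and locale issues; the writer always prints two decimals, making
  `parse()`/`format()` a strict round-trip;
* segment coordinates are out of scope: a `seg±N` flag records that an
  imbalance is partial, which is all the downstream rules need.

## Classification rules and their edge cases

**Unclassifiable embryos.** A mosaic-only or segmental-only imbalance of a
translocation chromosome is compatible with a mitotic, post-zygotic origin,
so no meiotic segregation call is made; such embryos are flagged
`unclassifiable` and excluded from segregation denominators (they are still
listed in tables). This is a conservative choice the source data cannot
adjudicate.

**Independence of the two analyses.** An embryo with, say, trisomy 16 on top
of an adjacent product still receives its segregation call from the
translocation chromosomes alone; the trisomy is the ICE module's business.

**ICE precedence.** Categories must partition each cohort (the table rows
are mutually exclusive and sum to the totals), so an embryo with both a
constitutional aneuploidy and a supra-threshold mosaic call is counted once,
as `aneuploid`. Segmental imbalances count toward `aneuploid`; keeping them
out entirely would silently shrink an observable abnormality class.

**Mosaic threshold.** "Exceeding 20% of aneuploid cells" is implemented as
strictly greater than 0.20, applied at classification time (the parser keeps
sub-threshold calls so the threshold can be varied afterwards). Raising the
threshold can only shrink the mosaic category — a monotonicity property the
test suite checks.

**Age bands.** Carrier age is dichotomised at 35 completed years
(`<35` / `>=35`), the conventional advanced-maternal-age boundary.

## Contingency statistics

All comparisons are 2×2: category vs rest, group 1 vs group 2.

* **Odds ratio**: the cross-product `(a·d)/(b·c)`. With any zero cell the
  Haldane–Anscombe correction (+0.5 everywhere) is applied and flagged. The
  95% CI is the Woolf logit interval — an extension beyond the source
  tables, which print no intervals.
* **Test selection** follows Cochran's rule: Fisher's exact test when any
  expected count is below 5 or the total below 40, otherwise the uncorrected
  Pearson χ². The rule is deterministic and the choice is recorded in every
  result. Yates' correction is available behind a flag but off by default.
* **Fisher's exact test** uses the two-sided point-probability definition
  (sum of all fixed-margin tables no more probable than the observed one),
  the dominant convention in general statistical software. The tests verify
  it against a from-first-principles enumeration oracle and against
  `stats::fisher.test()`.

Two printed-value caveats, documented rather than reproduced: the published
gender comparison prints OR = 2.95 (alternate) and 0.33 (adjacent), but the
cross-product ORs from the printed counts are ≈2.75 and ≈0.37 — the
estimator behind those two numbers is not stated, so they are not targets.
Likewise the overall "normal" ICE row prints OR = 0.76 while its own counts
(671/306 vs 584/201) give 0.7547, i.e. 0.75 at two decimals; the package
reports the count-derived value. All other headline ORs (1.74, 0.63, 1.30,
1.35, 1.40) reproduce exactly at two decimals. One further inconsistency:
the young-carrier ICE rows imply 835 embryos while the segregation table
prints 836; we use each table's own denominator when reproducing it.

## The cohort simulator

`simulate_cohort()` generates the kind of two-arm cohort the analysis
assumes, with per-embryo ground-truth labels so every classifier can be
tested against what actually happened. Defaults encode the study
conditions: 217 carrier patients (99 male) with 977 embryos, 134 control
patients with 785 embryos; gender-specific mode probabilities
(0.8245/0.1712/0.0042 male, 0.6310/0.3611/0.0079 female, rows renormalised);
a translocation mix of 55.3% rob(13;14), 10.6% rob(14;21) and the remaining
34.1% uniform over the other eight pairs; per-embryo aneuploidy targets of
24.77% (carriers, non-translocation chromosomes) and 20.25% (controls);
mosaic-category targets of 6.55% and 5.35%. Ages are drawn normal(30.6,
4.1), rounded and clamped to 20–45, which puts about 86% of embryos in the
young band, consistent with the reported stratum sizes.

Mechanics worth knowing:

* Background constitutional errors are i.i.d. per eligible chromosome with
  rate `λ = 1 − (1 − target)^(1/K)`; `K` is 20 autosomes for carriers (the
  translocation pair is never hit, so segregation truth stays well defined)
  and 22 autosomes plus the constitutional sex chromosomes for controls
  (23–24 depending on embryo sex; λ uses the 23.5 average). The closed form
  `1 − (1 − λ)^K` is checked against simulation in the tests.
* Mosaic events are single-chromosome; the aneuploid-cell fraction is
  uniform on (0.2, 0.8) — so essentially all simulated mosaics are callable
  at the default threshold — and is rounded to the two decimals the
  karyotype dialect carries, so truth labels and re-parsed strings agree
  exactly at the threshold boundary. The per-embryo event rate is
  `target_mosaic / (1 − target_aneuploidy)`, compensating for the aneuploid-
  precedence rule.
* Within a mode, the 2/4/2 products are sampled uniformly; no within-mode
  product frequencies are published at the blastocyst stage, so uniformity
  is an explicit assumption (configurable only by post-processing).
* One root seed drives everything through R's global RNG in a fixed stream
  order (carrier patients, carrier embryos in id order, then controls), so a
  given `sim_config()` reproduces its cohort byte for byte.

What the simulator does *not* emulate: recombination within the trivalent,
meiotic drive, attrition between cleavage and blastocyst, maternal-age
effects on background aneuploidy (rates are age-independent), multi-
chromosome mosaicism, and any correlation between embryos of one patient
beyond shared covariates. Passing recovery tests therefore demonstrates
internal consistency of classifier and generator under the configured
rates — not that real cohorts satisfy those rates.

## Numerical and testing choices

Percentages print with two decimals in tables and one decimal in prose-style
summaries; odds ratios round to two decimals only for display — tests and
reports compute on unrounded values. Fisher ties are compared with a 1e−7
relative tolerance, matching common practice. Test problem sizes were chosen
for tight-but-fast checks: 3σ binomial envelopes at cohort sizes of a few
hundred to 2,000 embryos, a 2,000-replicate null calibration of the χ² test
at 200 per arm, and Fisher-vs-enumeration agreement exhaustively for all
fixed-margin tables with total ≤ 40 plus 2,000 random tables with totals up
to 60.

## Limitations

Parental origin and meiosis I/II stage of an imbalance are not inferable
from embryo copy number; normal vs balanced-carrier status requires
haplotype information and is out of scope; p-values from other software may
differ where a different test variant (e.g. continuity correction) was the
default, which is why only count-derived odds ratios are treated as exact
reference points.
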