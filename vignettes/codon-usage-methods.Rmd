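---
title: "Methods: codon usage bias indices and their calibration in cubkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias indices and their calibration in cubkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cubkit implements the index battery used to dissect codon usage bias (CUB)
in viral coding sequences — composition, RSCU, ENC, dinucleotide odds
ratios, CAI/RCDI, PR2, neutrality regression, correspondence analysis,
GRAVY/AROMA — together with a seeded generator that provides ground truth
for every one of them. This vignette records the models, the conventions
chosen where several coexist in the field, and what the tests do and do
not establish.

## Substrate and validation

All indices operate on one common substrate: the *retained codons* of a
record. A coding sequence is normalised to upper-case DNA (U→T), split
into triplets, and cleaned in three documented steps:

- a trailing partial codon is dropped with a warning (deposited CDS
  occasionally include partial termini); `strict = TRUE` turns this into
  an error;
- any codon containing a symbol outside {A, C, G, T} is skipped and
  counted, because every downstream formula assumes unambiguous codons;
- stop codons stay in the 64-codon count vector but are excluded from all
  sense-codon statistics, and internal stops are flagged.

The genetic code is fixed to the standard table: the viruses this package
was built around are +ssRNA viruses using standard translation, and
supporting alternative codes would complicate every family-based statistic
for no use case. Synonymous statistics use the 59-codon set (61 sense
codons minus AUG and UGG, which offer no synonymous choice). User-facing
tables render codons in RNA form.

## Composition conventions

Two third-position conventions coexist and give different numbers; cubkit
uses both, each where it is standard:

- **GC3s** is the G+C fraction over *all* synonymous third positions.
- **A3s/U3s/G3s/C3s** use *per-base denominators*: codons ending in X are
  divided by the synonymous codons of families that have at least one
  X-ending member. Under this convention the four values typically sum to
  more than 1, and GC3s ≠ G3s + C3s. A shared denominator would force the
  sum to exactly 1 and could not reproduce the reference tables this
  layout mirrors.

AU3 is reported as the complement of GC3s (percentage of synonymous third
positions that are A or U). GC12 is the arithmetic mean of GC1 and GC2,
maintained to 1e-12 by construction.

## RSCU and missingness

RSCU is the observed count relative to equal use within the family;
per-family sums equal the degeneracy (a property test enforces this to
1e-9 on random tables). An amino acid absent from a sequence yields
*missing* RSCU for its codons, not 0: a 0 would read as "never used" and
drag multi-sequence means down. This deliberately diverges from tools that
print 0; the divergence only matters for short sequences, since a
~2,800-codon polyprotein essentially always uses all 18 families.
Classification thresholds (>1.6 over-represented, <0.6 under-represented,
1 as the no-bias point) are applied as strict inequalities.

## ENC

Wright's estimator is used with families kept whole: 9 two-fold, 1
three-fold (Ile), 5 four-fold, 3 six-fold (Leu, Ser, Arg), which is what
the 9/1/5/3 class weights presuppose. Three repairs, all logged on the
result object:

- families with fewer than 2 observed codons, or with estimated
  homozygosity F ≤ 0 (possible at tiny counts), are excluded from their
  class mean rather than clamped;
- a missing three-fold class (no Ile) is imputed as (F̄₂ + F̄₄)/2;
- sampling noise can push ENC above the theoretical ceiling; it is capped
  at 61.

If a 2-, 4- or 6-fold class has no usable family the ENC is reported
missing rather than guessed. The null curve is the standard
2 + s + 29/(s² + (1 − s)²); its closed-form anchors (60.5 at s = 0.5, 31
at 0, 32 at 1) and the near-symmetry identity
ENC(s) = ENC(1 − s) + (2s − 1) are asserted in tests.

## Dinucleotides

ρ<sub>xy</sub> = ƒ<sub>xy</sub>/(ƒ<sub>x</sub>ƒ<sub>y</sub>) with
overlapping dinucleotides counted within each sequence only — never across
sequence junctions — and mononucleotide frequencies taken over the same
string (all L bases rather than L − 1; the difference is O(1/L)).
Multi-set summaries average per-sequence profiles within each virus first
and then average the virus means, so a 96-sequence set cannot swamp an
8-sequence set in the grand mean. Whether to average per-sequence values
or concatenate per virus was genuinely open; per-sequence averaging was
chosen because it weights sequences equally and keeps the per-virus
summaries comparable across sets of very different sizes.

## CAI and RCDI

Both indices need only within-family relative frequencies, so host
references may arrive as counts, Kazusa-style per-thousand tables, or RSCU
columns — all are reduced to the same form. Zero-valued reference codons
receive a pseudocount of 0.5 before normalisation (keeps log-weights and
ratios finite); the value is recorded on the reference object. CAI is the
geometric mean of weights over sense codons, with AUG/UGG carrying weight
1 — they contribute nothing to the numerator but keep L equal to the
sense-codon count. RCDI's lower bound of 1 is a per-family
Cauchy–Schwarz consequence and is enforced as an invariant test in exact
arithmetic (tolerance 1e-9) on random query/host pairs.

The packaged host reference values (four honeybee-virus host species, as
RSCU) are published reference columns shipped as a plain-text fixture;
live codon-usage-database tables are user-supplied files, so no test ever
touches the network.

## PR2, neutrality, COA

PR2 tallies third bases over all synonymous codons, consistent with the
composition module; the classical fourfold-degenerate-only variant is
available via a flag. The neutrality fit is ordinary least squares of
GC12 on GC3s via `stats::lm`, reported with the slope's two-sided p-value
and 95% interval; mutation/selection shares are slope·100 and
(1 − slope)·100 and always sum to 100. A constant response is reported as
slope 0 with R² = 0.

Correspondence analysis follows the chi-square-metric SVD of standardised
residuals, on RSCU values (not raw counts). Missing RSCU entries are
imputed at the neutral value 1 before decomposition so that family absence
does not manufacture inertia; the imputation count is reported. Axis
inertia fractions are σ²-proportional, non-increasing, and sum to 100% of
the nonzero total; an all-identical-rows matrix is flagged degenerate
rather than divided by zero. Tests cross-check the fractions against an
independent eigendecomposition and against vegan's CA.

GRAVY uses the Kyte–Doolittle scale, whose mean is bounded by ±4.5 (claims
of a ±2 range for this index circulate but do not follow from the scale);
AROMA is the Phe+Tyr+Trp fraction. Correlation matrices are Pearson r with
two-sided p per pair on pairwise-complete cases, pooled across all sets by
default (per-virus behind a flag), with non-significant entries rendered
blank in the table output.

## The generator and what the tests show

The generator draws an amino acid from a composition vector (uniform by
default) and then a codon from its family's probability vector, which can
be (a) explicit, (b) a Wright-null dial θ placing mass θ on G/C-ending
synonyms split evenly — giving sequences whose ENC must track the null
curve, (c) copied from a host reference — giving RCDI → 1 and CAI equal to
its analytic expectation exp(Σ p log w), or (d) uniform. A CpG multiplier
reweights codons containing CG *within* families; cross-boundary CpG is
emergent and not controlled, so the realised ρ(CG) is milder than the
multiplier. Tests therefore compare recovered dinucleotide profiles
against an analytic expectation computed from the planted codon
distribution (exact for i.i.d. codon draws), not against the raw
multiplier. R's Mersenne-Twister generator under a fixed integer seed
makes output bit-reproducible.

Four presets mirror the shape of the honeybee-virus study (43/57/8/96
sequences, ~2,800 codons, GC3s dials 0.23/0.54/0.31/0.31, CpG multiplier
0.5). Test and example runs use scaled-down versions (typically 3–50
sequences of 300–3,000 codons), sizes at which every stated tolerance is
already meaningful while the whole suite runs in about a minute.

What passing tests show: the formulas are implemented correctly, the
conventions are self-consistent, and planted parameters are recovered at
Monte-Carlo accuracy. What they do not show: real viral CDS have
phylogenetic correlation, site-wise selection heterogeneity, and
dinucleotide structure that no i.i.d. codon model produces; results on
real data inherit none of the generator's guarantees beyond formula
correctness.

## Known limitations

- No alternative genetic codes, ORF finding, or alignment; inputs must
  already be CDS.
- ENC-prime (background-corrected) and codon-pair/tRNA-adaptation indices
  are out of scope.
- CAI/RCDI values depend on the vintage of the host usage table; two
  analyses are comparable only if they share the reference.
- The concordance count in host comparison uses the documented
  same-side-of-1 rule; other "similar selection" criteria exist and give
  different counts.
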