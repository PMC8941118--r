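---
title: "Cumulative skew scanning and the four-parameter replichore model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative skew scanning and the four-parameter replichore model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skewfit)
```

## The science in brief

Most bacterial chromosomes are circular and are replicated bidirectionally
from a single origin. The two replication arms (replichores) are copied by
different machinery — one strand continuously (leading), the other in
fragments (lagging) — and this asymmetry leaves a compositional fingerprint:
a small but persistent excess of G over C (and usually T over A) on the
leading strand. Within a strand, G≈C and T≈A overall (Chargaff's second
parity rule), so this *GC skew* is a localized deviation from parity, worth
roughly 2–5% of bases in well-skewed genomes.

Windowed skew, `(G−C)/(G+C)` per window of `N` bases, is sensitive to the
choice of `N`. This package therefore works exclusively with *cumulative*
skew: a running `G−C` total along the chromosome. For `GGGCCC` the running
total is 1, 2, 3, 2, 1, 0 — a rise and a fall — while the windowed skew at
`N = 6` is 0. On a whole chromosome the cumulative curve is, to a good
approximation, two straight line segments: rising at rate `alpha1` across
the leading arc, falling at rate `alpha2` across the lagging arc. The
inflection points locate the origin and terminus of replication.

## The model

A cumulative skew track is modeled by four parameters:

* `alpha1` — per-nucleotide skew slope on the leading strand. `alpha1 =
  0.046` means 46 excess G per 1000 leading-strand nucleotides.
* `alpha2` — slope magnitude on the lagging strand (modeled slope `−alpha2`).
* `div` — fraction of the chromosome on the leading strand. `div = 0.557`
  means the leading arc covers 55.7% of the chromosome.
* `shift` — circular offset of the origin relative to the start of the
  sequence file, as a fraction of length. This is an assembly artifact, not
  biology.

The predicted value at position `p` is `alpha1·A(p) − alpha2·(p − A(p))`,
where `A(p)` counts leading-arc nucleotides in `[0, p)`; the leading arc is
`[shift·L, (shift+div)·L)` on the circle. Two conventions the model fixes:

* **Anchoring.** The curve is forced through 0 at position 0, matching a
  cumulative counter that starts at zero. This removes a free intercept.
* **No circular closure.** We do not require `alpha1·div = alpha2·(1−div)`.
  The final cumulative value equals the chromosome's total base excess,
  which is genuinely nonzero in real genomes; forcing closure would bias the
  slopes.

The goodness-of-fit `rms` is the root-mean-squared fit error divided by the
absolute mean of the observed values, so strongly skewed chromosomes are not
penalized for their scale. `rms` is scale-free: multiplying a track by a
constant changes the fitted slopes proportionally and leaves `rms` alone.
When the observed mean is numerically zero the ratio is undefined and the
package returns `Inf` as a sentinel (a flat constrained track, e.g. a
codon-position skew of a gene-free toy). We interpret "absolute mean skew"
as `|mean(values)|`; the alternative reading `mean(|values|)` would only
rescale the statistic.

## Fitting strategy

Fitting minimizes RMSE over `(alpha1, alpha2, div, shift)` with Nelder–Mead
downhill simplex. The shift axis is strongly multi-modal (the objective is
periodic in it), so ten deterministic starts are used: the first seeds the
slopes with the average observed skew (`|final|/L`), `div = 0.5`,
`shift = 0`; the other nine keep those seeds and place `shift` on the grid
0.1 … 0.9. Each start runs to a relative function tolerance of 1e-10 or
2000 iterations; the best result (ties broken by smaller shift) is polished
by restarting the simplex at its own optimum twice, which reliably tightens
the last digits. The winner is then *canonicalized*: if `alpha1 < 0` the
optimizer described the mirrored curve (a chromosome sequenced in the
non-canonical direction), so the arcs are relabeled — slopes swapped and
negated, `div → 1−div`, `shift → (shift+div) mod 1` — leaving the curve
identical but the rising-GC arc reported as leading.

GC skew is the most strongly defined skew, so its fitted `div` and `shift`
are frozen and shared by all ten other tracks (TA, six codon-position skews,
two non-coding skews, gene strand bias). With the arc geometry fixed the
model is *linear* in the two slopes, so the constrained fits use exact least
squares — the closed-form minimizer of the same objective a 2-D simplex
would approximate, and bit-reproducible. Constrained slopes may legitimately
be negative: Firmicutes, for instance, show TA skew discordant with GC.

Fitting operates on checkpoint values (default every 4096 nt plus the
sequence end), not raw bases: that resolution is ample for slopes and
breakpoints, and makes fitting cost independent of genome size.

## The scanner

One pass over the reference strand maintains all counters simultaneously:
total GC and TA skew; the same skews split by codon position 0/1/2 inside
protein-coding genes plus a non-coding bucket (the four buckets sum to the
total at every checkpoint, by construction); a strand-bias counter (+1 for
each nucleotide of a positive-sense gene, −1 for negative-sense, 0
elsewhere); a non-genic counter; and plain A/C/G/T counts. IUPAC ambiguity
codes advance the position but touch no counter.

Decisions where the field's conventions leave room:

* "Protein-coding gene" means GFF3 `CDS` rows — the unambiguous carrier of
  codon phase. `gene` rows flagged `protein_coding` are accepted only when a
  file has no `CDS` at all, so minimal annotations work without
  double-counting in full ones.
* Codon phase on minus-strand genes is counted from the gene's own 5′ end;
  the *letters* counted are always those of the reference strand as
  traversed. Only the position classification is gene-aware.
* A nucleotide covered by several genes is codon-classified by the first
  gene in coordinate order (preserving the partition property), while the
  strand-bias counter sums all covering genes' contributions (+1−1 = 0 for
  an antisense pair).
* A CDS whose length is not a multiple of 3 is excluded from codon-position
  accounting (warned), but still counts as genic elsewhere.
* The published checkpoint table names five per-base counter slots and four
  codon-position skew columns; the accompanying text describes three codon
  positions plus a non-coding remainder. We emit `gcskew0..2` + `gcskewNG`
  (likewise TA) and single `acount..tcount` totals rather than invent
  semantics for the extra slots.

## The synthetic generator

`simulate_genome()` is the package's oracle: it plants known `(gc_alpha1,
gc_alpha2, ta_alpha1, ta_alpha2, div, shift)` and emits FASTA + GFF3 that the
whole pipeline can be run on, so every green test traces back to parameters
chosen before the sequence existed.

Per position the base probabilities are `P(G) = ¼ + r_gc/2`,
`P(C) = ¼ − r_gc/2`, `P(T) = ¼ + r_ta/2`, `P(A) = ¼ − r_ta/2`, with the
signed rates `r_*` switching at the two arc breakpoints. Deterministic mode
does not sample: each base runs a floor (Bresenham-style) schedule of its
probability, and the fired events, in scheduled order, are the sequence.
Wherever `n·P(b)` is integral for all four bases the realized counts are
exact — at rate 0.046 the first 1000 leading-strand nucleotides contain
exactly 46 excess G, which is what makes the worked-example tests exact
rather than approximate. Binomial mode replaces the schedules with seeded
multinomial draws, giving realistic counting noise (cumulative tracks become
random walks around the model curve, increment variance ≈ 0.5 per
nucleotide).

Genes are non-overlapping CDS intervals (lengths multiples of 3, mean
~900 nt, exponential gaps matched to the requested density), placed away
from the two arc breakpoints so ground truth stays exactly computable, with
strand drawn from the leading-strand preference; the gene nearest the
planted origin is named `dnaA`. Only the start codon (ATG) and stop codon
(TAA) are stamped into the sequence. In deterministic mode the stamping
damage (~±1 count per gene) is repaired by flipping a matching number of
bases elsewhere in the same arc, so planted per-arc excess totals remain
exact; leftover error is at most one count per arc. When
`codon_g_fraction ≠ 0.5`, gene-body G/C identities are re-drawn on the sense
strand instead — this deliberately plants gene-driven (codon-bias × strand-
bias) skew and is *not* repaired, since the perturbation is the point.

Defaults describe the stated world of the package's tests: a 2^20-nt
chromosome, `gc_alpha = 0.046` (the printed-rate example), concordant
`ta_alpha = 0.025` (typical skews are ~2.5%), `div = 0.557`, 85% coding
density and a 0.7 leading-strand gene preference — values a microbial
genomicist would call unremarkable.

What the generator does **not** emulate: realistic codon usage (only the G/C
balance is controllable), horizontal transfer, inversions, multi-origin
replication, sequencing artifacts, or plasmid-specific replication modes. A
green test therefore establishes that the scanner and fitter do what they
claim on genomes that obey the model — not that the model describes every
real chromosome (the `rms` quality statistic exists precisely to flag the
ones it does not).

## Numerical choices and edge cases

* Windowed skew of a `G+C = 0` window is defined as 0, keeping the function
  total; windowed skew is illustrative only.
* Checkpoints fall at `interval, 2·interval, …` plus the sequence end, so
  final values satisfy exact conservation (`gcskew = gcount − ccount`).
* All-zero tracks are a degenerate input for the four-parameter fit
  (goodness undefined) and raise an error; constrained fits return zero
  slopes with an `Inf` sentinel instead, since they occur routinely
  (gene-free toys).
* `div` is kept in `(1e-4, 1−1e-4)` by penalty during optimization; ties
  among equally good starts resolve to the smallest shift; everything is
  deterministic end to end, so pipeline outputs are byte-identical across
  runs.
* CSV floats are written with 6 significant digits (stable diffs, exact
  round trips of the written precision); integers unpadded.

## Known limitations

* The noisy parameter-recovery property at the extreme low end
  (`alpha = 0.005` on a 4 Mb chromosome) runs into the information bound:
  binomial sampling alone puts the slope-estimate standard deviation near
  13% of the true value there, so no fitter can guarantee 10% relative
  error; the corresponding test documents rather than hides this.
* The origin position is estimated only via `shift` at checkpoint
  resolution; no attempt is made to pin down the origin exactly (no OriC /
  DnaA-box motif search).
* Multi-origin or rearranged chromosomes are flagged by a high `rms`, not
  modeled.
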