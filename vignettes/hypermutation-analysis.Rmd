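---
title: "Profiling APOBEC3 G>A hypermutation in proviruses"
author: "hypermutR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling APOBEC3 G>A hypermutation in proviruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypermutR)
```

## The model

APOBEC3 enzymes deaminate cytidine to uracil on single-stranded retroviral
minus-strand DNA during reverse transcription. After plus-strand synthesis
the lesion reads as a plus-strand G→A substitution. Three observable
signatures follow, and the package is organized around them:

1. **Strand bias**: an excess of G>A over C>T (the minus-strand-edited vs
   plus-strand-edited classes) and over A>G (the RNA-editing class).
2. **Context preference**: the deaminated C is chosen partly by its −1/−2
   minus-strand neighbors. The two laboratory-mouse deaminase alleles favor
   T(T/C)C (B6-type) and XTC (BALB-type) respectively.
3. **C-tract runs**: consecutive minus-strand cytosines are edited in
   cascades, because each fresh C→T edit can convert its 3'-minus neighbor's
   context (e.g. CCC stepwise into TCC, CTC or TTC) into a preferred target.
   This yields runs of adjacent plus-strand G>A mutations.

All coordinates in the package are 1-based, inclusive, on the ungapped
reference plus strand. For a plus-strand G at position $i$, the minus-strand
context is the reverse complement of the plus triplet $(i, i+1, i+2)$,
displayed 5'→3' on the minus strand as (−2, −1, C).

## Mismatch profiling

`classifyMismatches()` emits one record per alignment column where both
characters are proper bases and differ; gap and N columns contribute
nothing, and indels are tallied separately but never counted as mismatches —
the analysis counts substitutions. `summarizeProfile()` derives

$$\%\,\mathrm{G>A} = 100\cdot\frac{n_{G>A}}{n_{\text{total}}},\qquad
\mathrm{G>A\ per\ kb} = 1000\cdot\frac{n_{G>A}}{L_{\text{ref}}}$$

at full precision; presentation rounding (half away from zero, 1 or 2
decimals) lives exclusively in the reporting layer, because that is the
rounding that reproduces every internally consistent cell of the published
summary tables the fixtures transcribe. Cells of those tables that disagree
with their own printed counts are annotated `known_inconsistent` in the
fixture files and surfaced by `checkAgainstExpected()` rather than silently
absorbed or asserted.

Runs of G>A are defined on adjacent reference coordinates — a literal
minus-strand C tract — so an alignment gap between two G>A records breaks a
run. A maximal run of length $k \ge 2$ counts once under key $k$; lengths
above 5 keep their own key.

## Alignment

`alignPairwise()` is a desk-scale stand-in for external multiple aligners:
global Needleman–Wunsch with affine gaps (a gap of length $L$ costs
$\mathrm{open} + L\cdot\mathrm{extend}$), computed by
`Biostrings::pairwiseAlignment()`. Default scores (match 2, mismatch −3,
open 8, extend 2) are deliberately gap-averse so isolated substitutions are
not absorbed into indels. The exact column-level alignments produced by
external tools on the published sequences are not reproducible without their
parameters; for that reason pre-computed aligned FASTA is a first-class
input via `ingestAlignedFasta()`, which projects every non-reference record
onto the shared reference coordinate frame (columns gapped in both members
of a pair are dropped for that pair). The test suite checks alignment
scores against an independent brute-force affine DP oracle; tie-breaking
among co-optimal alignments follows the library's deterministic traceback.

## Target-site context analysis

`extractContexts()` supports two context sources. `"reference"` encodes the
classical assumption that every edit saw the unmutated template;
`"contemporaneous"` reads the −1/−2 neighbors from the query, modeling
neighbors that had already been edited when the site was deaminated (the
third character stays C, the base the site itself carried before editing).
Sites within 2 nt of the reference 3' end, adjacent to gap columns, or with
N neighbors are dropped with a logged count; whether the published analyses
also dropped indel-adjacent sites is unstated, and dropping is the
conservative choice because such contexts are not well defined.

The "standalone" filter keeps sites whose −1/−2 neighbors carry no mismatch.
Its two readings — exclude on *any* neighbor mismatch versus only on
neighbor G>A — both appear in the source material; the stricter reading is
the default and the narrower one is available via `exclude = "GA"`.

`buildLogo()` computes per-position frequencies and information content
$2 - H$ bits with no small-sample correction, matching default sequence-logo
behavior at the site counts involved (hundreds).

`classifyPreference()` renders numerically what is classically a visual
logo call, so its score and thresholds are package constructions, validated
only on synthetic data:

$$s = \log_2\frac{f(T_{-2})}{b_T} \;-\; \log_2\,\max_{B\neq T}\frac{f(B_{-2})}{b_B}$$

computed over sites with T or C at −1 (the T(T/C)C candidate set), with
background $b$ defaulting to uniform (supply the reference minus-strand
composition for composition-corrected calls). Labels: `B6-like` when
$s > 0.5$; else `BALB-like` when the −2 column is near-uniform
(information < 0.3 bits) while $f(T_{-1}) > 0.5$; else `indeterminate`, and
always `indeterminate` below 20 sites. The 0.5 log2-unit dead zone, the
0.3-bit uniformity ceiling and the 20-site gate are configurable; parameter
recovery on simulations (20 seeds per regime, ~500 edits each) labels at
least 18/20 correctly in each regime at these defaults.

## Coding impact

Stop-gain scanning translates full query codons (read off the ungapped
query bases aligned to the reference codon positions), while the
nonsynonymous fraction evaluates each G>A record independently against the
reference codon — the first mirrors realized stops, the second per-site
substitution reporting. `gaStopConvertibleCodons()` proves by exhaustion
over all 64 codons and all subsets of their G positions that TGG is the
only non-stop codon from which G>A changes alone can reach a stop; the
observation that every deaminase-induced premature stop is a mutated
tryptophan codon is therefore a theorem, not a dataset coincidence. The
standard nuclear code is used throughout; selenocysteine recoding is out of
scope.

## LTR comparison

`compareLTRs()` aligns both LTRs of a provirus to a reference LTR and calls
a substitution *shared* only when both LTRs carry the same substituted base
at the same reference position — stricter than mere co-occurrence, and the
definition under which 3'-specific G>A counts are meaningful. Positions
where the two LTRs differ from the reference with different bases produce
two specific entries. Alignments below 0.5 length-normalized identity are
rejected as non-homologous. Single-base indels are reported separately. No
default mask is applied; hypervariable segments (where mismatches cannot be
reliably identified) must be supplied by the caller because their
coordinates are dataset-specific.

## The simulator: a stated world

`generateProvirus()` fixes the world the analyses assume: 8,000 bp total,
two identical 1,300 bp LTRs (the unusually large LTR class of the proviruses
that motivated this package), G+C fraction 0.42 (matching the ~21% G / ~27%
A composition of the unedited reference provirus), and one internal CDS
seeded with an ATG start and 20 TGG codons. These defaults were chosen once
from the stated properties of the modeled proviruses and are not tuned to
test outcomes.

`simulateEditing()` performs sequential scans of the minus-strand cytosines.
The default scan direction is minus-strand 3'→5' — ascending plus-strand
coordinates, the order in which reverse transcription exposes template —
which means a fresh edit can only influence its 3'-minus neighbor's context
on a *later* pass; the opposite direction allows within-pass cascades. The
direction only matters when `cascade = TRUE` and is configurable, since the
biology does not pin down an effective scan order. Per-site edit
probability is $\min(1, \text{baseRate}\cdot w(\text{context}))$; the
default weights TTC 8, TCC 4, CTC 4 (else 1) with baseRate 0.02 are
calibration-free choices that produce mismatch densities in the range of
heavily edited proviruses — no observation constrains absolute per-pass
rates, and `tuneEditRate()` exists to solve analytically for the rate that
reaches a target expected edit count from the template's site census. The
3'-LTR double exposure is modeled as whole-interval extra passes, the
simplest mechanism consistent with strand displacement; no attempt is made
to model PPT-anchored gradients, which the modeled proviruses do not show.
Background substitutions exclude G>A (so mismatch classes remain
attributable to their mechanism) unless explicitly lifted for stress tests.
A single seeded generator drives all draws in scan order, so the truth log
fully determines the output.

What a green test on this world establishes: that the analysis stack
recovers planted signal (truth positions, context preferences, cascade
clustering, LTR asymmetry) exactly or at stated statistical thresholds. What
it does not establish: recovery of the published per-provirus numbers, which
depend on real sequences; selection, repair, and recombination, which the
simulator deliberately omits; or the absolute editing rates of any enzyme.

## Haplotype calling

The engine is generic over any diagnostic-site table; the packaged table is
a synthetic placeholder (clearly labelled in its filename and header)
because the real diagnostic residues are published only as a figure.
Identical residue vectors share a haplotype id assigned in first-appearance
order, so the partition of samples into haplotypes is invariant under
reordering and batching even though ids may permute. Samples missing data at
any diagnostic site are excluded from the distinct-haplotype count but
reported with partial vectors; restricting the site table to a subset
yields compatibility classes for partially sequenced samples.

## Numerical choices and degenerate inputs

- Consensus ties break to the first record's character when it is among the
  tied winners, else alphabetically — deterministic and documented, since no
  consensus rule is stated for the published group consensus.
- IUPAC ambiguity codes other than N normalize to N with a warning rather
  than an error; N never enters mismatch counts or composition denominators.
- An empty mismatch set yields `NA` percent (rendered `-`), zero per-kb, and
  an empty run histogram; an empty region overlap is empty output, not an
  error.
- Percent composition on all-N input is an error (no denominator).
- `findRuns` treats duplicate positions (impossible from one alignment, but
  possible in hand-built input) as one.

## Known limitations

- The aligner is pairwise only; multiple-alignment optimization belongs to
  external tools whose output is ingested.
- The preference discriminant is a package construction; on real data it
  should be read alongside the logo, not instead of it.
- Significance testing of G>A excess (e.g. Fisher-style hypermutation
  tests) is deliberately out of scope; the profiles report raw excesses.
- Phylogenetics, selection analysis (dN/dS), genome mining and LTR-based
  age estimation are out of scope; the haplotype module only prepares
  alignments usable by such tools.
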