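# hypermutR

Detection and characterization of APOBEC3-style G>A hypermutation in
endogenous retroviruses.

## The problem

APOBEC3 cytidine deaminases are packaged into retroviral particles and
deaminate C→U on the viral *minus-strand* DNA during reverse transcription,
which surfaces as G→A substitutions on the plus strand. Germline-integrated
proviruses — such as the endogenous mouse mammary tumor virus (*Mtv*)
proviruses — preserve a fossil record of this editing. Reading that record
requires a chain of analyses:

- **Mismatch profiling** of a provirus against a reference: counts per
  substitution class, %G>A of all mismatches, G>A per 1,000 bp, query base
  composition (%G depressed, %A inflated by heavy editing), and runs of
  consecutive G>A mutations produced by editing of minus-strand C tracts.
- **Sliding-window gradients** (default 400-base windows, 100-base step) of
  G>A, A>G and C>T density across the genome.
- **Target-site context analysis**: each edited minus-strand C sits in a
  trinucleotide context written 5'→3' as (−2, −1, C). The murine deaminase
  alleles differ in preference — mA3^B6 favors T(T/C)C, mA3^BALB favors XTC
  (plus-strand G(G/A)A and GAX). The package extracts contexts under the
  reference or the *contemporaneous* (already-edited) neighborhood, builds
  position-frequency logos with information content `2 − H` bits, intersects
  shared sites across proviruses, applies the "standalone" filter (sites
  with unmutated −1/−2 neighbors), and scores the B6-vs-BALB preference with
  a log2-odds discriminant.
- **Coding impact**: premature stop gains (every G>A-only stop gain
  descends from a tryptophan TGG codon — a theorem of the genetic code the
  package proves by exhaustion), start-codon losses, and the nonsynonymous
  fraction of G>A changes.
- **5' vs 3' LTR comparison**: proviral LTRs are identical at integration;
  G>A substitutions unique to the 3' LTR diagnose editing of the nascent 3'
  LTR while it is transiently single-stranded late in reverse transcription.
- **Haplotype enumeration** of deaminase coding sequences at diagnostic
  residue sites.
- **A ground-truth simulator** of the whole process: a synthetic provirus
  with identical LTRs and a TGG-seeded CDS, minus-strand deamination with
  context-dependent rates, cascade target creation (editing CCC tracts into
  preferred TTC/CTC/TCC targets), extra 3'-LTR exposure, and background
  noise — with a full truth log for recovery tests.

## Worked example

```r
library(hypermutR)

template <- generateProvirus(seed = 11)          # 8 kb, two identical 1.3 kb LTRs
rate <- tuneEditRate(template, editConfig(), targetEdits = 500)
cfg <- editConfig(baseRate = rate, cascade = TRUE, passes = 2,
                  ltr3ExtraExposure = 2, seed = 11)
sim <- simulateEditing(template, cfg)

aln <- ingestAlignedFasta(
  c(template = templateSeq(template),
    edited   = as.character(sim$edited[[1]])),
  refId = "template")[["edited"]]

profile <- profileAlignment(aln)
profile
#> MismatchProfile over 8000 reference bases
#>   G>A: 802  C>T: 0  A>G: 0  total: 802
#>   %G>A/total: 100.0  G>A per kb: 100.3
#>   runs of G>A: 2x75, 3x17, 4x1, 5x1
```

Every mismatch is G>A (no background noise was configured), the per-kb rate
is in the range of the most heavily edited proviruses on record, and the
run histogram shows the C-tract clustering that cascade editing produces.

```r
recs <- classifyMismatches(aln)
sites <- extractContexts(recs[recs$klass == "G>A", ], aln)
classifyPreference(sites)
#> PreferenceCall: B6-like (score 0.516, n = 802)
```

The default simulator weights (TTC 8, TCC 4, CTC 4) encode a
T(T/C)C-leaning deaminase, and the preference call recovers it.

```r
l5 <- ltr5Range(template); l3 <- ltr3Range(template)
ed <- as.character(sim$edited[[1]])
compareLTRs(c(five  = substring(ed, l5[1], l5[2])),
            c(three = substring(ed, l3[1], l3[2])),
            c(ref   = substring(templateSeq(template), l5[1], l5[2])))
#> LTRComparison
#>   shared substitutions:      84
#>   5'-specific substitutions: 37
#>   3'-specific substitutions: 88 (G>A: 88)
#>   indel positions: 5' 0, 3' 0

ev <- scanStopGains(aln, cdsTable(template))
nrow(ev)                      # 21 premature stops
all(ev$refCodon == "TGG")     # TRUE: every G>A stop gain is a mutated Trp
```

The two extra 3'-LTR editing passes leave more than twice as many
3'-specific as 5'-specific G>A substitutions — the directional LTR
asymmetry the comparison is designed to detect.

A thin shell front-end wraps the same functions:

```sh
Rscript inst/scripts/hypermut.R pipeline --out outdir --seed 11
Rscript inst/scripts/hypermut.R profile --aln pair.fa --ref-id template --out profile.json
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it generates a provirus and simulates editing under `--seed`, profiles the
edited provirus against its template, extracts target-site contexts and a
preference call, and re-verifies the shipped expected summary tables from
their raw counts. Run it from the repository root against the installed
package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
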