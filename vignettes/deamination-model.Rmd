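---
title: "Modelling strand-specific deamination of LINE-1 TPRT intermediates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling strand-specific deamination of LINE-1 TPRT intermediates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l1deam)
```

## The biology being modelled

LINE-1 (L1) retrotransposons integrate by target-site primed reverse
transcription (TPRT): the element endonuclease nicks genomic DNA, the freed
3' end primes reverse transcription of the L1 mRNA, and second-strand
synthesis completes the insertion, normally leaving short target-site
duplications (TSDs) on both sides. Several single-strand DNA species are
transiently exposed during this process: the nascent minus-strand cDNA
(once the RNA of the mRNA/cDNA heteroduplex is degraded by RNase H), the 5'
flank's top strand, and the 3' flank's bottom strand.

APOBEC3A (A3A) is a cytidine deaminase that converts C to U in single-strand
DNA, preferring the 5'-TCA-3' trinucleotide. A C-to-U event on the
minus-strand cDNA is fixed by second-strand synthesis and surfaces as a G-to-A
change on the element's plus (coding) strand — the strand-specific signature
this package simulates, detects and tabulates. Uracils are normally removed
by uracil DNA glycosylase (UNG) and the abasic site processed further, which
can either restore the C or destroy the integration intermediate; expressing
the phage uracil glycosylase inhibitor (UGI) blocks UNG, so the edits persist
and become observable.

The in vitro counterpart is the LEAP assay: L1 ribonucleoprotein particles
extend a 3' RACE adapter primer (the packaged `adapter_5np1` oligo, which
contains a single cytidine in a TCA context) from the mRNA poly(A) tail, and
the cDNAs are amplified and sequenced. The adapter is single-stranded for the
whole reaction; the rest of the cDNA only becomes single-stranded when
RNase H is added. That geometry gives the assay its crucial internal control:
deamination concentrated on the adapter with intact heteroduplexes, spreading
into the cDNA body only with RNase H.

## The generative model

`simulate_leap_products()` draws, per product, a poly(A) tail length and
assembles the minus-strand cDNA as `adapter + oligo(dT) + revcomp(element)`.
An `exposure_model()` decides which intervals are single-stranded (adapter
only, or everything under RNase H). Every exposed C with a complete
trinucleotide context is edited independently with probability
`p_by_context[context]`, contexts always read 5'-3' on the chemically
deaminated strand. Terminal C's have no complete context and are never
edited, matching a 16-row NCN accounting with no 2-mer rows. Edits are
written directly as T (the post-second-strand-synthesis view; all observed
data are sequenced DNA, so no separate U alphabet is carried).

`simulate_insertions()` additionally draws a TSD length, a 5' truncation
(retained length geometric from the 3' end, reflecting the 3'-anchored nature
of TPRT), an optional twin-priming inversion/deletion, and routes every
uracil through a `repair_model()`: restored with probability `p_restore`,
intermediate destroyed with `p_abort` (the insertion is never recovered), or
retained. UGI forces retention. Flank exposure flags plant C>T edits in the
5' TSD copy (top strand) and G>A edits in the 3' TSD copy (bottom strand) —
the two strand-attribution rules used to explain inexact TSDs.

### Default parameter choices

| parameter | default | why |
|---|---|---|
| poly(A) tail length | uniform 10–60 nt | typical LEAP product tail range; no distribution is dictated by the data, so a flat prior over a plausible range |
| retained element length | geometric, mean 150 nt (floor 30) | most genomic L1 inserts are heavily 5' truncated; the floor keeps every simulated insert mappable |
| inversion probability | 0.15 | roughly the fraction of inversion/deletion structures seen among characterized engineered inserts |
| TSD length | uniform 8–20 bp | the typical L1 TSD range |
| deamination presets | `leap_condition()` | per-condition effective probabilities equal to the observed point estimates: adapter/no-RNase-H p(TCA) = 0.91, +RNase H p(TCA) = 0.38 with off-target 0.042, RNase H alone 0.042, catalytic mutant 0.067 |

The same enzyme carries different effective per-site probabilities across
conditions because the exposure *time* differs (the adapter is
single-stranded for the whole reaction, the RNase-H-exposed cDNA only
transiently); the presets are effective rates, not kinetic constants.

### Random-number discipline

One root seed; each product/insertion derives a child seed from it by
counter, so item *i* is reproducible regardless of how many items are drawn,
and writers emit byte-identical FASTA/TSV for identical configurations.

## Calling and accounting

`call_products()` aligns each product to the reference amplicon with an
ends-free (overlap) pairwise alignment — match +1, mismatch −1, a gap of
length *k* costs 3 + *k* — so 5' truncations and tail-length differences are
free end effects rather than penalized gaps. One call is emitted per mismatch
column; gap columns are reported separately by `call_indels()` and excluded
from deamination statistics. Calls are classified mechanically from
(ref, alt): plus-strand G>A (the cDNA deamination signature), plus-strand
C>T (counted apart precisely because cDNA deamination cannot produce it), or
other. The deaminated-strand context attached to each call is the reverse
complement of the plus-strand reference trinucleotide.

Two conventions deserve note:

* **Terminal mismatches.** Under ends-free scoring a mismatch at (or
  immediately next to) a sequence end is indistinguishable from an overhang
  and is trimmed by any optimal aligner. The oracle-equivalence tests
  therefore place substitutions at interior positions; real deamination sites
  sit well inside the amplicon.
* **Availability denominators.** `build_context_table()` counts a site as
  available in a product only if the product's aligned span covers it, so
  truncated products do not inflate denominators; with full-length products
  this reduces to the fixed "sites × products" denominator. The adapter's
  single minus-strand C is tabulated as a separate entry (C-centred, context
  TCA), never merged into the 16 G-centred rows. Percents are reported to one
  decimal; zero availability is reported blank rather than 0 (with zero
  products, percents are defined as 0).

`deamination_fit()` wraps the estimation layer in a classed model object:
binomial point estimates per context with Wilson score intervals, and
`print`/`summary`/`coef`/`confint`/`predict`/`residuals`/`plot`/`simulate`
methods (`simulate` regenerates products from the fitted probabilities —
a parametric bootstrap of the assay).

## Structural annotation and identifiability

`map_insertion()` locates the inserted segment by scanning the pre- and
post-integration sequences inward from both ends. The scans are
*deamination-tolerant*: a reference C read as T (5' side, top strand), a
reference G read as A (3' side / element body) counts as agreement, so
junctions are found exactly even on heavily edited molecules, and an edit at
the very first or last TSD base does not break the boundary. The poly(A)
tail is stripped as the maximal trailing A-run; the remainder is mapped onto
the element as a forward suffix (truncation point = element length − matched
suffix + 1, valid because TPRT anchors the element 3' end) plus, when
present, a reverse-complement segment placed by a unique sliding match
(ambiguous placement is an error, never a guess — likewise an inversion
junction that cannot be distinguished from its alternatives).

`detect_tsd()` then searches, anchored at those exact boundaries, for the
longest duplication of the sequence 5' of the insertion reappearing 3' of it
(default cap 30 bp, at most 2 mismatches). Two guard rails matter:

* the mismatch budget is additionally capped at one per four bases
  (`min(max_mismatch, L %/% 4)`, minimum reported length 4), because a flat
  2-mismatch allowance finds spurious "inexact TSDs" of length 4–6 in ~5% of
  random flank pairs;
* exact recovery of a *planted* TSD length is only guaranteed when the number
  of planted edits in the duplication does not exceed the mismatch budget.

**Why the generator redraws ambiguous structures.** Junction microhomology —
a chance agreement between the first inserted base and the base that would
follow the TSD, a poly(A) tail running into an A-starting flank, or a
duplication scan that would return a longer-than-planted TSD — makes the
planted coordinates genuinely unidentifiable: two different structures
produce the same sequence. The generator therefore redraws such structures
(and `make_reference()` pins the element 3' terminus to a pyrimidine and
places the insertion point after a pyrimidine), so that every planted
structure is recoverable exactly. This conditions the simulated distribution
slightly (a few percent of raw draws are rejected) and is a deliberate trade:
round-trip tests then verify the annotation machinery itself rather than
averaging over intrinsically ambiguous cases. Real data contain such
ambiguous junctions; on them the annotator still returns a deterministic,
canonical answer (longest TSD), it just cannot be checked against a hidden
truth.

TSD mismatches are attributed by the strand rules — 5' copy T vs 3' copy C
is 5'-flank top-strand deamination; 5' copy G vs 3' copy A is 3'-flank
bottom-strand deamination; anything else is unexplained. Coding consequences
of internal calls translate reference vs mutated codons under the standard
genetic code (`silent`/`missense`/`nonsense`, `noncoding` outside supplied
ORFs); inverted-segment edits are mapped back to element coordinates (where
a plus-strand G>A in the insert reads as C>T on the element strand) before
translation.

## Assay quantification

`normalize_retro()` divides the retrotransposition colony ratio
(L1 reporter, cofactor vs control) by the toxicity ratio (NEO control
reporter, cofactor vs control) and scales to percent, so nonspecific
cytotoxicity of the cofactor cancels; the control is 100% by construction
and the whole statistic is invariant to rescaling all counts.
Normalization is per technical replicate, and experiments are pooled at the
replicate level (`aggregate_experiments()`), with the sample (n−1) SD over
all pooled technical replicates — pooling raw counts first would be the main
alternative; per-replicate normalization was chosen because it keeps each
experiment's own control as its reference.

## What the synthetic data do and do not show

The generator emulates: strand-specific editing of exposed single-strand
regions with trinucleotide preference; the adapter-vs-internal exposure
asymmetry and its reversal by RNase H; UNG/UGI-dependent retention of edits;
5' truncation, twin-priming inversions, and (in)exact TSDs. It does not
model RNA secondary structure, RT processivity or misincorporation kinetics,
cell-population dynamics, endonuclease-independent integration, or junction
capture of extraneous sequence (e.g. telomeric repeats at an
inversion/deletion junction). Passing round-trip tests therefore demonstrate
that the calling/annotation stack is exact on the modelled signal — not that
real sequencing artefacts (chimeras, indels in homopolymers, basecall error)
are handled; `background_p` provides only a uniform substitution error.

## Problem sizes used by the tests and the acceptance script

Unit tests run at n = 25–200 products/insertions; property-style checks use
2,000–10,000 products (strand conservation, exposure gating), 1,000 random
pairs (call oracle), 100 replicates of n = 100 products (Wilson CI
coverage of the generator truth p(TCA) = 0.38), and 500 insertions for the
structural round trip. The acceptance script re-runs the full
simulate→align→call→tabulate pipeline at 100 products per characterized
condition, 100 coverage replicates, and 200 annotated insertions — sizes
chosen to keep every stochastic check comfortably tight while the whole
suite stays quick on one CPU.
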