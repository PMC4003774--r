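# l1deam

Simulation and analysis of strand-specific APOBEC3A (A3A) deamination of the
transiently exposed single-strand DNA that arises during LINE-1 (L1)
retrotransposition.

## The problem

L1 elements integrate by target-site primed reverse transcription (TPRT).
During TPRT — and in its in vitro counterpart, the LEAP assay — several DNA
species are transiently single-stranded: the minus-strand cDNA (once RNase H
degrades the mRNA of the mRNA/cDNA heteroduplex), the single-strand 3' RACE
adapter used to prime LEAP reactions, and the genomic flanks of the
integration site. A3A deaminates cytosines in single-strand DNA, preferring
the 5'-TCA-3' context. A C→U event on the minus-strand cDNA is fixed at
second-strand synthesis and read out as a **G→A change on the element's plus
strand** — a strand-specific signature. Uracil repair (UNG) normally erases
or destroys these intermediates; blocking it with UGI makes the edits
observable in recovered insertions, including as *inexact target-site
duplications* (TSDs) when a flank strand was hit.

`l1deam` provides, for anyone studying deaminase editing of retroelement
intermediates:

* a **generative model** of LEAP cDNA products and genomic L1 insertions
  (exposure intervals, per-trinucleotide deamination probabilities
  `p(context)`, UNG/UGI repair branches, 5' truncations, twin-priming
  inversion/deletions, TSDs) with per-item RNG streams and byte-stable
  FASTA/TSV output;
* **edit calling**: ends-free pairwise alignment to the reference amplicon,
  strand-classified substitution calls (`GtoA_plus` / `CtoT_plus` / `other`),
  poly(A) tail-length estimation, indels kept apart;
* **context accounting**: the 16-row G-centred trinucleotide table with
  coverage-aware availability denominators (percent deaminated =
  100 · deaminated / available per context), a separate adapter-site entry,
  per-product edit histograms and independence fingerprints, and a fitted
  model object (`deamination_fit()`) with Wilson score intervals and the
  usual `coef`/`confint`/`predict`/`simulate` methods;
* **insertion annotation**: truncation points, inversion junctions, TSD
  detection with per-mismatch strand attribution (5' copy T vs 3' copy C ⇒
  top-strand deamination of the 5' flank; 5' G vs 3' A ⇒ bottom-strand
  deamination of the 3' flank), and coding consequences of internal edits;
* **assay quantification**: toxicity-normalized retrotransposition
  percentages from colony counts,
  `percent = 100 · (L1 ratio) / (NEO toxicity ratio)`.

The published assay oligonucleotides (the 5np1 LEAP adapter with its single
cytidine at position 30 in a TCA context, the FITC-TCA deaminase substrate,
and the PCR/sequencing primers) ship with the package
(`leap_oligos()`, `inst/extdata/oligos.fasta`).

## Worked example

Simulate 100 LEAP products under the RNase-H condition (generator truth:
p(TCA) = 0.38, off-target 0.042), call edits back by alignment, and fit the
per-context deamination probabilities:

```r
library(l1deam)

ref  <- make_reference(element_length = 300, seed = 7)
cond <- leap_condition("a3a_rnaseh")
sim  <- simulate_leap_products(ref, 100, cond$exposure, cond$deam, seed = 1)
cs   <- call_products(ref, sim$products)
fit  <- deamination_fit(ref, cs$calls, cs$coverage)
summary(fit)
```

```
Per-context deamination fit (internal region, 100 products, 95% Wilson CIs)
     context deaminated available estimate lower upper
         AGA         25       500    0.050 0.034 0.073
         ...
         TGA        148       400    0.370 0.324 0.418
         ...
 adapter:TCA         33       100    0.330 0.246 0.427
Minus-strand 5'-TCA-3' consensus (plus-strand TGA): 148 of 400 sites deaminated (37.0%)
```

The plus-strand TGA row *is* the minus-strand 5'-TCA-3' consensus (reverse
complement): 148 of the 400 available site-product pairs were deaminated, an
estimate of 0.370 whose 95% interval covers the generating value 0.38, while
every off-target row sits near 0.042. Without RNase H the same model edits
only the adapter's single C site and internal rows drop to zero — the
exposure asymmetry that distinguishes a protected heteroduplex from exposed
single-strand cDNA.

Insertions work the same way:

```r
deam <- deamination_model(p_tca = 0.38, p_other = 0.042)
isim <- simulate_insertions(ref, 50, deam, repair_model(ugi_active = TRUE),
                            exposure = exposure_model(rnase_h_active = TRUE,
                                                      flank5_top_exposed = TRUE),
                            seed = 2)
anns <- annotate_insertions(isim)
anns[[1]]   # truncation point, TSD pair with attributions, coding consequences
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/l1deam.R` (subcommands `simulate`, `call`, `contexts`,
`annotate`, `quantify`).

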