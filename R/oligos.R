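#' Oligonucleotides used in the LEAP and deaminase assays
#'
#' Returns the assay oligonucleotides shipped with the package, as a named
#' character vector. These are the published primer/substrate sequences used
#' throughout the worked examples:
#'
#' * `adapter_5np1` — the LEAP 3' RACE adapter ("5np1"): a unique 46-nt
#'   sequence containing a single cytidine (in a 5'-TCA-3' APOBEC3A consensus
#'   context) followed by oligo(dT)12. During LEAP it primes reverse
#'   transcription from the L1 poly(A) tail, and remains single-stranded,
#'   making its lone C the prime deamination target.
#' * `adapter_5np1_outer` — the outer PCR primer nested in the adapter.
#' * `l1_3end` — the L1 3'-end PCR primer.
#' * `fitc_tca` — the FITC-labelled single-strand deaminase-assay substrate
#'   with a single cytosine in a 5'-TCA-3' context.
#' * `neo_as_reco`, `rescue3seq`, `polyAseq` — insertion-recovery sequencing
#'   primers (`polyAseq` contains IUPAC B/N anchor bases).
#'
#' The same sequences are available as a FASTA file via
#' `system.file("extdata", "oligos.fasta", package = "l1deam")`.
#'
#' @return Named character vector of oligonucleotide sequences (5'->3').
#' @examples
#' scan_cytidines(leap_oligos()[["adapter_5np1"]])
#' @export
leap_oligos <- function() {
  c(adapter_5np1 = paste0("GATGGATGATGAATAAAGTGTGGGATGATCATGATGTATGGATAGG",
                          "TTTTTTTTTTTT"),
    adapter_5np1_outer = "GATGGATGATGAATAAAGTG",
    l1_3end = "GGGTTCGAAATCGATAAGCTTGGATCCAGAC",
    fitc_tca = "TATTATTATTATTATTATTCATTTATTTATTTATTTATTT",
    neo_as_reco = "TCTATCGCCTTCTTGACGAG",
    rescue3seq = "ACTCACGTTAAGGGATTTTGGTCA",
    polyAseq = "AAAAAAAAAAAAAAAAAAAABN")
}

#' Scan a single-strand oligonucleotide for cytidines and their contexts
#'
#' Lists every cytosine in a sequence together with its trinucleotide context
#' (read 5'->3' on the strand scanned, C centred). Terminal cytosines have no
#' complete context and are reported with `context = NA` and
#' `is_tca = FALSE`, matching the convention that a C without both neighbours
#' is not an editable consensus site.
#'
#' @param seq A DNA string (A/C/G/T).
#' @return A data.frame with columns `position`, `context`, `is_tca`.
#' @examples
#' scan_cytidines("TTCAT")
#' @export
scan_cytidines <- function(seq) {
  if (!is_dna(seq)) stop_input("sequence must be a non-empty A/C/G/T string")
  pos <- base_positions(seq, "C")
  ctx <- context_at(seq, pos)
  data.frame(position = pos,
             context = ctx,
             is_tca = !is.na(ctx) & ctx == "TCA",
             stringsAsFactors = FALSE)
}

#' Count occurrences of a trinucleotide motif in a sequence
#'
#' Overlapping occurrences are counted.
#'
#' @param seq A DNA string.
#' @param motif A trinucleotide (default the 5'-TCA-3' APOBEC3A consensus).
#' @return Integer count.
#' @export
count_motif <- function(seq, motif = "TCA") {
  n <- nchar(seq)
  if (n < nchar(motif)) return(0L)
  starts <- substring(seq, seq_len(n - nchar(motif) + 1L),
                      nchar(motif):n)
  sum(starts == motif)
}
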