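#' Build a synthetic reference set for LEAP and insertion simulations
#'
#' Constructs (deterministically for a given seed) the two reference sequences
#' every downstream stage works against:
#'
#' * `amplicon_plus` — the plus (coding) strand of the LEAP amplicon: a random
#'   L1-derived segment (GC content constrained to 0.30–0.60), a poly(A)
#'   tract of `ref_tail_length` nt, then the reverse complement of the
#'   adapter's unique (non-oligo-dT) portion. The minus strand of this
#'   amplicon is the first-strand cDNA primed by the adapter.
#' * `genomic_locus` — a random target locus with a defined `insertion_point`
#'   at which simulated integrations occur.
#'
#' The amplicon is partitioned into named regions (`internal`, `tail`,
#' `adapter`) used for region-aware substitution accounting, and the position
#' of the adapter's single minus-strand cytidine is recorded as the
#' `adapter_site` (a plus-strand G).
#'
#' One open reading frame is placed on the element segment (a span whose
#' length is divisible by 3) so that coding consequences of internal edits can
#' be annotated; supply `orf_intervals` to override.
#'
#' @param element_length Length (nt) of the random L1-derived segment
#'   (minimum 200).
#' @param adapter_seq Adapter sequence (5'->3', A/C/G/T); default the packaged
#'   5np1 adapter.
#' @param locus_length Length (nt) of the genomic target locus.
#' @param seed Integer seed; identical seeds give identical references.
#' @param ref_tail_length Poly(A) length of the reference amplicon.
#' @param insertion_point 1-based position in the locus at which insertions are
#'   simulated (defaults to the midpoint, nudged so the base immediately 5' of
#'   it is not an A — a poly(A)/flank junction would otherwise be ambiguous).
#' @param orf_intervals Optional list of `c(start, end)` 1-based inclusive
#'   coding spans on the element segment (lengths divisible by 3).
#' @return An object of class `l1_reference`.
#' @examples
#' ref <- make_reference(element_length = 300, seed = 7)
#' nchar(ref$amplicon_plus)
#' @export
make_reference <- function(element_length = 300L,
                           adapter_seq = leap_oligos()[["adapter_5np1"]],
                           locus_length = 1000L,
                           seed = 1L,
                           ref_tail_length = 30L,
                           insertion_point = NULL,
                           orf_intervals = NULL) {
  if (element_length < 200L) stop_input("element_length must be >= 200")
  if (!is_dna(adapter_seq))
    stop_input("adapter_seq must be a non-empty A/C/G/T string")
  adapter_unique <- sub("T+$", "", adapter_seq)
  if (!nzchar(adapter_unique))
    stop_input("adapter_seq must contain a non-oligo-dT portion")

  with_seed(seed, {
    segment <- random_dna_gc(element_length, gc_min = 0.3, gc_max = 0.6)
    ## pin the element 3' terminus to a pyrimidine so the element/poly(A)
    ## junction of simulated insertions stays identifiable even after G>A
    ## editing of the terminal base
    if (substring(segment, element_length, element_length) %in% c("A", "G"))
      segment <- paste0(substring(segment, 1L, element_length - 1L),
                        sample(c("C", "T"), 1L))
    locus <- random_dna_gc(locus_length, gc_min = 0.3, gc_max = 0.6)
  })

  if (is.null(insertion_point)) {
    insertion_point <- as.integer(locus_length %/% 2L)
    ## the base 5' of the insertion point must not look like poly(A) tail
    ## (A) nor like a deaminated G, or the tail/flank junction of simulated
    ## insertions would be ambiguous
    while (!substring(locus, insertion_point - 1L,
                      insertion_point - 1L) %in% c("C", "T"))
      insertion_point <- insertion_point + 1L
  }
  if (insertion_point < 2L || insertion_point > locus_length - 60L)
    stop_input("insertion_point must leave room for flanks within the locus")
  if (!substring(locus, insertion_point - 1L,
                 insertion_point - 1L) %in% c("C", "T"))
    stop_input("the locus base 5' of insertion_point must be C or T ",
               "(an A- or G-adjacent junction is ambiguous next to the ",
               "poly(A) tail of simulated insertions)")

  amplicon <- paste0(segment, strrep("A", ref_tail_length),
                     revcomp(adapter_unique))
  n_amp <- nchar(amplicon)
  regions <- list(
    internal = c(1L, element_length),
    tail = c(element_length + 1L, element_length + ref_tail_length),
    adapter = c(element_length + ref_tail_length + 1L, n_amp))

  ## the adapter's minus-strand C sites map to plus-strand G's in the adapter
  ## region: minus position i <-> plus position n_amp - i + 1
  c_minus <- base_positions(adapter_unique, "C")
  adapter_site <- sort(n_amp - c_minus + 1L)

  if (is.null(orf_intervals)) {
    orf_len <- 3L * ((element_length - 60L) %/% 3L)
    orf_intervals <- list(c(31L, 30L + orf_len))
  }
  for (iv in orf_intervals) {
    if ((iv[2] - iv[1] + 1L) %% 3L != 0L)
      stop_input("ORF interval lengths must be divisible by 3")
    if (iv[1] < 1L || iv[2] > element_length)
      stop_input("ORF intervals must lie on the element segment")
  }

  structure(list(amplicon_plus = amplicon,
                 element = segment,
                 adapter_seq = adapter_seq,
                 adapter_unique = adapter_unique,
                 ref_tail_length = as.integer(ref_tail_length),
                 regions = regions,
                 adapter_site = adapter_site,
                 genomic_locus = locus,
                 insertion_point = as.integer(insertion_point),
                 orf_intervals = orf_intervals,
                 seed = as.integer(seed)),
            class = "l1_reference")
}

## random DNA with GC content constrained to [gc_min, gc_max]
random_dna_gc <- function(n, gc_min, gc_max, max_tries = 100L) {
  for (k in seq_len(max_tries)) {
    x <- sample(DNA_BASES, n, replace = TRUE)
    gc <- mean(x %in% c("G", "C"))
    if (gc >= gc_min && gc <= gc_max) return(chars_to_seq(x))
  }
  stop("failed to draw a sequence within the GC bounds")
}

#' @export
print.l1_reference <- function(x, ...) {
  cat("LEAP/insertion reference set\n")
  cat(sprintf("  amplicon: %d nt (element %d + poly(A) %d + adapter %d)\n",
              nchar(x$amplicon_plus), nchar(x$element), x$ref_tail_length,
              nchar(revcomp(x$adapter_unique))))
  cat(sprintf("  adapter minus-strand C site(s) at plus position(s): %s\n",
              paste(x$adapter_site, collapse = ", ")))
  cat(sprintf("  genomic locus: %d nt, insertion point %d\n",
              nchar(x$genomic_locus), x$insertion_point))
  cat(sprintf("  ORF interval(s) on element: %s\n",
              paste(vapply(x$orf_intervals,
                           function(iv) sprintf("%d-%d", iv[1], iv[2]),
                           character(1)), collapse = ", ")))
  invisible(x)
}
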