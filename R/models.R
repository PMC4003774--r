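#' Per-context deamination model
#'
#' Probability that an exposed cytosine is deaminated (C->U, observed as C->T
#' after second-strand synthesis), as a function of its trinucleotide context
#' read 5'->3' on the chemically deaminated strand (the minus-strand cDNA, the
#' 5'-flank top strand, or the 3'-flank bottom strand). The APOBEC3A consensus
#' is 5'-TCA-3'; the default model is TCA-dominant with a uniform off-target
#' rate.
#'
#' @param p_tca Probability of deamination at a 5'-TCA-3' site.
#' @param p_other Probability at every other NCN context.
#' @param p_by_context Optional named numeric vector overriding individual
#'   contexts (names among the 16 NCN trinucleotides).
#' @param background_p Per-base probability of a non-deamination substitution
#'   (RT/sequencing error), applied uniformly on the product plus strand.
#' @return An object of class `deamination_model`: list with `p_by_context`
#'   (named length-16 numeric) and `background_p`.
#' @examples
#' m <- deamination_model(p_tca = 0.38, p_other = 0.042)
#' m$p_by_context[["TCA"]]
#' @export
deamination_model <- function(p_tca = 0.38, p_other = 0.042,
                              p_by_context = NULL, background_p = 0) {
  ctx <- trinucleotides("C")
  p <- setNames(rep(p_other, 16L), ctx)
  p[["TCA"]] <- p_tca
  if (!is.null(p_by_context)) {
    bad <- setdiff(names(p_by_context), ctx)
    if (length(bad)) stop_input("unknown context(s): ", paste(bad, collapse = ", "))
    p[names(p_by_context)] <- p_by_context
  }
  if (any(p < 0 | p > 1) || background_p < 0 || background_p > 1)
    stop_input("all probabilities must be in [0, 1]")
  structure(list(p_by_context = p, background_p = background_p),
            class = "deamination_model")
}

#' Single-strand exposure model
#'
#' Controls which parts of a TPRT/LEAP intermediate are single-stranded and
#' hence deaminable. Without RNase H the nascent minus-strand cDNA stays
#' annealed to the L1 mRNA and only the single-strand adapter primer is
#' exposed; with RNase H the full minus-strand cDNA becomes exposed. The two
#' flank flags expose the transiently single-stranded genomic DNA at an
#' integration site: the 5'-flank top strand and the 3'-flank bottom strand
#' (each over the target-site duplication span).
#'
#' @param rnase_h_active Logical; degrade the mRNA of the mRNA/cDNA
#'   heteroduplex, exposing the full minus-strand cDNA.
#' @param flank5_top_exposed,flank3_bottom_exposed Logical; expose the
#'   corresponding genomic flank strand during integration.
#' @return An object of class `exposure_model`.
#' @export
exposure_model <- function(rnase_h_active = FALSE,
                           flank5_top_exposed = FALSE,
                           flank3_bottom_exposed = FALSE) {
  structure(list(rnase_h_active = isTRUE(rnase_h_active),
                 flank5_top_exposed = isTRUE(flank5_top_exposed),
                 flank3_bottom_exposed = isTRUE(flank3_bottom_exposed)),
            class = "exposure_model")
}

## exposed intervals (1-based inclusive) on a minus-strand cDNA of length
## `minus_len` whose 5' end is the adapter's unique (non-oligo-dT) portion
exposed_intervals_minus <- function(exposure, minus_len, adapter_unique_len) {
  if (exposure$rnase_h_active) {
    list(c(1L, minus_len))
  } else {
    list(c(1L, min(adapter_unique_len, minus_len)))
  }
}

#' Uracil repair model
#'
#' What happens to a uracil created by deamination of the minus-strand cDNA or
#' an exposed genomic flank. With active UNG (and no UGI), each uracil is
#' either restored to C (probability `p_restore`, base excision followed by
#' error-free repair), or triggers destruction of the integration intermediate
#' (probability `p_abort`; the event is never recovered), or persists and is
#' fixed as a mutation at second-strand synthesis. Expressing the phage UGI
#' protein blocks UNG entirely, forcing every uracil to persist.
#'
#' @param ung_active Logical; uracil DNA glycosylase active.
#' @param ugi_active Logical; UGI expressed (overrides UNG, all uracils kept).
#' @param p_restore Probability a uracil is repaired back to C.
#' @param p_abort Probability uracil processing destroys the intermediate.
#' @return An object of class `repair_model`.
#' @export
repair_model <- function(ung_active = TRUE, ugi_active = FALSE,
                         p_restore = 0.5, p_abort = 0.5) {
  if (p_restore < 0 || p_abort < 0 || p_restore + p_abort > 1)
    stop_input("need p_restore >= 0, p_abort >= 0, p_restore + p_abort <= 1")
  if (isTRUE(ugi_active) || !isTRUE(ung_active)) {
    p_restore <- 0
    p_abort <- 0
  }
  structure(list(ung_active = isTRUE(ung_active),
                 ugi_active = isTRUE(ugi_active),
                 p_restore = p_restore, p_abort = p_abort),
            class = "repair_model")
}

#' Structural model of simulated products and insertions
#'
#' Distributions for the structural features of simulated LEAP products and
#' genomic insertions. Distributions are supplied as sampler functions
#' `function(n)` returning `n` positive integers, so any discrete law can be
#' plugged in; the defaults are
#'
#' * poly(A) tail length: uniform on 10..60 nt,
#' * retained element length (5' truncation measured from the 3' end):
#'   geometric with mean `mean_retained` (default 150 nt), floored at
#'   `min_retained` and capped at the element length,
#' * inversion/deletion (twin-priming) probability 0.15,
#' * TSD length: uniform on 8..20 bp (the typical L1 target-site duplication
#'   range).
#'
#' @param tail_length_dist Sampler for poly(A) tail lengths.
#' @param retained_length_dist Sampler for retained element lengths (before
#'   flooring/capping).
#' @param p_inversion Probability that an insertion has an inversion/deletion
#'   structure.
#' @param tsd_length_dist Sampler for TSD lengths.
#' @param min_retained Minimum retained element length (identifiability floor
#'   for structural annotation).
#' @param mean_retained Mean of the default geometric retained-length law.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(tail_length_dist = NULL,
                            retained_length_dist = NULL,
                            p_inversion = 0.15,
                            tsd_length_dist = NULL,
                            min_retained = 30L,
                            mean_retained = 150) {
  if (p_inversion < 0 || p_inversion > 1)
    stop_input("p_inversion must be in [0, 1]")
  if (is.null(tail_length_dist))
    tail_length_dist <- function(n) sample.int(51L, n, replace = TRUE) + 9L
  if (is.null(retained_length_dist))
    retained_length_dist <- function(n) 1L + stats::rgeom(n, 1 / mean_retained)
  if (is.null(tsd_length_dist))
    tsd_length_dist <- function(n) sample.int(13L, n, replace = TRUE) + 7L
  structure(list(tail_length_dist = tail_length_dist,
                 retained_length_dist = retained_length_dist,
                 p_inversion = p_inversion,
                 tsd_length_dist = tsd_length_dist,
                 min_retained = as.integer(min_retained)),
            class = "structure_model")
}

#' Preset experimental conditions
#'
#' Deamination/exposure presets matching the characterized LEAP reaction
#' conditions, with per-condition effective deamination probabilities taken
#' from the corresponding observed point estimates (adapter-site and internal
#' 5'-TCA-3' deamination fractions). The same enzyme shows different
#' effective per-site probabilities across conditions because the exposure
#' time of the substrate differs (the adapter is single-stranded for the whole
#' reaction; RNase-H-exposed cDNA only transiently).
#'
#' * `"a3a"` — wild-type deaminase, no RNase H: only the adapter is exposed;
#'   p(TCA) = 0.91.
#' * `"a3a_rnaseh"` — wild-type deaminase plus RNase H: full minus-strand
#'   exposure; p(TCA) = 0.38, off-target 0.042.
#' * `"rnaseh_only"` — RNase H without added deaminase (residual endogenous
#'   activity): uniform 0.042.
#' * `"c106s_rnaseh"` — catalytic-mutant deaminase plus RNase H:
#'   p(TCA) = 0.067, off-target 0.042.
#'
#' @param condition One of the preset names above.
#' @return List with elements `deam` (a [deamination_model()]) and `exposure`
#'   (an [exposure_model()]).
#' @examples
#' leap_condition("a3a_rnaseh")$deam$p_by_context[["TCA"]]
#' @export
leap_condition <- function(condition = c("a3a", "a3a_rnaseh", "rnaseh_only",
                                         "c106s_rnaseh")) {
  condition <- match.arg(condition)
  switch(condition,
    a3a = list(deam = deamination_model(p_tca = 0.91, p_other = 0.042),
               exposure = exposure_model(rnase_h_active = FALSE)),
    a3a_rnaseh = list(deam = deamination_model(p_tca = 0.38, p_other = 0.042),
                      exposure = exposure_model(rnase_h_active = TRUE)),
    rnaseh_only = list(deam = deamination_model(p_tca = 0.042, p_other = 0.042),
                       exposure = exposure_model(rnase_h_active = TRUE)),
    c106s_rnaseh = list(deam = deamination_model(p_tca = 0.067, p_other = 0.042),
                        exposure = exposure_model(rnase_h_active = TRUE)))
}
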