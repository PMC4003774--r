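## ---- deamination-tolerant junction scans -----------------------------------
## Boundary finding treats a deamination-consistent difference (reference C
## read as T on the strand deaminated 5' of the insertion, reference G read as
## A 3' of it, element G read as A inside the insert) as agreement, so
## junctions are located exactly even on heavily edited molecules. The scans
## assume substitution-only differences (no indels in the flanks), which is
## the TPRT situation the generator emulates.

agree_len_left <- function(x, y, rule = c("ct", "ga", "plain")) {
  rule <- match.arg(rule)
  a <- seq_chars(x); b <- seq_chars(y)
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  ok <- switch(rule,
               ct = a == b | (a == "C" & b == "T"),
               ga = a == b | (a == "G" & b == "A"),
               plain = a == b)
  bad <- which(!ok)
  if (!length(bad)) n else bad[1L] - 1L
}

agree_len_right <- function(x, y, rule = c("ct", "ga", "plain")) {
  rule <- match.arg(rule)
  a <- rev(seq_chars(x)); b <- rev(seq_chars(y))
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  ok <- switch(rule,
               ct = a == b | (a == "C" & b == "T"),
               ga = a == b | (a == "G" & b == "A"),
               plain = a == b)
  bad <- which(!ok)
  if (!length(bad)) n else bad[1L] - 1L
}

## longest duplication of the end of left_ctx at the start of right_ctx;
## the mismatch budget is capped at one per four bases so short spurious
## inexact TSDs are not called in random flanks
tsd_scan <- function(left_ctx, right_ctx, max_len = 30L, max_mismatch = 2L,
                     min_len = 4L) {
  lmax <- min(max_len, nchar(left_ctx), nchar(right_ctx))
  lc <- seq_chars(left_ctx)
  rc <- seq_chars(right_ctx)
  for (L in rev(seq_len(lmax))) {
    if (L < min_len) break
    b5 <- lc[(length(lc) - L + 1L):length(lc)]
    b3 <- rc[seq_len(L)]
    mm <- which(b5 != b3)
    if (length(mm) <= min(max_mismatch, L %/% 4L)) {
      return(list(length = L, n_mismatch = length(mm), offsets = mm,
                  base5 = b5[mm], base3 = b3[mm],
                  tsd5 = chars_to_seq(b5), tsd3 = chars_to_seq(b3)))
    }
  }
  list(length = 0L, n_mismatch = 0L, offsets = integer(0),
       base5 = character(0), base3 = character(0), tsd5 = "", tsd3 = "")
}

#' Locate the element-derived segment(s) of a post-integration locus
#'
#' Compares the pre- and post-integration locus sequences to find the
#' inserted segment, strips its poly(A) tail, and maps the remainder onto the
#' element: a single forward segment (`element[truncation_point..end]`) for a
#' canonical 5'-truncated insertion, or an inverted segment followed by a
#' forward segment (twin priming) with the inversion/deletion junction at
#' their boundary. Boundary scans are deamination-tolerant (G>A / C>T
#' consistent differences do not break the match) and assume
#' substitution-only differences in the flanks.
#'
#' @param pre_locus Pre-integration locus sequence.
#' @param post_locus Post-integration locus sequence.
#' @param element Element (plus strand) the insertion derives from.
#' @return List with `segments` (data.frame: `element_start`, `element_end`,
#'   `orientation` (`+`/`-`), `insert_start`, `insert_end` — insert
#'   coordinates are 1-based within the inserted segment), `truncation_point`,
#'   `inversion` (logical), `junction_insert` (insert coordinate of the first
#'   forward-segment base, NA without inversion), `insert_seq`,
#'   `poly_a_length`, and `flank` (list `left_end`, `right_start`: post-locus
#'   coordinates delimiting the insertion).
#' @export
map_insertion <- function(pre_locus, post_locus, element) {
  if (identical(pre_locus, post_locus))
    stop(errorCondition("no insertion: pre- and post-integration sequences are identical",
                        class = c("l1deam_annotation_error", "error")))
  jl <- agree_len_left(pre_locus, post_locus, rule = "ct")
  jr <- agree_len_right(pre_locus, post_locus, rule = "ga")
  n_post <- nchar(post_locus)
  ins_len <- n_post - jr - jl
  if (ins_len < 1L)
    stop(errorCondition("no inserted segment found between the flanks",
                        class = c("l1deam_annotation_error", "error")))
  insert_seq <- substring(post_locus, jl + 1L, n_post - jr)

  ## strip the poly(A) tail
  ins_chars <- seq_chars(insert_seq)
  ta <- 0L
  while (ta < length(ins_chars) && ins_chars[length(ins_chars) - ta] == "A")
    ta <- ta + 1L
  elem_region <- substring(insert_seq, 1L, nchar(insert_seq) - ta)
  if (nchar(elem_region) < 20L)
    stop(errorCondition("no element-derived segment found in the insertion",
                        class = c("l1deam_annotation_error", "error")))

  elen <- nchar(element)
  fl <- agree_len_right(element, elem_region, rule = "ga")
  fl <- min(fl, elen)
  q <- nchar(elem_region) - fl

  if (q == 0L) {
    trunc <- elen - fl + 1L
    segments <- data.frame(element_start = trunc, element_end = elen,
                           orientation = "+",
                           insert_start = 1L, insert_end = fl,
                           stringsAsFactors = FALSE)
    inversion <- FALSE
    junction <- NA_integer_
  } else {
    if (fl < 20L && q >= 20L) {
      ## no usable forward anchor: try a fully inverted (minus-orientation)
      ## placement of the whole region below
      fl <- 0L
      q <- nchar(elem_region)
    } else if (fl < 20L) {
      stop(errorCondition("no element-derived segment found in the insertion",
                          class = c("l1deam_annotation_error", "error")))
    }
    rem <- substring(elem_region, 1L, q)
    a <- place_inverted_segment(revcomp(rem), element,
                                limit_end = if (fl > 0L) elen - fl else elen)
    segments <- data.frame(
      element_start = c(a, if (fl > 0L) elen - fl + 1L),
      element_end = c(a + q - 1L, if (fl > 0L) elen),
      orientation = c("-", if (fl > 0L) "+"),
      insert_start = c(1L, if (fl > 0L) q + 1L),
      insert_end = c(q, if (fl > 0L) q + fl),
      stringsAsFactors = FALSE)
    inversion <- fl > 0L
    trunc <- min(segments$element_start)
    junction <- if (inversion) q + 1L else NA_integer_
  }

  list(segments = segments, truncation_point = trunc,
       inversion = inversion, junction_insert = junction,
       insert_seq = insert_seq, poly_a_length = ta,
       flank = list(left_end = jl, right_start = n_post - jr + 1L))
}

## unique deamination-tolerant placement of an inverted segment on the
## element; ambiguity (2+ placements) is an error, never a guess
place_inverted_segment <- function(probe_plus, element, limit_end) {
  q <- nchar(probe_plus)
  probe <- seq_chars(probe_plus)        # element-plus-strand reading
  ech <- seq_chars(element)
  lim <- min(limit_end, length(ech)) - q + 1L
  if (lim < 1L)
    stop(errorCondition("inverted segment longer than the available element",
                        class = c("l1deam_annotation_error", "error")))
  thr <- floor(0.2 * q)
  hits <- integer(0)
  for (s in seq_len(lim)) {
    win <- ech[s:(s + q - 1L)]
    mm <- sum(!(win == probe | (win == "C" & probe == "T")))
    if (mm <= thr) hits <- c(hits, s)
  }
  if (length(hits) == 0L)
    stop(errorCondition("inverted segment does not map to the element",
                        class = c("l1deam_annotation_error", "error")))
  if (length(hits) > 1L)
    stop(errorCondition("ambiguous inverted-segment placement on the element",
                        class = c("l1deam_annotation_error", "error")))
  hits
}

#' Detect the target-site duplication flanking an insertion
#'
#' Finds the longest duplication (up to `max_len`, with at most
#' `min(max_mismatch, L %/% 4)` mismatches for a length-L candidate) of the
#' sequence immediately 5' of the insertion reappearing immediately 3' of it,
#' anchored at the exact flank boundaries from [map_insertion()]. Ties are
#' broken toward the longer duplication. Each mismatch between the two copies
#' is attributed by [classify_tsd_mismatch()].
#'
#' @param pre_locus,post_locus,element As in [map_insertion()].
#' @param mapping Optional precomputed [map_insertion()] result.
#' @param max_len Longest TSD considered (default 30).
#' @param max_mismatch Mismatch cap between the two copies (default 2).
#' @return List with `tsd5`, `tsd3` (empty strings when no duplication is
#'   found), `length`, `status` (`"exact"`/`"inexact"`), and `mismatches`
#'   (data.frame `offset`, `base5`, `base3`, `attribution`).
#' @export
detect_tsd <- function(pre_locus, post_locus, element, mapping = NULL,
                       max_len = 30L, max_mismatch = 2L) {
  if (is.null(mapping)) mapping <- map_insertion(pre_locus, post_locus, element)
  jl <- mapping$flank$left_end
  rs <- mapping$flank$right_start
  left_ctx <- substring(post_locus, max(1L, jl - max_len + 1L), jl)
  right_ctx <- substring(post_locus, rs,
                         min(nchar(post_locus), rs + max_len - 1L))
  hit <- tsd_scan(left_ctx, right_ctx, max_len = max_len,
                  max_mismatch = max_mismatch)
  mismatches <- data.frame(offset = hit$offsets, base5 = hit$base5,
                           base3 = hit$base3,
                           attribution = classify_tsd_mismatch(hit$base5,
                                                               hit$base3),
                           stringsAsFactors = FALSE)
  list(tsd5 = hit$tsd5, tsd3 = hit$tsd3, length = hit$length,
       status = if (hit$n_mismatch == 0L) "exact" else "inexact",
       mismatches = mismatches)
}

#' Attribute a TSD mismatch to a deamination mechanism
#'
#' Deamination of the transiently exposed 5'-flank top strand leaves a C>T
#' change in the 5' TSD copy relative to the 3' copy (`base5 = T`,
#' `base3 = C`); deamination of the 3'-flank bottom strand leaves a G>A
#' change in the 3' copy relative to the 5' copy (`base5 = G`, `base3 = A`).
#' Anything else is `unexplained`.
#'
#' @param base5,base3 The differing bases in the 5' and 3' TSD copies
#'   (vectorised).
#' @return Character vector of attributions.
#' @export
classify_tsd_mismatch <- function(base5, base3) {
  out <- rep("unexplained", length(base5))
  out[base5 == "T" & base3 == "C"] <- "five_prime_top_strand_deamination"
  out[base5 == "G" & base3 == "A"] <- "three_prime_bottom_strand_deamination"
  out
}

#' Coding consequence of a substitution on the element
#'
#' Translates the reference and mutated codons (standard genetic code) for a
#' substitution inside a supplied ORF: `silent` (same amino acid),
#' `nonsense` (stop gained), `missense` (otherwise); positions outside every
#' ORF are `noncoding`.
#'
#' @param position 1-based element coordinate of the substitution.
#' @param ref,alt Reference and observed base on the element plus strand.
#' @param element Element sequence.
#' @param orf_intervals List of `c(start, end)` 1-based inclusive ORF spans
#'   (in-frame, lengths divisible by 3).
#' @return One of `"noncoding"`, `"silent"`, `"missense"`, `"nonsense"`.
#' @examples
#' ## a TGG (Trp) codon hit at its second position becomes TAG (stop)
#' annotate_coding_consequence(2, "G", "A", "TGGAAA", list(c(1, 6)))
#' @export
annotate_coding_consequence <- function(position, ref, alt, element,
                                        orf_intervals) {
  hit <- NULL
  for (iv in orf_intervals) {
    if (position >= iv[1] && position <= iv[2]) { hit <- iv; break }
  }
  if (is.null(hit)) return("noncoding")
  if (substring(element, position, position) != ref)
    stop_input("ref base does not match the element at position ", position)
  off <- position - hit[1]
  cstart <- hit[1] + 3L * (off %/% 3L)
  codon_ref <- substring(element, cstart, cstart + 2L)
  codon_alt <- mutate_at(codon_ref, off %% 3L + 1L, alt)
  aa_ref <- Biostrings::GENETIC_CODE[[codon_ref]]
  aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
  if (aa_alt == aa_ref) "silent"
  else if (aa_alt == "*") "nonsense"
  else "missense"
}

#' Structurally annotate one insertion
#'
#' Full annotation of a recovered insertion against the element and the
#' pre-integration locus: element segment mapping (truncation, inversion),
#' TSD detection with per-mismatch strand attribution, and internal
#' substitution calls in element coordinates with coding consequences.
#'
#' @param pre_locus,post_locus,element As in [map_insertion()].
#' @param orf_intervals ORF spans on the element (see
#'   [annotate_coding_consequence()]); `NULL` for none (all internal calls
#'   `noncoding`).
#' @param max_tsd_len,max_tsd_mismatch Passed to [detect_tsd()].
#' @return Object of class `l1_annotated_insertion`: list with
#'   `truncation_point`, `inversion`, `segments`, `junction_insert`,
#'   `poly_a_length`, `tsd5`, `tsd3`, `tsd_length`, `tsd_status`,
#'   `tsd_mismatches`, and `internal_calls` (data.frame: `insert_position`,
#'   `element_position`, `in_inverted`, `element_ref`, `element_alt`,
#'   `strand_class` — classified on the post-integration plus strand — and
#'   `consequence`).
#' @export
annotate_insertion <- function(pre_locus, post_locus, element,
                               orf_intervals = NULL,
                               max_tsd_len = 30L, max_tsd_mismatch = 2L) {
  mapping <- map_insertion(pre_locus, post_locus, element)
  tsd <- detect_tsd(pre_locus, post_locus, element, mapping = mapping,
                    max_len = max_tsd_len, max_mismatch = max_tsd_mismatch)

  ins <- seq_chars(mapping$insert_seq)
  calls <- list()
  for (si in seq_len(nrow(mapping$segments))) {
    seg <- mapping$segments[si, ]
    obs <- ins[seg$insert_start:seg$insert_end]
    if (seg$orientation == "+") {
      refb <- seq_chars(substring(element, seg$element_start,
                                  seg$element_end))
      epos <- seg$element_start:seg$element_end
      eref <- refb; ealt <- obs
      post_ref <- refb; post_alt <- obs
    } else {
      ## insert read is the reverse complement of the element segment
      refb <- seq_chars(revcomp(substring(element, seg$element_start,
                                          seg$element_end)))
      epos <- seg$element_end:seg$element_start
      eref <- chartr_vec(refb); ealt <- chartr_vec(obs)
      post_ref <- refb; post_alt <- obs
    }
    mm <- which(refb != obs)
    if (length(mm)) {
      calls[[si]] <- data.frame(
        insert_position = seg$insert_start + mm - 1L,
        element_position = epos[mm],
        in_inverted = seg$orientation == "-",
        element_ref = unname(eref[mm]), element_alt = unname(ealt[mm]),
        strand_class = classify_substitution(post_ref[mm], post_alt[mm]),
        stringsAsFactors = FALSE)
    }
  }
  internal_calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(insert_position = integer(0), element_position = integer(0),
               in_inverted = logical(0), element_ref = character(0),
               element_alt = character(0), strand_class = character(0),
               stringsAsFactors = FALSE)
  internal_calls <- internal_calls[order(internal_calls$insert_position), ,
                                   drop = FALSE]
  rownames(internal_calls) <- NULL
  internal_calls$consequence <- vapply(seq_len(nrow(internal_calls)),
    function(k) annotate_coding_consequence(
      internal_calls$element_position[k], internal_calls$element_ref[k],
      internal_calls$element_alt[k], element,
      if (is.null(orf_intervals)) list() else orf_intervals),
    character(1))

  structure(list(truncation_point = mapping$truncation_point,
                 inversion = mapping$inversion,
                 segments = mapping$segments,
                 junction_insert = mapping$junction_insert,
                 poly_a_length = mapping$poly_a_length,
                 tsd5 = tsd$tsd5, tsd3 = tsd$tsd3, tsd_length = tsd$length,
                 tsd_status = tsd$status, tsd_mismatches = tsd$mismatches,
                 internal_calls = internal_calls),
            class = "l1_annotated_insertion")
}

#' @export
print.l1_annotated_insertion <- function(x, ...) {
  cat("Annotated insertion\n")
  cat(sprintf("  truncation point: %d%s\n", x$truncation_point,
              if (x$inversion) sprintf(" (inversion/deletion, junction at insert position %d)",
                                       x$junction_insert) else ""))
  cat(sprintf("  TSD: %s / %s (%d bp, %s)\n",
              if (nzchar(x$tsd5)) x$tsd5 else "-",
              if (nzchar(x$tsd3)) x$tsd3 else "-",
              x$tsd_length, x$tsd_status))
  if (nrow(x$tsd_mismatches))
    for (k in seq_len(nrow(x$tsd_mismatches)))
      cat(sprintf("    mismatch at offset %d: %s vs %s -> %s\n",
                  x$tsd_mismatches$offset[k], x$tsd_mismatches$base5[k],
                  x$tsd_mismatches$base3[k], x$tsd_mismatches$attribution[k]))
  cat(sprintf("  internal calls: %d (%s)\n", nrow(x$internal_calls),
              if (nrow(x$internal_calls))
                paste(table(x$internal_calls$consequence), collapse = "/")
              else "none"))
  invisible(x)
}

#' Annotate all recovered insertions of a simulation
#'
#' @param sim An `l1_insertion_sim`.
#' @return Named list of [annotate_insertion()] results (one per recovered
#'   insertion).
#' @export
annotate_insertions <- function(sim) {
  stopifnot(inherits(sim, "l1_insertion_sim"))
  rec <- recovered_insertions(sim)
  out <- lapply(seq_len(nrow(rec)), function(i)
    annotate_insertion(sim$ref$genomic_locus, rec$post_sequence[i],
                       sim$ref$element, sim$ref$orf_intervals))
  names(out) <- rec$insertion_id
  out
}
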