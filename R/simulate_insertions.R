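#' Simulate genomic L1 insertions
#'
#' Generative model of TPRT outcomes at the reference locus. For each
#' insertion the generator draws a target-site duplication (TSD) length, a 5'
#' truncation of the element (retained length geometric from the 3' end),
#' optionally an inversion/deletion (twin-priming) structure, and a poly(A)
#' tail; assembles the post-integration locus as
#' `flank5 + TSD + element part + poly(A) + TSD + flank3`; deaminates the
#' minus-strand cDNA (when `exposure$rnase_h_active`) and, per the flank
#' flags, the 5'-flank top strand and 3'-flank bottom strand over the TSD
#' spans; and routes every uracil through the repair model: restored to C,
#' aborting the intermediate (`recovered = FALSE`; the insertion is counted in
#' the truth totals but excluded from the recovered set), or retained and
#' fixed as a mutation (always, under UGI).
#'
#' Fixed mutations surface as G>A on the post-integration plus strand for
#' cDNA edits, C>T in the 5' TSD copy for 5'-flank top-strand edits, and G>A
#' in the 3' TSD copy for 3'-flank bottom-strand edits.
#'
#' Structures whose junctions would be ambiguous (a chance base coincidence —
#' microhomology — that shifts the apparent junction, also allowing for bases
#' that editing could turn into a coincidence) are redrawn, so every planted
#' structure is identifiable; the vignette discusses why exact structural
#' round-trips require this.
#'
#' @param ref An [make_reference()] reference set.
#' @param n Number of insertions (>= 1).
#' @param deam A [deamination_model()].
#' @param repair A [repair_model()].
#' @param structure A [structure_model()].
#' @param exposure An [exposure_model()]; defaults to RNase H active (the
#'   in-vivo situation in which the cDNA is deaminable) with both flanks
#'   unexposed.
#' @param seed Integer root seed (per-insertion child streams by counter).
#' @return Object of class `l1_insertion_sim`: list with `insertions`
#'   (data.frame: `insertion_id`, `post_sequence`, `truncation_point`,
#'   `inversion`, `inv_start`, `inv_end`, `fwd_start`, `tail_length`,
#'   `tsd_length`, `tsd5`, `tsd3`, `n_internal_edits`, `n_flank_edits`,
#'   `recovered`), `internal_truth` (per-edit: insert/element coordinates,
#'   orientation, ref/alt), `flank_truth` (side, offset within the TSD,
#'   bases, expected attribution), and the models used.
#' @export
simulate_insertions <- function(ref, n,
                                deam = deamination_model(),
                                repair = repair_model(),
                                structure = structure_model(),
                                exposure = exposure_model(rnase_h_active = TRUE),
                                seed = 1L) {
  stopifnot(inherits(ref, "l1_reference"), n >= 1)
  locus <- ref$genomic_locus
  ip <- ref$insertion_point

  rows <- vector("list", n)
  int_truth <- vector("list", n)
  flank_truth <- vector("list", n)

  for (i in seq_len(n)) {
    with_seed(child_seed(seed, i + 500000L), {
      draw <- draw_identifiable_structure(ref, structure, deam)
      tail_len <- as.integer(structure$tail_length_dist(1L))

      ins_elem <- draw$insert_elem      # element-derived part, plus strand
      ## deaminate the minus-strand cDNA of the full insert (element + tail)
      insert_plus <- paste0(ins_elem, strrep("A", tail_len))
      minus <- revcomp(insert_plus)
      internal <- data.frame(position = integer(0), context = character(0))
      if (exposure$rnase_h_active) {
        de <- apply_deamination(minus, list(c(1L, nchar(minus))), deam)
        internal <- de$edits
      }
      ## map minus positions to insert plus positions
      int_pos_plus <- nchar(insert_plus) - internal$position + 1L

      ## flank (TSD) edits: 5' copy top strand, 3' copy bottom strand
      tsd <- draw$tsd
      f5 <- f3 <- data.frame(offset = integer(0), ref = character(0),
                             alt = character(0), attribution = character(0),
                             stringsAsFactors = FALSE)
      if (exposure$flank5_top_exposed) {
        de5 <- apply_deamination(flank_ctx_seq(locus, ip, tsd),
                                 list(tsd_span(tsd)), deam)
        if (nrow(de5$edits)) {
          f5 <- data.frame(offset = de5$edits$position - 1L,
                           ref = "C", alt = "T",
                           attribution = "five_prime_top_strand_deamination",
                           stringsAsFactors = FALSE)
        }
      }
      if (exposure$flank3_bottom_exposed) {
        ## bottom strand of the TSD span, read 5'->3' (revcomp of top)
        bottom <- revcomp(flank_ctx_seq(locus, ip, tsd))
        de3 <- apply_deamination(bottom, list(tsd_span(tsd)), deam)
        if (nrow(de3$edits)) {
          ## bottom position b (context length L+2) -> top-strand TSD offset
          f3 <- data.frame(offset = nchar(tsd) + 2L - de3$edits$position,
                           ref = "G", alt = "A",
                           attribution = "three_prime_bottom_strand_deamination",
                           stringsAsFactors = FALSE)
        }
      }

      ## repair branches over every uracil (cDNA + flanks)
      n_u <- length(int_pos_plus) + nrow(f5) + nrow(f3)
      keep <- rep(TRUE, n_u)
      aborted <- FALSE
      if (!repair$ugi_active && repair$ung_active && n_u > 0L) {
        u <- runif(n_u)
        keep <- u >= repair$p_restore + repair$p_abort
        aborted <- any(u >= repair$p_restore &
                       u < repair$p_restore + repair$p_abort)
      }
      k_int <- seq_len(length(int_pos_plus))
      k5 <- length(int_pos_plus) + seq_len(nrow(f5))
      k3 <- length(int_pos_plus) + nrow(f5) + seq_len(nrow(f3))
      int_pos_plus <- int_pos_plus[keep[k_int]]
      f5 <- f5[keep[k5], , drop = FALSE]
      f3 <- f3[keep[k3], , drop = FALSE]

      ## assemble the post-integration locus
      insert_edited <- mutate_at(insert_plus, int_pos_plus, "A")
      tsd5 <- mutate_at(tsd, f5$offset, "T")
      tsd3 <- mutate_at(tsd, f3$offset, "A")
      post <- paste0(substring(locus, 1L, ip - 1L), tsd5, insert_edited,
                     tsd3, substring(locus, ip + nchar(tsd), nchar(locus)))

      id <- sprintf("insertion_%05d", i)
      rows[[i]] <- data.frame(
        insertion_id = id, post_sequence = post,
        truncation_point = draw$truncation_point,
        inversion = draw$inversion,
        inv_start = draw$inv_start, inv_end = draw$inv_end,
        fwd_start = draw$fwd_start,
        tail_length = tail_len, tsd_length = nchar(tsd),
        tsd5 = tsd5, tsd3 = tsd3,
        n_internal_edits = length(int_pos_plus),
        n_flank_edits = nrow(f5) + nrow(f3),
        recovered = !aborted, stringsAsFactors = FALSE)

      if (length(int_pos_plus)) {
        emap <- insert_element_map(draw, nchar(insert_plus))
        int_truth[[i]] <- data.frame(
          insertion_id = id,
          insert_position = as.integer(int_pos_plus),
          element_position = emap$elem_pos[int_pos_plus],
          in_inverted = emap$inverted[int_pos_plus],
          ref = "G", alt = "A", stringsAsFactors = FALSE)
      }
      if (nrow(f5) || nrow(f3)) {
        flank_truth[[i]] <- rbind(
          if (nrow(f5)) cbind(insertion_id = id, side = "five_prime", f5,
                              stringsAsFactors = FALSE),
          if (nrow(f3)) cbind(insertion_id = id, side = "three_prime", f3,
                              stringsAsFactors = FALSE))
      }
    })
  }

  insertions <- do.call(rbind, rows)
  rownames(insertions) <- NULL
  int_truth <- do.call(rbind, int_truth[!vapply(int_truth, is.null,
                                                logical(1))])
  flank_truth <- do.call(rbind, flank_truth[!vapply(flank_truth, is.null,
                                                    logical(1))])
  structure(list(insertions = insertions,
                 internal_truth = int_truth,
                 flank_truth = flank_truth,
                 ref = ref, deam = deam, repair = repair,
                 structure = structure, exposure = exposure,
                 seed = as.integer(seed)),
            class = "l1_insertion_sim")
}

## TSD with one base of locus context either side, so TSD-terminal C's have a
## defined trinucleotide context on the exposed strand
flank_ctx_seq <- function(locus, ip, tsd) {
  paste0(substring(locus, ip - 1L, ip - 1L), tsd,
         substring(locus, ip + nchar(tsd), ip + nchar(tsd)))
}

tsd_span <- function(tsd) c(2L, nchar(tsd) + 1L)

mutate_at <- function(seq, offsets, base) {
  if (!length(offsets)) return(seq)
  ch <- seq_chars(seq)
  ch[offsets] <- base
  chars_to_seq(ch)
}

## uniform integer draw on lo..hi that never falls into sample()'s scalar trap
rng_int <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

## element coordinate and orientation for every position of the insert plus
## strand (poly(A) positions get NA)
insert_element_map <- function(draw, insert_len) {
  elem_pos <- rep(NA_integer_, insert_len)
  inverted <- rep(FALSE, insert_len)
  if (draw$inversion) {
    q <- draw$inv_end - draw$inv_start + 1L
    elem_pos[seq_len(q)] <- draw$inv_end - seq_len(q) + 1L
    inverted[seq_len(q)] <- TRUE
    fl <- nchar(draw$insert_elem) - q
    elem_pos[q + seq_len(fl)] <- draw$fwd_start + seq_len(fl) - 1L
  } else {
    rl <- nchar(draw$insert_elem)
    elem_pos[seq_len(rl)] <- draw$truncation_point + seq_len(rl) - 1L
  }
  list(elem_pos = elem_pos, inverted = inverted)
}

## could `obs` be confused with `ref` once deamination-consistent changes
## (ref G read as A, or an observed G editable to A) are allowed for?
junction_ambiguous <- function(ref_base, obs_base) {
  obs <- obs_base
  if (obs_base == "G") obs <- c(obs, "A")       # obs may be edited later
  any(obs == ref_base | (ref_base == "G" & obs == "A") |
        (ref_base == "C" & obs == "T"))
}

## draw (and redraw until identifiable) a truncation / inversion / TSD
## structure; uses the current RNG stream
draw_identifiable_structure <- function(ref, structure, deam,
                                        max_tries = 200L) {
  element <- ref$element
  elen <- nchar(element)
  locus <- ref$genomic_locus
  ip <- ref$insertion_point

  for (k in seq_len(max_tries)) {
    tsd_len <- as.integer(structure$tsd_length_dist(1L))
    retained <- as.integer(structure$retained_length_dist(1L))
    retained <- max(structure$min_retained, min(elen, retained))
    trunc <- elen - retained + 1L
    inversion <- runif(1L) < structure$p_inversion && retained >= 40L

    if (inversion) {
      q <- rng_int(10L, min(60L, retained - 30L))
      d_max <- min(30L, retained - q - 20L)
      d <- if (d_max > 0L) rng_int(0L, d_max) else 0L
      inv_start <- trunc
      inv_end <- trunc + q - 1L
      fwd_start <- trunc + q + d
      insert_elem <- paste0(revcomp(substring(element, inv_start, inv_end)),
                            substring(element, fwd_start, elen))
    } else {
      q <- 0L
      inv_start <- inv_end <- fwd_start <- NA_integer_
      insert_elem <- substring(element, trunc, elen)
    }

    ## identifiability checks ------------------------------------------------
    ## (1) 5' junction: the first insert base must stay distinguishable from
    ##     the base that follows the TSD in the pre-integration locus
    if (junction_ambiguous(substring(locus, ip + tsd_len, ip + tsd_len),
                           substring(insert_elem, 1L, 1L))) next
    tsd <- substring(locus, ip, ip + tsd_len - 1L)
    ## (2) inversion junction: the last inverted base must stay
    ##     distinguishable from the element base 5' of the forward segment
    if (inversion) {
      last_inv <- substring(insert_elem, q, q)
      if (junction_ambiguous(substring(element, fwd_start - 1L,
                                       fwd_start - 1L), last_inv)) next
      if (!unique_revcomp_placement(element, inv_start, inv_end)) next
    }
    ## (3) the duplication scan on the assembled flanks must return exactly
    ##     the planted TSD
    left_ctx <- paste0(substring(locus, 1L, ip - 1L), tsd)
    right_ctx <- paste0(tsd, substring(locus, ip + tsd_len, nchar(locus)))
    hit <- tsd_scan(left_ctx, right_ctx, max_len = 30L, max_mismatch = 2L)
    if (hit$length != tsd_len || hit$n_mismatch != 0L) next

    return(list(truncation_point = trunc, inversion = inversion,
                inv_start = inv_start, inv_end = inv_end,
                fwd_start = fwd_start, insert_elem = insert_elem,
                tsd = tsd))
  }
  stop("could not draw an identifiable insertion structure; ",
       "check the structural model against the reference")
}

## TRUE when element[a..b] matches no other window of the element at <= 20%
## deamination-tolerant mismatches (the inverted-segment placement is unique)
unique_revcomp_placement <- function(element, a, b) {
  q <- b - a + 1L
  probe <- seq_chars(substring(element, a, b))
  ech <- seq_chars(element)
  lim <- length(ech) - q + 1L
  thr <- floor(0.2 * q)
  n_hits <- 0L
  for (s in seq_len(lim)) {
    win <- ech[s:(s + q - 1L)]
    mm <- sum(!(win == probe | (win == "C" & probe == "T") |
                  (win == "G" & probe == "A")))
    if (mm <= thr) {
      n_hits <- n_hits + 1L
      if (n_hits > 1L) return(FALSE)
    }
  }
  n_hits == 1L
}

#' @export
print.l1_insertion_sim <- function(x, ...) {
  cat(sprintf("Simulated L1 insertions: n = %d (seed %d)\n",
              nrow(x$insertions), x$seed))
  cat(sprintf("  recovered %d/%d; inversions %d; internal edits %d; flank edits %d\n",
              sum(x$insertions$recovered), nrow(x$insertions),
              sum(x$insertions$inversion),
              sum(x$insertions$n_internal_edits),
              sum(x$insertions$n_flank_edits)))
  invisible(x)
}

#' Recovered insertions from a simulation
#'
#' Insertions whose intermediate survived the repair model (`recovered`);
#' aborted intermediates are excluded here but remain in the truth tables.
#'
#' @param sim An `l1_insertion_sim`.
#' @return The `insertions` data.frame restricted to recovered events.
#' @export
recovered_insertions <- function(sim) {
  stopifnot(inherits(sim, "l1_insertion_sim"))
  sim$insertions[sim$insertions$recovered, , drop = FALSE]
}

#' Write simulated insertions (FASTA) and ground truth (TSV)
#'
#' Writes the recovered post-integration sequences as FASTA plus three truth
#' TSVs (structures, internal edits, flank edits); byte-stable.
#'
#' @param sim An `l1_insertion_sim`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_insertion_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "l1_insertion_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- recovered_insertions(sim)
  fasta <- file.path(dir, "insertions.fasta")
  write_fasta(rec$insertion_id, rec$post_sequence, fasta)
  hdr <- paste0("seed=", sim$seed)
  p1 <- file.path(dir, "truth_structures.tsv")
  write_tsv_commented(sim$insertions[, setdiff(names(sim$insertions),
                                               "post_sequence")], p1, hdr)
  p2 <- file.path(dir, "truth_internal_edits.tsv")
  write_tsv_commented(if (is.null(sim$internal_truth)) {
    data.frame(insertion_id = character(0))
  } else sim$internal_truth, p2, hdr)
  p3 <- file.path(dir, "truth_flank_edits.tsv")
  write_tsv_commented(if (is.null(sim$flank_truth)) {
    data.frame(insertion_id = character(0))
  } else sim$flank_truth, p3, hdr)
  invisible(c(fasta = fasta, structures = p1, internal = p2, flank = p3))
}
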