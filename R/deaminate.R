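#' Deaminate exposed cytosines on a single strand
#'
#' Applies the per-context deamination model to one single-strand DNA
#' molecule: each cytosine lying inside an exposed interval, and having both a
#' 5' and a 3' neighbour, is independently converted to T (representing the
#' uracil after second-strand synthesis) with probability
#' `model$p_by_context[context]`, where the context is the trinucleotide read
#' 5'->3' on this strand. Terminal cytosines (no complete context) are never
#' edited. Uses the current RNG stream; seed the caller for reproducibility.
#'
#' @param sequence_minus The single-strand sequence (conventionally the
#'   minus-strand cDNA), 5'->3'.
#' @param exposed List of 1-based inclusive `c(start, end)` intervals on the
#'   strand that are single-stranded and hence deaminable.
#' @param model A [deamination_model()].
#' @return List with `edited` (the sequence after deamination) and `edits`, a
#'   data.frame of `position` (1-based on this strand) and `context` (the
#'   trinucleotide on this strand) for every deaminated C.
#' @examples
#' m <- deamination_model(p_tca = 1, p_other = 0)
#' apply_deamination("TTCAT", list(c(1, 5)), m)$edited  # "TTTAT"
#' @export
apply_deamination <- function(sequence_minus, exposed, model) {
  stopifnot(inherits(model, "deamination_model"))
  n <- nchar(sequence_minus)
  for (iv in exposed) {
    if (iv[1] < 1L || iv[2] > n || iv[1] > iv[2])
      stop_input("exposed interval [", iv[1], ", ", iv[2],
                 "] outside sequence bounds (length ", n, ")")
  }
  pos <- base_positions(sequence_minus, "C")
  if (length(pos)) {
    inside <- rep(FALSE, length(pos))
    for (iv in exposed) inside <- inside | (pos >= iv[1] & pos <= iv[2])
    pos <- pos[inside]
  }
  ctx <- context_at(sequence_minus, pos)
  keep <- !is.na(ctx)
  pos <- pos[keep]; ctx <- ctx[keep]
  if (!length(pos)) {
    return(list(edited = sequence_minus,
                edits = data.frame(position = integer(0),
                                   context = character(0),
                                   stringsAsFactors = FALSE)))
  }
  p <- model$p_by_context[ctx]
  hit <- runif(length(pos)) < p
  edited <- sequence_minus
  if (any(hit)) {
    ch <- seq_chars(sequence_minus)
    ch[pos[hit]] <- "T"
    edited <- chars_to_seq(ch)
  }
  list(edited = edited,
       edits = data.frame(position = pos[hit], context = ctx[hit],
                          stringsAsFactors = FALSE))
}

## uniform background substitutions on a plus-strand sequence; `skip` are
## positions already altered. Returns edited sequence + data.frame of changes.
apply_background <- function(sequence_plus, background_p, skip = integer(0)) {
  n <- nchar(sequence_plus)
  if (background_p <= 0 || n == 0L) {
    return(list(edited = sequence_plus,
                changes = data.frame(position = integer(0),
                                     ref = character(0), alt = character(0),
                                     stringsAsFactors = FALSE)))
  }
  hit <- which(runif(n) < background_p)
  hit <- setdiff(hit, skip)
  if (!length(hit)) {
    return(list(edited = sequence_plus,
                changes = data.frame(position = integer(0),
                                     ref = character(0), alt = character(0),
                                     stringsAsFactors = FALSE)))
  }
  ch <- seq_chars(sequence_plus)
  ref <- ch[hit]
  alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                character(1), USE.NAMES = FALSE)
  ch[hit] <- alt
  list(edited = chars_to_seq(ch),
       changes = data.frame(position = hit, ref = ref, alt = alt,
                            stringsAsFactors = FALSE))
}

## mechanical strand classification of a plus-strand substitution
classify_substitution <- function(ref, alt) {
  out <- rep("other", length(ref))
  out[ref == "G" & alt == "A"] <- "GtoA_plus"
  out[ref == "C" & alt == "T"] <- "CtoT_plus"
  out
}
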