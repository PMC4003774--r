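#' Call substitutions from a pairwise alignment
#'
#' Emits one strand-classified call per mismatch column of the alignment.
#' Gap columns are never substitutions (indels are excluded from deamination
#' statistics and reported separately by [call_indels()]). Each call carries:
#'
#' * `position` — 1-based plus-strand reference coordinate,
#' * `ref`, `alt` — reference and query base,
#' * `strand_class` — `GtoA_plus` (plus-strand G>A, i.e. C>U on the
#'   minus-strand cDNA), `CtoT_plus` (plus-strand C>T, counted separately
#'   because deamination of the minus strand cannot produce it), or `other`,
#' * `region` — label from the supplied region map (e.g. `internal`,
#'   `tail`, `adapter`),
#' * `context_minus` — the trinucleotide around the site on the deaminated
#'   (minus) strand: the reverse complement of the plus-strand reference
#'   trinucleotide centred at `position` (NA at reference termini).
#'
#' @param aln An [align_pairwise()] result.
#' @param regions Named list of `c(start, end)` 1-based inclusive intervals on
#'   the reference (e.g. `ref$regions`); positions outside every interval get
#'   region `NA`.
#' @return data.frame of calls sorted by position.
#' @export
call_substitutions <- function(aln, regions = NULL) {
  stopifnot(inherits(aln, "l1_alignment"))
  r <- seq_chars(aln$ref_aligned)
  q <- seq_chars(aln$query_aligned)
  ref_pos <- aln$ref_offset - 1L + cumsum(r != "-")
  mm <- which(r != q & r != "-" & q != "-")
  pos <- ref_pos[mm]
  calls <- data.frame(position = as.integer(pos),
                      ref = r[mm], alt = q[mm],
                      strand_class = classify_substitution(r[mm], q[mm]),
                      region = region_label(pos, regions),
                      context_minus = revcomp(context_at(aln$ref, pos)),
                      stringsAsFactors = FALSE)
  calls[order(calls$position), , drop = FALSE]
}

#' Report indels from a pairwise alignment
#'
#' Insertions and deletions are kept out of the substitution stream; this
#' companion lists them (one row per gap run).
#'
#' @inheritParams call_substitutions
#' @return data.frame with `position` (reference base 5' of the gap), `type`
#'   (`ins`/`del`), `length`, and `sequence`.
#' @export
call_indels <- function(aln) {
  stopifnot(inherits(aln, "l1_alignment"))
  r <- seq_chars(aln$ref_aligned)
  q <- seq_chars(aln$query_aligned)
  ref_pos <- aln$ref_offset - 1L + cumsum(r != "-")
  gap <- r == "-" | q == "-"
  if (!any(gap)) {
    return(data.frame(position = integer(0), type = character(0),
                      length = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  runs <- rle(gap)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  do.call(rbind, lapply(keep, function(k) {
    i <- starts[k]:ends[k]
    is_ins <- r[i[1]] == "-"
    data.frame(position = as.integer(ref_pos[i[1]]) - as.integer(is_ins),
               type = if (is_ins) "ins" else "del",
               length = length(i),
               sequence = chars_to_seq(if (is_ins) q[i] else r[i]),
               stringsAsFactors = FALSE)
  }))
}

region_label <- function(pos, regions) {
  if (is.null(regions)) return(rep(NA_character_, length(pos)))
  out <- rep(NA_character_, length(pos))
  for (nm in names(regions)) {
    iv <- regions[[nm]]
    out[pos >= iv[1] & pos <= iv[2]] <- nm
  }
  out
}

#' Estimate the poly(A) tail length of an aligned product
#'
#' Returns the length of the uninterrupted A-run in the query starting at the
#' alignment column of `tail_anchor` (the reference position where the
#' poly(A) tract begins). Gap columns in the reference (query insertions,
#' i.e. a tail longer than the reference tract) are counted; gap columns in
#' the query are not A's and terminate the run.
#'
#' @param aln An [align_pairwise()] result.
#' @param tail_anchor 1-based reference position of the first tail base.
#' @return Integer tail length (0 if the query has no A at the anchor).
#' @export
estimate_tail_length <- function(aln, tail_anchor) {
  stopifnot(inherits(aln, "l1_alignment"))
  if (tail_anchor < aln$ref_offset || tail_anchor > aln$ref_end)
    stop_input("tail_anchor (", tail_anchor, ") outside the aligned reference",
               " span [", aln$ref_offset, ", ", aln$ref_end, "]")
  r <- seq_chars(aln$ref_aligned)
  q <- seq_chars(aln$query_aligned)
  ref_pos <- aln$ref_offset - 1L + cumsum(r != "-")
  col <- which(ref_pos == tail_anchor & r != "-")[1L]
  n <- 0L
  while (col <= length(q) && q[col] == "A") {
    n <- n + 1L
    col <- col + 1L
  }
  n
}

#' Align products and call substitutions against a reference
#'
#' Pipeline wrapper: aligns every product sequence to the reference amplicon
#' (ends-free), calls substitutions with region labels, estimates poly(A)
#' tail lengths, and records per-product aligned reference spans (the
#' coverage used as the availability denominator in context accounting).
#'
#' @param ref An [make_reference()] reference set.
#' @param products data.frame with `product_id` and `sequence` columns (as
#'   returned in `simulate_leap_products()$products` or by [read_fasta()],
#'   renaming `id` to `product_id`).
#' @return Object of class `l1_callset`: list with `calls` (data.frame with a
#'   `product_id` column prepended to the [call_substitutions()] columns),
#'   `indels`, `coverage` (data.frame `product_id`, `ref_start`, `ref_end`),
#'   and `tails` (data.frame `product_id`, `tail_length`).
#' @export
call_products <- function(ref, products) {
  stopifnot(inherits(ref, "l1_reference"))
  if (!is.null(products$id) && is.null(products$product_id))
    products$product_id <- products$id
  alns <- align_pairwise_set(ref$amplicon_plus, products$sequence)
  anchor <- ref$regions$tail[1]
  per <- lapply(seq_along(alns), function(i) {
    a <- alns[[i]]
    calls <- call_substitutions(a, ref$regions)
    if (nrow(calls))
      calls <- cbind(product_id = products$product_id[i], calls,
                     stringsAsFactors = FALSE)
    ind <- call_indels(a)
    if (nrow(ind))
      ind <- cbind(product_id = products$product_id[i], ind,
                   stringsAsFactors = FALSE)
    tl <- if (anchor >= a$ref_offset && anchor <= a$ref_end)
      estimate_tail_length(a, anchor) else NA_integer_
    list(calls = calls, indels = ind,
         cov = c(a$ref_offset, a$ref_end), tail = tl)
  })
  calls <- do.call(rbind, c(Filter(function(x) NROW(x) > 0,
                                   lapply(per, `[[`, "calls")),
                            list(empty_calls())))
  indels <- do.call(rbind, Filter(function(x) NROW(x) > 0,
                                  lapply(per, `[[`, "indels")))
  cov <- t(vapply(per, `[[`, numeric(2), "cov"))
  structure(list(calls = calls,
                 indels = indels,
                 coverage = data.frame(product_id = products$product_id,
                                       ref_start = as.integer(cov[, 1]),
                                       ref_end = as.integer(cov[, 2]),
                                       stringsAsFactors = FALSE),
                 tails = data.frame(product_id = products$product_id,
                                    tail_length = vapply(per, `[[`,
                                                         numeric(1), "tail"),
                                    stringsAsFactors = FALSE),
                 ref = ref),
            class = "l1_callset")
}

empty_calls <- function() {
  data.frame(product_id = character(0), position = integer(0),
             ref = character(0), alt = character(0),
             strand_class = character(0), region = character(0),
             context_minus = character(0), stringsAsFactors = FALSE)
}

#' @export
print.l1_callset <- function(x, ...) {
  cat(sprintf("Substitution calls: %d products, %d calls (%d G>A, %d C>T, %d other)\n",
              nrow(x$coverage), nrow(x$calls),
              sum(x$calls$strand_class == "GtoA_plus"),
              sum(x$calls$strand_class == "CtoT_plus"),
              sum(x$calls$strand_class == "other")))
  invisible(x)
}

#' Write calls as TSV (and optionally a minimal VCF)
#'
#' @param callset An [call_products()] result.
#' @param path Output TSV path.
#' @param vcf Optional path for a minimal VCF (reference = the amplicon).
#' @return Invisibly, the TSV path.
#' @export
write_calls <- function(callset, path, vcf = NULL) {
  stopifnot(inherits(callset, "l1_callset"))
  write_tsv_commented(callset$calls, path,
                      headers = "coords=1-based plus strand of reference amplicon")
  if (!is.null(vcf)) {
    con <- file(vcf, "wt")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##reference=amplicon_plus",
                 paste0("##INFO=<ID=SC,Number=1,Type=String,",
                        "Description=\"Strand class\">"),
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    cl <- callset$calls
    if (nrow(cl))
      writeLines(sprintf("amplicon\t%d\t%s\t%s\t%s\t.\t.\tSC=%s",
                         cl$position, cl$product_id, cl$ref, cl$alt,
                         cl$strand_class), con)
  }
  invisible(path)
}
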