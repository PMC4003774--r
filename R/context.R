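#' Build the G-centered trinucleotide context table
#'
#' Reproduces the deamination accounting chart: all 16 plus-strand NGN
#' trinucleotides (G centred; each corresponds to a C-centred context on the
#' first-strand cDNA by reverse complement, plus-strand 5'-TGA-3' being the
#' minus-strand 5'-TCA-3' consensus), with
#'
#' * `occurrences` — times the trinucleotide occurs in the reference region,
#' * `available` — site-product pairs actually interrogated: each occurrence
#'   counts once per product whose aligned span covers the site (so
#'   5'-truncated products do not inflate the denominator),
#' * `deaminated` — `GtoA_plus` calls observed at those sites,
#' * `percent` — `100 * deaminated / available` (NA when nothing is
#'   available; trinucleotides absent from the reference keep
#'   `occurrences = 0`, the chart's "grayed-out" rows).
#'
#' The adapter's single-strand C site is tabulated separately (it is C-centred
#' on the minus strand, context 5'-TCA-3' for the packaged adapter) and is
#' never merged into the 16 G-centred rows.
#'
#' @param ref An [make_reference()] reference set.
#' @param calls data.frame of calls with `product_id`, `position`,
#'   `strand_class` (from [call_products()] or a simulation truth table).
#' @param coverage data.frame `product_id`, `ref_start`, `ref_end` of aligned
#'   spans; defaults to full coverage for every product in `calls` — pass the
#'   real spans whenever truncations are possible.
#' @param region `"internal"` or `"adapter"` — which reference region the
#'   16-row table accounts for.
#' @param n_products Number of products interrogated (defaults to
#'   `nrow(coverage)`); required when `coverage` is defaulted and products
#'   without calls exist.
#' @return Object of class `l1_context_table`: list with `rows` (16-row
#'   data.frame), `adapter_site` (list: `position`, `available`, `deaminated`,
#'   `percent`), `region`, `n_products`.
#' @export
build_context_table <- function(ref, calls, coverage = NULL,
                                region = "internal", n_products = NULL) {
  stopifnot(inherits(ref, "l1_reference"))
  if (!region %in% names(ref$regions))
    stop_input("unknown region: ", region)
  amp <- ref$amplicon_plus
  iv <- ref$regions[[region]]

  if (is.null(coverage)) {
    ids <- unique(calls$product_id)
    if (is.null(n_products)) n_products <- length(ids)
    coverage <- data.frame(product_id = as.character(ids),
                           ref_start = rep(1L, length(ids)),
                           ref_end = rep(nchar(amp), length(ids)),
                           stringsAsFactors = FALSE)
    if (n_products > nrow(coverage)) {
      extra <- n_products - nrow(coverage)
      coverage <- rbind(coverage,
                        data.frame(product_id = sprintf("uncalled_%d",
                                                        seq_len(extra)),
                                   ref_start = 1L, ref_end = nchar(amp),
                                   stringsAsFactors = FALSE))
    }
  }
  n_products <- nrow(coverage)

  ## G sites in the region, with their plus-strand contexts
  g_pos <- base_positions(amp, "G")
  g_pos <- g_pos[g_pos >= iv[1] & g_pos <= iv[2]]
  g_ctx <- context_at(amp, g_pos)
  keep <- !is.na(g_ctx)
  g_pos <- g_pos[keep]; g_ctx <- g_ctx[keep]

  ctx16 <- trinucleotides("G")
  occurrences <- as.integer(table(factor(g_ctx, levels = ctx16)))

  ## availability: per site, number of products covering it
  avail_site <- vapply(g_pos, function(p)
    sum(coverage$ref_start <= p & coverage$ref_end >= p), numeric(1))
  available <- as.integer(rowsum_by(avail_site, g_ctx, ctx16))

  ga <- calls[calls$strand_class == "GtoA_plus" &
                calls$position %in% g_pos, , drop = FALSE]
  deam_site <- vapply(g_pos, function(p) sum(ga$position == p), numeric(1))
  deaminated <- as.integer(rowsum_by(deam_site, g_ctx, ctx16))

  percent <- ifelse(available > 0, 100 * deaminated / available,
                    ifelse(rep(nrow(coverage) == 0L, 16L), 0, NA_real_))

  rows <- data.frame(context = ctx16, occurrences = occurrences,
                     available = available, deaminated = deaminated,
                     percent = percent, stringsAsFactors = FALSE)

  ## adapter single-strand C site(s), C-centred on the minus strand
  asite <- ref$adapter_site
  a_av <- sum(vapply(asite, function(p)
    sum(coverage$ref_start <= p & coverage$ref_end >= p), numeric(1)))
  a_de <- sum(calls$strand_class == "GtoA_plus" & calls$position %in% asite)
  adapter_site <- list(position = asite,
                       context_minus = revcomp(context_at(amp, asite)),
                       available = as.integer(a_av),
                       deaminated = as.integer(a_de),
                       percent = if (a_av > 0) 100 * a_de / a_av
                                 else if (n_products == 0L) 0 else NA_real_)

  structure(list(rows = rows, adapter_site = adapter_site, region = region,
                 n_products = n_products),
            class = "l1_context_table")
}

rowsum_by <- function(x, by, levels) {
  if (!length(x)) return(setNames(rep(0, length(levels)), levels))
  s <- tapply(x, factor(by, levels = levels), sum, default = 0)
  as.numeric(s)
}

#' @export
print.l1_context_table <- function(x, ...) {
  cat(sprintf("Trinucleotide deamination accounting (%s region, %d products)\n",
              x$region, x$n_products))
  rows <- x$rows
  rows$percent <- ifelse(is.na(rows$percent), "",
                         sprintf("%.1f", rows$percent))
  print(rows, row.names = FALSE)
  a <- x$adapter_site
  cat(sprintf("Adapter single-strand C site [%s]: %d of %d deaminated (%s)\n",
              paste(a$context_minus, collapse = ","), a$deaminated,
              a$available,
              if (is.na(a$percent)) "-" else sprintf("%.1f%%", a$percent)))
  invisible(x)
}

#' Write a context table as TSV
#'
#' Mirrors the chart layout (trinucleotide, occurrences, available,
#' deaminated, percent to one decimal, blank on zero availability); the
#' adapter site is appended as a separate commented footer line.
#'
#' @param table An [build_context_table()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_context_table <- function(table, path) {
  stopifnot(inherits(table, "l1_context_table"))
  rows <- table$rows
  rows$percent <- ifelse(is.na(rows$percent), "", sprintf("%.1f", rows$percent))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# region=%s n_products=%d", table$region,
                     table$n_products), con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  a <- table$adapter_site
  writeLines(sprintf("# adapter_site\t%s\t%d\t%d\t%s",
                     paste(a$context_minus, collapse = ","), a$available,
                     a$deaminated,
                     if (is.na(a$percent)) "" else sprintf("%.1f", a$percent)),
             con)
  invisible(path)
}

#' Histogram of G>A edits per product
#'
#' @param calls data.frame with `product_id` and `strand_class`.
#' @param product_ids All product ids (so products with zero edits populate
#'   the zero bin); defaults to the ids present in `calls`.
#' @return Named integer vector: names are edit counts, values are numbers of
#'   products; always includes the `"0"` bin and sums to the number of
#'   products.
#' @export
edits_per_product_histogram <- function(calls, product_ids = NULL) {
  if (is.null(product_ids)) product_ids <- unique(calls$product_id)
  ga <- calls[calls$strand_class == "GtoA_plus", , drop = FALSE]
  counts <- table(factor(ga$product_id, levels = product_ids))
  tab <- table(as.integer(counts))
  out <- setNames(as.integer(tab), names(tab))
  if (!"0" %in% names(out)) out <- c(setNames(0L, "0"), out)
  out[order(as.integer(names(out)))]
}

#' Fingerprints of product independence
#'
#' Each sequenced product is fingerprinted by its poly(A) tail length and its
#' sorted set of edit positions; two clones of the same cDNA share both,
#' whereas independent cDNAs essentially never do.
#'
#' @param calls data.frame with `product_id`, `position`, `strand_class`.
#' @param tails data.frame `product_id`, `tail_length`.
#' @return data.frame `product_id`, `tail_length`, `edit_positions`
#'   (";"-joined sorted positions, "" if none).
#' @export
product_fingerprints <- function(calls, tails) {
  ga <- calls[calls$strand_class == "GtoA_plus", , drop = FALSE]
  ep <- vapply(tails$product_id, function(id)
    paste(sort(ga$position[ga$product_id == id]), collapse = ";"),
    character(1), USE.NAMES = FALSE)
  data.frame(product_id = tails$product_id,
             tail_length = tails$tail_length,
             edit_positions = ep, stringsAsFactors = FALSE)
}

#' Deduplicate products by independence fingerprint
#'
#' Groups products with identical (tail length, edit set) fingerprints; the
#' first member of each group is kept as the unique representative.
#'
#' @param fingerprints An [product_fingerprints()] data.frame.
#' @return List with `unique` (data.frame of first occurrences) and
#'   `collisions` (list of product-id character vectors, one per group of
#'   size >= 2).
#' @export
dedup_independent <- function(fingerprints) {
  key <- paste(fingerprints$tail_length, fingerprints$edit_positions,
               sep = "|")
  first <- !duplicated(key)
  groups <- split(fingerprints$product_id, key)
  collisions <- unname(groups[vapply(groups, length, integer(1)) >= 2L])
  ## preserve input order of collision groups
  if (length(collisions)) {
    ord <- order(vapply(collisions, function(g)
      match(g[1], fingerprints$product_id), integer(1)))
    collisions <- collisions[ord]
  }
  list(unique = fingerprints[first, , drop = FALSE], collisions = collisions)
}

#' Per-context deamination probability estimates
#'
#' Point estimate (`deaminated / available`) and 95% Wilson score interval
#' for every context row with nonzero availability, plus the adapter site.
#'
#' @param table An [build_context_table()] result.
#' @param conf.level Confidence level for the Wilson interval.
#' @return data.frame `context`, `deaminated`, `available`, `estimate`,
#'   `lower`, `upper`; the adapter site appears as context `adapter:TCA`
#'   (C-centred, minus strand).
#' @export
estimate_context_probabilities <- function(table, conf.level = 0.95) {
  stopifnot(inherits(table, "l1_context_table"))
  rows <- table$rows[table$rows$available > 0, , drop = FALSE]
  est <- lapply(seq_len(nrow(rows)), function(i) {
    ci <- wilson_ci(rows$deaminated[i], rows$available[i], conf.level)
    data.frame(context = rows$context[i],
               deaminated = rows$deaminated[i],
               available = rows$available[i],
               estimate = rows$deaminated[i] / rows$available[i],
               lower = ci[1], upper = ci[2], stringsAsFactors = FALSE)
  })
  a <- table$adapter_site
  if (a$available > 0) {
    ci <- wilson_ci(a$deaminated, a$available, conf.level)
    est <- c(est, list(data.frame(
      context = paste0("adapter:", paste(a$context_minus, collapse = ",")),
      deaminated = a$deaminated, available = a$available,
      estimate = a$deaminated / a$available,
      lower = ci[1], upper = ci[2], stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, est)
  rownames(out) <- NULL
  out
}
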