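#' Simulate LEAP cDNA products
#'
#' Generative model of the LEAP (L1 Element Amplification Protocol) assay.
#' For each product an independent poly(A) tail length is drawn, the
#' minus-strand cDNA is assembled as `adapter_unique + oligo(dT over the
#' tail) + revcomp(element segment)`, the exposure model determines which part
#' of that strand is single-stranded (adapter only, or everything when RNase H
#' is active), and exposed cytosines are deaminated per the deamination model.
#' Deaminations on the minus strand surface as G->A changes on the reported
#' plus-strand product sequence; optional background substitutions
#' (`model$background_p`) are applied uniformly on the plus strand.
#'
#' Each product uses an RNG child stream derived from `seed` by counter, so
#' product `i` is reproducible independently of how many products are drawn.
#'
#' @param ref An [make_reference()] reference set.
#' @param n Number of products (>= 1).
#' @param exposure An [exposure_model()].
#' @param deam A [deamination_model()].
#' @param structure A [structure_model()] (only the tail-length law is used).
#' @param seed Integer root seed.
#' @return An object of class `l1_leap_sim`: list with `products` (data.frame:
#'   `product_id`, `sequence`, `tail_length`, `n_edits`), `truth` (data.frame
#'   of planted changes: `product_id`, `position` (1-based on the reference
#'   amplicon plus strand), `ref`, `alt`, `strand_class`, `region`,
#'   `context_minus`), and the models used.
#' @examples
#' ref <- make_reference(seed = 7)
#' cond <- leap_condition("a3a")
#' sim <- simulate_leap_products(ref, 5, cond$exposure, cond$deam, seed = 1)
#' sim$truth
#' @export
simulate_leap_products <- function(ref, n,
                                   exposure = exposure_model(),
                                   deam = deamination_model(),
                                   structure = structure_model(),
                                   seed = 1L) {
  stopifnot(inherits(ref, "l1_reference"), n >= 1)
  seg <- ref$element
  lseg <- nchar(seg)
  adapter_unique <- ref$adapter_unique
  la <- nchar(adapter_unique)
  rc_seg <- revcomp(seg)
  rc_adapter <- revcomp(adapter_unique)
  n_amp <- nchar(ref$amplicon_plus)
  ref_tail <- ref$ref_tail_length

  ids <- sprintf("product_%05d", seq_len(n))
  tails <- integer(n)
  seqs <- character(n)
  truth <- vector("list", n)

  for (i in seq_len(n)) {
    with_seed(child_seed(seed, i), {
      tail_i <- as.integer(structure$tail_length_dist(1L))
      minus <- paste0(adapter_unique, strrep("T", tail_i), rc_seg)
      lp <- nchar(minus)
      exp_iv <- exposed_intervals_minus(exposure, lp, la)
      de <- apply_deamination(minus, exp_iv, deam)

      ## product plus strand is the reverse complement of the edited cDNA
      plus <- revcomp(de$edited)
      pos_plus <- lp - de$edits$position + 1L

      bg <- apply_background(plus, deam$background_p, skip = pos_plus)
      plus <- bg$edited

      ## map product plus positions to reference amplicon coordinates
      map_ref <- function(p) {
        ifelse(p <= lseg, p,
               ifelse(p <= lseg + tail_i,
                      lseg + pmin.int(p - lseg, ref_tail),
                      p - tail_i + ref_tail))
      }
      region_of <- function(p) {
        ifelse(p <= lseg, "internal",
               ifelse(p <= lseg + tail_i, "tail", "adapter"))
      }

      rows <- list()
      if (nrow(de$edits)) {
        rp <- map_ref(pos_plus)
        rows[[1L]] <- data.frame(
          product_id = ids[i], position = as.integer(rp),
          ref = "G", alt = "A", strand_class = "GtoA_plus",
          region = region_of(pos_plus),
          context_minus = de$edits$context,
          stringsAsFactors = FALSE)
      }
      if (nrow(bg$changes)) {
        bp <- bg$changes$position
        rp <- map_ref(bp)
        rows[[2L]] <- data.frame(
          product_id = ids[i], position = as.integer(rp),
          ref = bg$changes$ref, alt = bg$changes$alt,
          strand_class = classify_substitution(bg$changes$ref, bg$changes$alt),
          region = region_of(bp),
          context_minus = revcomp(context_at(ref$amplicon_plus,
                                             as.integer(rp))),
          stringsAsFactors = FALSE)
      }
      tails[i] <- tail_i
      seqs[i] <- plus
      truth[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
    })
  }

  truth <- do.call(rbind, c(truth[!vapply(truth, is.null, logical(1))],
                            list(empty_truth())))
  truth <- truth[order(match(truth$product_id, ids), truth$position), ,
                 drop = FALSE]
  rownames(truth) <- NULL
  n_edits <- as.integer(table(factor(
    truth$product_id[truth$strand_class == "GtoA_plus"], levels = ids)))

  structure(list(products = data.frame(product_id = ids, sequence = seqs,
                                       tail_length = tails, n_edits = n_edits,
                                       stringsAsFactors = FALSE),
                 truth = truth, ref = ref, exposure = exposure, deam = deam,
                 structure = structure, seed = as.integer(seed)),
            class = "l1_leap_sim")
}

empty_truth <- function() {
  data.frame(product_id = character(0), position = integer(0),
             ref = character(0), alt = character(0),
             strand_class = character(0), region = character(0),
             context_minus = character(0), stringsAsFactors = FALSE)
}

#' @export
print.l1_leap_sim <- function(x, ...) {
  cat(sprintf("Simulated LEAP products: n = %d (seed %d)\n",
              nrow(x$products), x$seed))
  cat(sprintf("  RNase H %s; p(TCA) = %.3g; background %.3g\n",
              if (x$exposure$rnase_h_active) "on" else "off",
              x$deam$p_by_context[["TCA"]], x$deam$background_p))
  cat(sprintf("  planted changes: %d (%d G>A)\n", nrow(x$truth),
              sum(x$truth$strand_class == "GtoA_plus")))
  invisible(x)
}

#' Write simulated products (FASTA) and ground truth (TSV)
#'
#' The FASTA id line carries the tail length (`>product_00001 tail=32`); the
#' truth TSV starts with comment headers recording the seed. Output is
#' byte-stable: identical simulations give identical files.
#'
#' @param sim An `l1_leap_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (named `fasta`, `truth`).
#' @export
write_leap_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "l1_leap_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "products.fasta")
  writeLines(paste0(">", sim$products$product_id, " tail=",
                    sim$products$tail_length, "\n", sim$products$sequence),
             fasta)
  truth <- file.path(dir, "truth_products.tsv")
  write_tsv_commented(sim$truth, truth,
                      headers = c(paste0("seed=", sim$seed),
                                  "coords=1-based plus strand of reference amplicon"))
  invisible(c(fasta = fasta, truth = truth))
}
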