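#' @importFrom stats rbinom runif sd setNames prop.test
#' @importFrom utils write.table read.table packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

## character-vector view of a sequence string (uppercase assumed)
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

chars_to_seq <- function(x) paste0(x, collapse = "")

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement; input must be A/C/G/T (plus N, which
#' maps to N).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("TCA")  # "TGA"
#' @export
revcomp <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  comp <- chartr("ACGTN", "TGCAN", x[ok])
  out[ok] <- vapply(comp, function(s) chars_to_seq(rev(seq_chars(s))),
                    character(1), USE.NAMES = FALSE)
  out
}

## per-character complement (no reversal)
chartr_vec <- function(ch) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch])
}

is_dna <- function(x) {
  nzchar(x) && !grepl("[^ACGT]", x)
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("l1deam_input_error", "error")))
}

## run code under a given seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## deterministic per-item child seed derived from a root seed by counter, so
## that item i's draws never depend on how many items precede it
child_seed <- function(root, i) {
  as.integer((as.double(root %% 1000003L) * 69621 + i * 181 + 7) %% 2147483587)
}

## all 16 trinucleotides with a fixed middle base, lexicographic flank order
trinucleotides <- function(middle) {
  as.vector(t(outer(DNA_BASES, DNA_BASES,
                    function(a, b) paste0(a, middle, b))))
}

## positions (1-based) of `base` in a sequence string
base_positions <- function(seq, base) {
  which(seq_chars(seq) == base)
}

## trinucleotide context around position i (NA at the termini)
context_at <- function(seq, i) {
  n <- nchar(seq)
  out <- rep(NA_character_, length(i))
  ok <- which(i > 1L & i < n)
  if (length(ok)) out[ok] <- substring(seq, i[ok] - 1L, i[ok] + 1L)
  out
}

## Wilson score interval via prop.test (no continuity correction)
wilson_ci <- function(x, n, conf.level = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  if (x == 0L || x == n) {
    ## prop.test handles the boundary, but keep the exact bound at 0/1
    ci <- stats::prop.test(x, n, conf.level = conf.level,
                           correct = FALSE)$conf.int
    if (x == 0L) ci[1] <- 0
    if (x == n) ci[2] <- 1
    return(as.numeric(ci))
  }
  as.numeric(stats::prop.test(x, n, conf.level = conf.level,
                              correct = FALSE)$conf.int)
}
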