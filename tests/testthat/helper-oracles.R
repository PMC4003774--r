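## Independent oracles and small generators used across the suite.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Ends-free (overlap) affine-gap alignment score by straightforward Gotoh
## dynamic programming: an implementation independent of the package's
## alignment engine, for tiny sequences only.
dp_overlap_score <- function(x, y, match = 1, mismatch = -1,
                             open = 3, ext = 1) {
  a <- strsplit(x, "")[[1]]
  b <- strsplit(y, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  X[, 1] <- 0            # free leading gap in y
  Y[1, ] <- 0            # free leading gap in x
  for (i in 1:n) for (j in 1:m) {
    s <- if (a[i] == b[j]) match else mismatch
    M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  max(M[n + 1, ], X[n + 1, ], Y[n + 1, ], M[, m + 1], X[, m + 1], Y[, m + 1])
}

## Brute-force position-by-position substitution comparison for equal-length
## indel-free pairs.
brute_force_subs <- function(ref, query) {
  r <- strsplit(ref, "")[[1]]
  q <- strsplit(query, "")[[1]]
  stopifnot(length(r) == length(q))
  i <- which(r != q)
  data.frame(position = i, ref = r[i], alt = q[i], stringsAsFactors = FALSE)
}

## A mutated copy of `ref` with substitutions confined to positions 3..L-2
## and spaced at least 4 apart: under the ends-free alignment convention a
## terminal (or next-to-terminal) mismatch is indistinguishable from an
## overhang, and dense clusters admit equally scoring gapped alignments, so
## sparse interior placement is the identifiable regime.
mutate_interior <- function(ref, rate = 0.15) {
  ch <- strsplit(ref, "")[[1]]
  L <- length(ch)
  idx <- which(runif(L) < rate)
  idx <- idx[idx >= 3 & idx <= L - 2]
  keep <- integer(0)
  for (i in idx) if (!length(keep) || i - keep[length(keep)] >= 4)
    keep <- c(keep, i)
  for (i in keep) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

## shared small fixture: one reference used by many tests
test_ref <- function() make_reference(element_length = 300, seed = 7)
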