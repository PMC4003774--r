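test_that("identity and single-mismatch alignments behave as expected", {
  a <- align_pairwise("ACGTGAC", "ACGTGAC")
  expect_equal(a$score, 7)
  expect_false(grepl("-", a$ref_aligned, fixed = TRUE))
  expect_false(grepl("-", a$query_aligned, fixed = TRUE))
  expect_equal(nrow(call_substitutions(a)), 0L)

  b <- align_pairwise("ACGTGAC", "ACATGAC")
  calls <- call_substitutions(b)
  expect_equal(calls$position, 3L)
  expect_equal(calls$ref, "G")
  expect_equal(calls$alt, "A")
  expect_equal(calls$strand_class, "GtoA_plus")
})

test_that("5' truncated queries get a free leading gap", {
  a <- align_pairwise("AAAAAACGT", "ACGT")
  expect_equal(a$ref_offset, 6L)
  expect_equal(nrow(call_substitutions(a)), 0L)
  expect_equal(a$score, 4)
})

test_that("alignment scores match an exhaustive dynamic-programming oracle", {
  set.seed(202)
  for (k in 1:300) {
    x <- rand_dna(sample(3:10, 1))
    y <- rand_dna(sample(3:10, 1))
    expect_equal(align_pairwise(x, y)$score, dp_overlap_score(x, y),
                 info = paste(x, y))
  }
})

test_that("calls on indel-free pairs match brute-force comparison exactly", {
  set.seed(303)
  n_checked <- 0L
  for (k in 1:1000) {
    L <- sample(8:30, 1)
    ref <- rand_dna(L)
    query <- mutate_interior(ref, rate = 0.15)
    a <- align_pairwise(ref, query)
    got <- call_substitutions(a)
    want <- brute_force_subs(ref, query)
    expect_equal(got$position, want$position, info = paste(ref, query))
    expect_equal(got$ref, want$ref, info = paste(ref, query))
    expect_equal(got$alt, want$alt, info = paste(ref, query))
    n_checked <- n_checked + nrow(want)
  }
  expect_gt(n_checked, 1000L)   # the pairs really contained substitutions
})

test_that("strand bookkeeping: context_minus is the reverse complement of the plus context", {
  ref <- test_ref()
  cond <- leap_condition("a3a_rnaseh")
  sim <- simulate_leap_products(ref, 50, cond$exposure, cond$deam, seed = 21)
  cs <- call_products(ref, sim$products)
  expect_gt(nrow(cs$calls), 0L)
  plus_ctx <- substring(ref$amplicon_plus, cs$calls$position - 1L,
                        cs$calls$position + 1L)
  expect_equal(cs$calls$context_minus, revcomp(plus_ctx))
})

test_that("calls from simulated products equal the generator truth (round trip)", {
  ref <- test_ref()
  cond <- leap_condition("a3a_rnaseh")
  sim <- simulate_leap_products(ref, 100, cond$exposure, cond$deam, seed = 5)
  cs <- call_products(ref, sim$products)
  key <- function(df) paste(df$product_id, df$position, df$ref, df$alt,
                            df$strand_class)
  expect_identical(sort(key(cs$calls)), sort(key(sim$truth)))
  ## and the estimated tails equal the drawn tails
  expect_equal(cs$tails$tail_length, sim$products$tail_length)
})

test_that("poly(A) tail length is read off the alignment at the anchor", {
  ref <- test_ref()
  seg <- ref$element
  rc_adapter <- revcomp(ref$adapter_unique)
  anchor <- ref$regions$tail[1]

  q25 <- paste0(seg, strrep("A", 25), rc_adapter)
  expect_equal(estimate_tail_length(align_pairwise(ref$amplicon_plus, q25),
                                    anchor), 25L)
  q12 <- paste0(seg, strrep("A", 12), rc_adapter)
  expect_equal(estimate_tail_length(align_pairwise(ref$amplicon_plus, q12),
                                    anchor), 12L)
  ## anchor outside the aligned span errors
  a_trunc <- align_pairwise(ref$amplicon_plus,
                            substring(ref$amplicon_plus, anchor + 40L))
  expect_error(estimate_tail_length(a_trunc, anchor),
               class = "l1deam_input_error")
})

test_that("a query with no A at the anchor has tail length zero", {
  ref <- "CCGCAAAAAAGGTG"
  query <- "CCGCGGTG"         # tail deleted entirely
  a <- align_pairwise(ref, query)
  expect_equal(estimate_tail_length(a, 5), 0L)
})

test_that("indels are reported separately and never as substitutions", {
  ref <- "ATGCAGTTCGACAT"
  query_del <- paste0(substring(ref, 1, 5), substring(ref, 9))
  a <- align_pairwise(ref, query_del)
  expect_equal(nrow(call_substitutions(a)), 0L)
  ind <- call_indels(a)
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$type, "del")
  expect_equal(ind$length, 3L)
  expect_equal(ind$sequence, "GTT")
})
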