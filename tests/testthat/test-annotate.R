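## small constructed scenario: 60-bp locus, 120-bp "element"
make_toy <- function(seed = 1, elen = 120, llen = 400) {
  set.seed(seed)
  element <- rand_dna(elen)
  ## pin the element 3' terminus as the generator does
  element <- paste0(substring(element, 1, elen - 1), "C")
  locus <- rand_dna(llen)
  list(element = element, locus = locus)
}

## generator-style geometry: the TSD is the locus segment at the insertion
## point, duplicated around the insert. Junction-adjacent bases are chosen so
## the planted structure is identifiable (as the generator guarantees).
build_insertion <- function(locus, element, ip, tsd_len, insert,
                            tail = 18L) {
  tsd <- substring(locus, ip, ip + tsd_len - 1L)
  post <- paste0(substring(locus, 1, ip - 1L), tsd, insert,
                 strrep("A", tail), tsd, substring(locus, ip + tsd_len))
  list(pre = locus, post = post, tsd = tsd)
}

## an insertion point whose 5' neighbour is a pyrimidine (locus convention)
clean_ip <- function(locus, from = 150) {
  ip <- from
  while (!substring(locus, ip - 1, ip - 1) %in% c("C", "T")) ip <- ip + 1
  ip
}

## a truncation whose first retained base cannot be confused with the base
## following the TSD in the pre-integration locus
clean_trunc <- function(element, locus, ip, tsd_len, from = 41) {
  t <- from
  while (l1deam:::junction_ambiguous(
    substring(locus, ip + tsd_len, ip + tsd_len),
    substring(element, t, t))) t <- t + 1
  t
}

test_that("a simple truncated insertion maps to a single forward segment", {
  toy <- make_toy(2)
  ip <- clean_ip(toy$locus)
  trunc <- clean_trunc(toy$element, toy$locus, ip, 8)
  b <- build_insertion(toy$locus, toy$element, ip, 8,
                       substring(toy$element, trunc))
  m <- map_insertion(b$pre, b$post, toy$element)
  expect_false(m$inversion)
  expect_equal(m$truncation_point, trunc)
  expect_equal(m$poly_a_length, 18L)
  expect_equal(nrow(m$segments), 1L)
  expect_equal(m$segments$orientation, "+")
  expect_equal(m$flank$left_end, ip + 7L)
})

test_that("a twin-priming structure yields two segments and the junction", {
  toy <- make_toy(5)
  ip <- clean_ip(toy$locus)
  ## inverted element[a..b], deletion, forward element[cstart..end]; pick a
  ## configuration with unambiguous junctions
  found <- FALSE
  for (a in 31:60) {
    b <- a + 24; cstart <- b + 6
    insert <- paste0(revcomp(substring(toy$element, a, b)),
                     substring(toy$element, cstart))
    if (l1deam:::junction_ambiguous(
      substring(toy$locus, ip + 8, ip + 8), substring(insert, 1, 1))) next
    if (l1deam:::junction_ambiguous(
      substring(toy$element, cstart - 1, cstart - 1),
      substring(insert, 25, 25))) next   # last inverted base vs junction
    if (!l1deam:::unique_revcomp_placement(toy$element, a, b)) next
    found <- TRUE
    break
  }
  expect_true(found)
  bb <- build_insertion(toy$locus, toy$element, ip, 8, insert, tail = 25L)
  m <- map_insertion(bb$pre, bb$post, toy$element)
  expect_true(m$inversion)
  expect_equal(m$truncation_point, a)
  expect_equal(m$segments$element_start, c(a, cstart))
  expect_equal(m$segments$element_end, c(b, nchar(toy$element)))
  expect_equal(m$segments$orientation, c("-", "+"))
  expect_equal(m$junction_insert, b - a + 2L)
})

test_that("an unchanged locus is an annotation error", {
  toy <- make_toy(3)
  expect_error(map_insertion(toy$locus, toy$locus, toy$element),
               class = "l1deam_annotation_error")
})

test_that("planted TSDs are detected exactly, with and without edits", {
  toy <- make_toy(7)
  set.seed(17)
  ## controlled flanks: the bases abutting the TSD copies cannot extend a
  ## duplication or be mistaken for edits
  left <- paste0(rand_dna(150), "CCGT")
  right <- paste0("CTGG", rand_dna(150))
  trunc <- 41
  while (substring(toy$element, trunc, trunc) %in% c("C", "T"))
    trunc <- trunc + 1   # first insert base distinct from right flank's C
  insert <- substring(toy$element, trunc)
  build <- function(tsd0, tsd5, tsd3) {
    list(pre = paste0(left, tsd0, right),
         post = paste0(left, tsd5, insert, strrep("A", 20), tsd3, right))
  }

  b1 <- build("ACCTGA", "ACCTGA", "ACCTGA")
  t1 <- detect_tsd(b1$pre, b1$post, toy$element)
  expect_equal(t1$length, 6L)
  expect_equal(t1$status, "exact")
  expect_equal(t1$tsd5, "ACCTGA")

  ## a 5'-flank deamination: the pre-integration TSD carries a C at offset 4
  ## that reads T in the 5' copy (and stays C in the 3' copy)
  b2 <- build("ACCCGA", "ACCTGA", "ACCCGA")
  t2 <- detect_tsd(b2$pre, b2$post, toy$element)
  expect_equal(t2$length, 6L)
  expect_equal(t2$status, "inexact")
  expect_equal(t2$mismatches$offset, 4L)
  expect_equal(t2$mismatches$base5, "T")
  expect_equal(t2$mismatches$base3, "C")
  expect_equal(t2$mismatches$attribution, "five_prime_top_strand_deamination")
})

test_that("mismatched TSD copies are attributed by the strand rules", {
  expect_equal(classify_tsd_mismatch("T", "C"),
               "five_prime_top_strand_deamination")
  expect_equal(classify_tsd_mismatch("G", "A"),
               "three_prime_bottom_strand_deamination")
  expect_equal(classify_tsd_mismatch("A", "C"), "unexplained")
  expect_equal(classify_tsd_mismatch("C", "T"), "unexplained")
})

test_that("absent duplications give empty TSDs", {
  toy <- make_toy(9)
  ## deliberately dissimilar flanks: left ends in a T-run, right starts with a
  ## G-run, so no suffix/prefix duplication of any length exists
  left <- paste0(rand_dna(180), "CATTTTT")
  right <- paste0("GGGGGAC", rand_dna(180))
  pre <- paste0(left, right)
  trunc <- regexpr("C", substring(toy$element, 41, 80))[1] + 40L  # starts on C
  post <- paste0(left, substring(toy$element, trunc), strrep("A", 15), right)
  m <- map_insertion(pre, post, toy$element)
  expect_equal(m$truncation_point, trunc)
  td <- detect_tsd(pre, post, toy$element, mapping = m)
  expect_equal(td$length, 0L)
  expect_equal(td$tsd5, "")
  expect_equal(td$tsd3, "")
  expect_equal(td$status, "exact")
})

test_that("coding consequences follow the standard genetic code", {
  element <- "TGGCTGAAA"   # codons TGG | CTG | AAA
  orf <- list(c(1, 9))
  expect_equal(annotate_coding_consequence(2, "G", "A", element, orf),
               "nonsense")   # TGG -> TAG, stop gained
  expect_equal(annotate_coding_consequence(6, "G", "A", element, orf),
               "silent")     # CTG -> CTA, still Leu
  expect_equal(annotate_coding_consequence(4, "C", "A", element, orf),
               "missense")   # CTG -> ATG, Leu -> Met
  expect_equal(annotate_coding_consequence(2, "G", "A", element, list()),
               "noncoding")
})

test_that("consequence classes partition the internal calls", {
  ref <- test_ref()
  deam <- deamination_model(p_tca = 0.38, p_other = 0.042)
  sim <- simulate_insertions(ref, 60, deam, repair_model(ugi_active = TRUE),
                             seed = 71)
  anns <- annotate_insertions(sim)
  for (a in anns) {
    cons <- a$internal_calls$consequence
    expect_true(all(cons %in% c("noncoding", "silent", "missense",
                                "nonsense")))
    expect_equal(length(cons), nrow(a$internal_calls))
  }
})

test_that("annotation recovers planted structures exactly (round trip)", {
  ref <- test_ref()
  deam <- deamination_model(p_tca = 0.38, p_other = 0.042)
  sim <- simulate_insertions(ref, 150, deam, repair_model(ugi_active = TRUE),
                             seed = 72)
  anns <- annotate_insertions(sim)
  rec <- recovered_insertions(sim)
  for (i in seq_len(nrow(rec))) {
    a <- anns[[rec$insertion_id[i]]]
    expect_equal(a$truncation_point, rec$truncation_point[i])
    expect_equal(a$inversion, rec$inversion[i])
    expect_equal(a$tsd_length, rec$tsd_length[i])
    expect_equal(a$tsd5, rec$tsd5[i])
    if (rec$inversion[i]) {
      expect_equal(a$segments$element_start[1], rec$inv_start[i])
      expect_equal(a$segments$element_end[1], rec$inv_end[i])
      expect_equal(a$segments$element_start[2], rec$fwd_start[i])
    }
    ## internal calls equal the generator truth
    tt <- sim$internal_truth[sim$internal_truth$insertion_id ==
                               rec$insertion_id[i], , drop = FALSE]
    expect_equal(sort(a$internal_calls$element_position),
                 sort(tt$element_position))
  }
})

test_that("flank-edit attributions are sound: unexposed strands get no blame", {
  ref <- test_ref()
  deam <- deamination_model(p_tca = 0.6, p_other = 0.1)
  expo5 <- exposure_model(rnase_h_active = FALSE, flank5_top_exposed = TRUE)
  sim <- simulate_insertions(ref, 120, deam, repair_model(ugi_active = TRUE),
                             exposure = expo5, seed = 73)
  anns <- annotate_insertions(sim)
  attrs <- unlist(lapply(anns, function(a) a$tsd_mismatches$attribution))
  expect_gt(length(attrs), 0L)
  expect_true(all(attrs == "five_prime_top_strand_deamination"))
})
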