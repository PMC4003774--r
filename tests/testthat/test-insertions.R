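test_that("UGI retains every planted cDNA edit in recovered insertions", {
  ref <- test_ref()
  deam <- deamination_model(p_tca = 1, p_other = 0)
  sim <- simulate_insertions(ref, 30, deam, repair_model(ugi_active = TRUE),
                             seed = 61)
  expect_true(all(sim$insertions$recovered))
  ## with p(TCA)=1, every retained TGA site on the insert plus strand (and
  ## TCA site read on the minus strand of the inverted part) is edited:
  ## recompute k per insertion from the structure
  for (i in seq_len(nrow(sim$insertions))) {
    row <- sim$insertions[i, ]
    ins <- sim$internal_truth[sim$internal_truth$insertion_id ==
                                row$insertion_id, , drop = FALSE]
    ## reconstruct the unedited insert and count its minus-strand TCA sites
    if (row$inversion) {
      elem_part <- paste0(revcomp(substring(ref$element, row$inv_start,
                                            row$inv_end)),
                          substring(ref$element, row$fwd_start,
                                    nchar(ref$element)))
    } else {
      elem_part <- substring(ref$element, row$truncation_point,
                             nchar(ref$element))
    }
    minus <- revcomp(paste0(elem_part, strrep("A", row$tail_length)))
    k <- sum(scan_cytidines(minus)$is_tca)
    expect_equal(nrow(ins), k, info = row$insertion_id)
  }
})

test_that("UNG with certain abort recovers only edit-free insertions", {
  ref <- test_ref()
  deam <- deamination_model(p_tca = 0.38, p_other = 0.042)
  sim <- simulate_insertions(ref, 100, deam,
                             repair_model(ung_active = TRUE, p_restore = 0,
                                          p_abort = 1), seed = 62)
  rec <- recovered_insertions(sim)
  expect_gt(nrow(rec), 0L)
  expect_lt(nrow(rec), 100L)               # deaminated intermediates died
  expect_true(all(rec$n_internal_edits == 0L))
  expect_true(all(rec$n_flank_edits == 0L))
})

test_that("certain restoration repairs every edit but keeps every insertion", {
  ref <- test_ref()
  deam <- deamination_model(p_tca = 0.38, p_other = 0.042)
  sim <- simulate_insertions(ref, 100, deam,
                             repair_model(ung_active = TRUE, p_restore = 1,
                                          p_abort = 0), seed = 63)
  expect_true(all(sim$insertions$recovered))
  expect_true(all(sim$insertions$n_internal_edits == 0L))
})

test_that("recovery rate decreases monotonically with deamination probability", {
  ref <- test_ref()
  rates <- sapply(c(0.05, 0.2, 0.5, 0.9), function(p) {
    sim <- simulate_insertions(ref, 150, deamination_model(p_tca = p,
                                                           p_other = p),
                               repair_model(ung_active = TRUE,
                                            p_restore = 0.3, p_abort = 0.4),
                               seed = 64)   # common random numbers
    mean(sim$insertions$recovered)
  })
  expect_true(all(diff(rates) <= 0))
  expect_lt(rates[4], rates[1])
})

test_that("a forced 5'-flank edit leaves a single C>T difference between the TSD copies", {
  ## choose an insertion point whose duplicated target segment carries exactly
  ## one top-strand TCA site over every admissible TSD length (8..20)
  base <- make_reference(element_length = 300, seed = 7)
  locus <- base$genomic_locus
  ip_ok <- NA
  for (x in 100:900) {
    if (!substring(locus, x - 1, x - 1) %in% c("C", "T")) next
    sc <- scan_cytidines(substring(locus, x - 1, x + 20))
    tca_off <- sc$position[sc$is_tca] - 1L       # offsets within the TSD
    if (length(tca_off) == 1L && tca_off >= 2 && tca_off <= 7) {
      ip_ok <- x; break
    }
  }
  expect_false(is.na(ip_ok))
  ref <- make_reference(element_length = 300, seed = 7,
                        insertion_point = ip_ok)
  deam1 <- deamination_model(p_tca = 1, p_other = 0)
  expo <- exposure_model(rnase_h_active = FALSE, flank5_top_exposed = TRUE)
  sim <- simulate_insertions(ref, 5, deam1, repair_model(ugi_active = TRUE),
                             exposure = expo, seed = 3)
  for (i in 1:5) {
    row <- sim$insertions[i, ]
    tsd_ref <- substring(locus, ip_ok, ip_ok + row$tsd_length - 1L)
    expect_equal(row$tsd3, tsd_ref)               # 3' copy untouched
    diff_pos <- which(strsplit(row$tsd5, "")[[1]] !=
                        strsplit(row$tsd3, "")[[1]])
    expect_length(diff_pos, 1L)
    expect_equal(substring(row$tsd5, diff_pos, diff_pos), "T")
    expect_equal(substring(row$tsd3, diff_pos, diff_pos), "C")
  }
})

test_that("insertion simulation is seed-deterministic and write output is byte-stable", {
  ref <- test_ref()
  deam <- deamination_model(p_tca = 0.38, p_other = 0.042)
  s1 <- simulate_insertions(ref, 20, deam, repair_model(ugi_active = TRUE),
                            seed = 66)
  s2 <- simulate_insertions(ref, 20, deam, repair_model(ugi_active = TRUE),
                            seed = 66)
  expect_identical(s1$insertions, s2$insertions)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_insertion_sim(s1, d1)
  p2 <- write_insertion_sim(s2, d2)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
})
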