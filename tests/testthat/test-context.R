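test_that("the context table always has the 16 G-centred rows", {
  ref <- test_ref()
  tab <- build_context_table(ref, l1deam:::empty_calls(), n_products = 0)
  expect_equal(nrow(tab$rows), 16L)
  expect_true(all(grepl("^[ACGT]G[ACGT]$", tab$rows$context)))
  expect_true(all(tab$rows$available == 0))
  expect_true(all(tab$rows$percent == 0))   # zero products: percents are 0
})

test_that("planted edits at known sites give the exact percent", {
  ## a tiny hand-built reference region with exactly 2 plus-strand TGA sites
  ref <- test_ref()
  amp <- ref$amplicon_plus
  g_pos <- which(strsplit(ref$element, "")[[1]] == "G")
  ctx <- substring(ref$element, g_pos - 1, g_pos + 1)
  tga <- g_pos[ctx == "TGA" & g_pos > 1 & g_pos < nchar(ref$element)]
  expect_gte(length(tga), 2L)
  sites <- tga[1:2]

  ## 10 full-coverage products, edits planted at 7 of the 20 site-product pairs
  ids <- sprintf("p%02d", 1:10)
  planted <- data.frame(
    product_id = c(ids[1:4], ids[1:3]),
    position = c(rep(sites[1], 4), rep(sites[2], 3)),
    ref = "G", alt = "A", strand_class = "GtoA_plus",
    region = "internal", context_minus = "TCA",
    stringsAsFactors = FALSE)
  coverage <- data.frame(product_id = ids, ref_start = 1,
                         ref_end = nchar(amp), stringsAsFactors = FALSE)
  tab <- build_context_table(ref, planted, coverage)
  row <- tab$rows[tab$rows$context == "TGA", ]
  n_tga_sites <- sum(ctx == "TGA" & g_pos > 1 & g_pos < nchar(ref$element))
  expect_equal(row$occurrences, n_tga_sites)
  expect_equal(row$available, 10L * n_tga_sites)
  expect_equal(row$deaminated, 7L)

  ## with coverage restricted to the two planted sites only, the percent is
  ## exactly 7/20
  tab2 <- build_context_table(
    ref, planted,
    data.frame(product_id = ids, ref_start = min(sites) - 1,
               ref_end = max(sites) + 1, stringsAsFactors = FALSE))
  row2 <- tab2$rows[tab2$rows$context == "TGA", ]
  expect_equal(row2$available, 20L)
  expect_equal(row2$deaminated, 7L)
  expect_equal(row2$percent, 35.0)
})

test_that("availability counts only products whose aligned span covers a site", {
  ref <- test_ref()
  site <- ref$adapter_site
  coverage <- data.frame(product_id = c("a", "b", "c"),
                         ref_start = c(1, 1, 1),
                         ref_end = c(nchar(ref$amplicon_plus), site - 1, site),
                         stringsAsFactors = FALSE)
  tab <- build_context_table(ref, l1deam:::empty_calls(), coverage,
                             region = "adapter")
  expect_equal(tab$adapter_site$available, 2L)  # product b stops short
})

test_that("deaminated counts are conserved across rows", {
  ref <- test_ref()
  cond <- leap_condition("a3a_rnaseh")
  sim <- simulate_leap_products(ref, 100, cond$exposure, cond$deam, seed = 31)
  cs <- call_products(ref, sim$products)
  tab <- build_context_table(ref, cs$calls, cs$coverage)
  internal_ga <- sum(cs$calls$strand_class == "GtoA_plus" &
                       cs$calls$region == "internal" &
                       cs$calls$position > 1)
  expect_equal(sum(tab$rows$deaminated), internal_ga)
})

test_that("raising one context probability never lowers its deaminated count", {
  ref <- test_ref()
  counts <- sapply(c(0.1, 0.3, 0.6, 0.9), function(p) {
    deam <- deamination_model(p_tca = p, p_other = 0.042)
    sim <- simulate_leap_products(ref, 50, exposure_model(TRUE), deam,
                                  seed = 77)   # common random numbers
    tab <- build_context_table(ref, sim$truth, n_products = 50)
    tab$rows$deaminated[tab$rows$context == "TGA"]
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("the edits-per-product histogram includes the zero bin and sums to n", {
  calls <- data.frame(product_id = c("p3", "p3"), position = c(5L, 9L),
                      strand_class = "GtoA_plus", stringsAsFactors = FALSE)
  h <- edits_per_product_histogram(calls, product_ids = c("p1", "p2", "p3"))
  expect_equal(h, c("0" = 2L, "2" = 1L))
  expect_equal(sum(h), 3L)

  h0 <- edits_per_product_histogram(
    data.frame(product_id = character(0), strand_class = character(0)),
    product_ids = sprintf("p%d", 1:100))
  expect_equal(h0, c("0" = 100L))
})

test_that("the single-site histogram matches the binomial law", {
  ref <- test_ref()
  deam <- deamination_model(p_tca = 0.4, p_other = 0)
  sim <- simulate_leap_products(ref, 10000,
                                exposure_model(rnase_h_active = FALSE),
                                deam, seed = 41)
  h <- edits_per_product_histogram(sim$truth,
                                   product_ids = sim$products$product_id)
  frac1 <- (h[["1"]]) / 10000
  se <- sqrt(0.4 * 0.6 / 10000)
  expect_lt(abs(frac1 - 0.4), 3 * se)
})

test_that("independence deduplication groups identical fingerprints only", {
  fp <- data.frame(product_id = c("a", "b", "c", "d"),
                   tail_length = c(20, 20, 31, 20),
                   edit_positions = c("5;9", "5;9", "5;9", "5"),
                   stringsAsFactors = FALSE)
  dd <- dedup_independent(fp)
  expect_equal(dd$unique$product_id, c("a", "c", "d"))
  expect_equal(dd$collisions, list(c("a", "b")))

  ## same edit set, different tails: both retained
  fp2 <- fp[c(1, 3), ]
  dd2 <- dedup_independent(fp2)
  expect_equal(nrow(dd2$unique), 2L)
  expect_length(dd2$collisions, 0L)

  ## all distinct
  fp3 <- data.frame(product_id = c("x", "y"), tail_length = c(1, 2),
                    edit_positions = c("", ""), stringsAsFactors = FALSE)
  expect_length(dedup_independent(fp3)$collisions, 0L)
})

test_that("probability estimates reproduce the printed ratios with Wilson CIs", {
  est <- function(x, n) {
    ref <- test_ref()
    tab <- build_context_table(ref, l1deam:::empty_calls(), n_products = 0)
    tab$rows$available[tab$rows$context == "TGA"] <- n
    tab$rows$deaminated[tab$rows$context == "TGA"] <- x
    out <- estimate_context_probabilities(tab)
    out[out$context == "TGA", ]
  }
  e1 <- est(91L, 100L)
  expect_equal(e1$estimate, 0.91)
  e2 <- est(228L, 600L)
  expect_equal(e2$estimate, 0.38)
  e3 <- est(0L, 50L)
  expect_equal(e3$estimate, 0)
  expect_equal(e3$lower, 0)
  ## Wilson interval cross-check against prop.test
  ci <- prop.test(91, 100, correct = FALSE)$conf.int
  expect_equal(c(e1$lower, e1$upper), as.numeric(ci))
})

test_that("the fitted model object supports the standard methods", {
  ref <- test_ref()
  cond <- leap_condition("a3a_rnaseh")
  sim <- simulate_leap_products(ref, 100, cond$exposure, cond$deam, seed = 55)
  fit <- deamination_fit(ref, sim$truth, n_products = 100)
  expect_s3_class(fit, "deam_fit")
  co <- coef(fit)
  expect_true("TGA" %in% names(co))
  expect_gt(co[["TGA"]], 0.2)
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= co[rownames(ci)] + 1e-12))
  expect_true(all(ci[, 2] >= co[rownames(ci)] - 1e-12))
  pred <- predict(fit)
  expect_equal(pred, unname(co[fit$estimates$context] *
                              fit$estimates$available))
  res <- residuals(fit)
  expect_true(all(abs(res) < 1e-8))  # saturated binomial fit
  sim2 <- simulate(fit, nsim = 10, seed = 2)
  expect_s3_class(sim2, "l1_leap_sim")
  expect_equal(nrow(sim2$products), 10L)
  expect_output(print(fit), "deamination fit")
})
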