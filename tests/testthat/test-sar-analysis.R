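# SAR analytics: heat maps, contour statistics, correlation and
# threshold necessity.

lib1_screen <- function(seed = 2) {
  v <- evaluate_library(
    describe_library(enumerate_library(fx_registry(),
                                       library1_design(fx_registry()),
                                       structures = FALSE),
                     fx_registry()),
    rule_config())
  list(verdicts = v, records = simulate_screen(v, screen_params(seed = seed)))
}

test_that("the Library-1 heat map is the full 5 x 5 grid", {
  s <- lib1_screen()
  hm <- build_heatmap(s$records, s$verdicts, "invivo")
  expect_equal(dim(hm), c(5, 5))
  expect_equal(rownames(hm), as.character(c(6, 8, 10, 12, 14)))
  expect_false(anyNA(hm))
  expect_equal(sum(attr(hm, "counts")), nrow(s$records))
})

test_that("heat-map cells are medians of their replicates", {
  recs <- data.frame(name = c("1-10-8", "1-10-8", "1-10-8", "1-6-6"),
                     invitro_rlu = c(1e4, 1e4, 1e4, 1e3),
                     invivo_flux = c(1e8, 1e9, 1e10, 1e6),
                     is_hit = c(TRUE, TRUE, TRUE, FALSE))
  desc <- data.frame(name = c("1-10-8", "1-6-6"), m = c(10L, 6L),
                     n = c(8L, 6L))
  hm <- build_heatmap(recs, desc, "invivo")
  expect_equal(hm["10", "8"], 9) # median of log10(1e8,1e9,1e10)
  expect_equal(hm["6", "6"], 6)
  expect_true(is.na(hm["6", "8"])) # never screened, absent not zero
  single <- build_heatmap(recs[4, ], desc, "invivo")
  expect_equal(dim(single), c(1, 1))
  expect_equal(single[1, 1], 6)
})

test_that("marginal tail profiles cover every tail length", {
  s <- lib1_screen()
  pf <- tail_profiles(s$records, s$verdicts)
  expect_equal(pf$by_m$m, c(6, 8, 10, 12, 14))
  expect_equal(pf$by_n$n, c(6, 8, 10, 12, 14))
})

test_that("contour statistics identify the 18-carbon symmetric ridge", {
  full <- fx_screen_factorial()$table
  rec <- simulate_screen(full, screen_params(seed = 8))
  ct <- contour_stats(rec, full)
  am <- attr(ct, "argmax")
  expect_equal(am$tc_bin, "[18,20)")
  expect_equal(am$d_bin, "[0,0.25)")
  expect_equal(sum(ct$count), nrow(rec))
  # degenerate binning: a single all-covering bin is the global median
  ct1 <- contour_stats(rec, full, tc_bins = c(0, 100), d_bins = c(0, Inf))
  expect_equal(nrow(ct1), 1)
  expect_equal(ct1$median_log10_flux, stats::median(log10(rec$invivo_flux)))
  # identical readouts give a flat table
  rec_flat <- rec
  rec_flat$invivo_flux <- 1e7
  ctf <- contour_stats(rec_flat, full)
  expect_true(all(ctf$median_log10_flux == 7))
})

test_that("the correlation test equals the textbook formula", {
  x <- c(3.1, 4.2, 2.8, 5.0, 3.9, 4.4, 2.5, 3.3, 4.8, 3.6)
  y <- c(6.8, 7.9, 6.1, 8.8, 7.2, 8.1, 6.0, 6.6, 8.5, 7.1)
  rec <- data.frame(name = letters[1:10], invitro_rlu = 10^x,
                    invivo_flux = 10^y, is_hit = FALSE)
  ct <- correlation_test(rec)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(8 / (1 - r_hand^2))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 8)
  expect_equal(ct$r, r_hand, tolerance = 1e-12)
  expect_equal(ct$p, p_hand, tolerance = 1e-12)
  expect_equal(ct$n, 10)
})

test_that("perfect linear channels give |r| = 1", {
  rec <- data.frame(name = letters[1:5], invitro_rlu = 10^(1:5),
                    invivo_flux = 10^(1:5), is_hit = FALSE)
  expect_equal(correlation_test(rec)$r, 1, tolerance = 1e-12)
  rec$invivo_flux <- 10^(5:1)
  expect_equal(correlation_test(rec)$r, -1, tolerance = 1e-12)
  rec$invivo_flux <- rep(10, 5)
  expect_error(correlation_test(rec), "zero variance")
  expect_error(correlation_test(rec[1:2, ]), "at least 3")
})

test_that("threshold necessity reports both directions with edge cases", {
  s <- lib1_screen(seed = 13)
  tn <- threshold_necessity(s$records, threshold = 0)
  expect_true(is.null(tn$fraction_hits_above) ||
                tn$fraction_hits_above == 1)
  tn_hi <- threshold_necessity(s$records,
                               threshold = max(s$records$invitro_rlu) * 10)
  if (any(s$records$is_hit)) {
    expect_equal(tn_hi$fraction_hits_above, 0)
  } else {
    expect_null(tn_hi$fraction_hits_above)
  }
  no_hits <- s$records
  no_hits$is_hit <- FALSE
  expect_null(threshold_necessity(no_hits)$fraction_hits_above)
})

test_that("the bundled SAR report is internally consistent", {
  s <- lib1_screen(seed = 3)
  rep <- sar_report(s$records, s$verdicts)
  expect_s3_class(rep, "sar_report")
  expect_equal(rep$correlation$n, nrow(s$records))
  expect_equal(sum(attr(rep$heatmap_invivo, "counts")), nrow(s$records))
  expect_equal(rep$heatmap_invivo[, 1],
               build_heatmap(s$records, s$verdicts, "invivo")[, 1])
})
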