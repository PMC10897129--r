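# Rule-based potency classification and ranking.

lib1_verdicts <- function(d_max = 1.0) {
  reg <- fx_registry()
  lib <- enumerate_library(reg, library1_design(reg), structures = FALSE)
  evaluate_library(describe_library(lib, reg), rule_config(d_max = d_max))
}

test_that("the canonical examples classify as published", {
  reg <- fx_registry()
  v <- lib1_verdicts()
  expect_true(v$predicted_potent[v$name == "1-10-8"])
  # 18 carbons but strongly imbalanced: fails the symmetry criterion only
  row <- v[v$name == "1-6-12", ]
  expect_false(row$predicted_potent)
  expect_true(row$c1_total18)
  expect_false(row$c2_symmetry)
  # amine-11 lipidoid with 22 carbons: fails the 18-carbon criterion only
  lib <- enumerate_library(reg, list(amines = "amine-11",
                                     epoxides = "epoxide-12",
                                     acyls = "acyl-10"), structures = FALSE)
  v22 <- evaluate_library(describe_library(lib, reg), rule_config())
  expect_false(v22$predicted_potent)
  expect_false(v22$c1_total18)
  expect_true(v22$c2_symmetry)
  expect_true(v22$c3_headgroup)
})

test_that("Library 1 yields exactly the three published hits", {
  v <- lib1_verdicts()
  expect_setequal(v$name[v$predicted_potent],
                  c("1-8-10", "1-10-8", "1-12-6"))
})

test_that("a brute-force reimplementation of the printed criteria agrees on Library 1", {
  # independent filter: 18 total carbons, |n/(m-2) - 1| <= 1, and an
  # amine-1 headgroup (known efficacious)
  grid <- expand.grid(m = c(6, 8, 10, 12, 14), n = c(6, 8, 10, 12, 14))
  brute <- grid[grid$m + grid$n == 18 &
                  abs(grid$n / (grid$m - 2) - 1) <= 1, ]
  brute_names <- sprintf("1-%d-%d", brute$m, brute$n)
  v <- lib1_verdicts()
  expect_setequal(v$name[v$predicted_potent], brute_names)
})

test_that("no lipidoid off the 18-carbon total is ever predicted potent", {
  for (d_max in c(0.1, 0.5, 1.0, 5, 100)) {
    v <- lib1_verdicts(d_max)
    expect_true(all(v$total_carbons[v$predicted_potent] == 18),
                info = paste("d_max =", d_max))
  }
})

test_that("shrinking d_max only removes candidates", {
  prev <- NULL
  for (d_max in c(2, 1, 0.5, 0.25)) {
    cur <- sort(lib1_verdicts(d_max)$name[lib1_verdicts(d_max)$predicted_potent])
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("ranking orders the amine-11 case-study set by deviation", {
  reg <- fx_registry()
  designs <- lapply(list(c(10, 8), c(8, 10), c(12, 6), c(6, 12), c(12, 10)),
                    function(mn) list(amines = "amine-11",
                                      epoxides = paste0("epoxide-", mn[1]),
                                      acyls = paste0("acyl-", mn[2])))
  libs <- do.call(c, lapply(designs, function(d) {
    unclass(enumerate_library(reg, d, structures = FALSE))
  }))
  class(libs) <- c("lipidoid_library", "list")
  v <- rank_lipidoids(evaluate_library(describe_library(libs, reg),
                                       rule_config()))
  expect_equal(v$name[1], "11-10-8")
  expect_equal(v$name[nrow(v)], "11-12-10") # 22 carbons: worst violation
  # within the 18-carbon set the deviation rules: 0 < 0.4 < 2/3 < 2
  expect_equal(v$name[1:4], c("11-10-8", "11-12-6", "11-8-10", "11-6-12"))
  # any violated criterion outranks any compliant candidate
  compliant_max <- max(v$rank_score[v$predicted_potent])
  violated_min <- min(v$rank_score[!v$predicted_potent])
  expect_lt(compliant_max, violated_min)
  # singleton sort is the identity
  single <- v[v$name == "11-10-8", ]
  expect_equal(rank_lipidoids(single), single)
})

test_that("rank improves strictly as the deviation falls, all else equal", {
  v <- lib1_verdicts()
  tc18 <- v[v$total_carbons == 18, ]
  tc18 <- tc18[order(tc18$deviation), ]
  expect_true(all(diff(tc18$rank_score) > 0))
})

test_that("pooled screening of both libraries reproduces the published hit rate", {
  scr <- fx_screen_libraries()
  # 25 + 20 designs share 1-10-8, so 44 unique candidates
  expect_equal(scr$n_candidates, 44)
  expect_equal(scr$n_predicted_potent, 8)
  expect_equal(scr$hit_rate, 18)
  hits <- scr$table$name[scr$table$predicted_potent]
  expect_setequal(hits, c("1-8-10", "1-10-8", "1-12-6", "7-10-8", "9-10-8",
                          "10-10-8", "11-10-8", "12-10-8"))
})

test_that("an empty design yields an empty screen with undefined hit rate", {
  reg <- fx_registry()
  scr <- screen_library(reg, list(amines = character(0),
                                  epoxides = character(0),
                                  acyls = character(0)))
  expect_equal(scr$n_candidates, 0)
  expect_null(scr$hit_rate)
})

test_that("undefined symmetry fails the symmetry criterion with a note", {
  desc <- list(total_carbons = 18L, deviation = NA_real_,
               headgroup_efficacious = TRUE)
  v <- evaluate_rules(desc, rule_config())
  expect_false(v$c2_symmetry)
  expect_false(v$predicted_potent)
  expect_match(v$notes, "undefined symmetry", all = FALSE)
  expect_true(is.finite(v$rank_score))
})
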