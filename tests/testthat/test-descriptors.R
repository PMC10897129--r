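# Tail descriptors, headgroup classification and metabolite mass.

test_that("symmetry and total carbons reproduce the canonical tail pairs", {
  cases <- list(list(m = 10, n = 8, s = 1, tc = 18),
                list(m = 8, n = 10, s = 1.7, tc = 18),
                list(m = 12, n = 6, s = 0.6, tc = 18),
                list(m = 6, n = 12, s = 3, tc = 18),
                list(m = 12, n = 10, s = 1, tc = 22))
  for (cs in cases) {
    td <- tail_descriptors(c(cs$m, cs$n))
    expect_equal(td$s_display, cs$s, info = sprintf("%d-%d", cs$m, cs$n))
    expect_equal(td$total_carbons, cs$tc)
    expect_equal(td$deviation, abs(cs$n / (cs$m - 2) - 1), tolerance = 1e-12)
  }
  expect_error(tail_descriptors(c(2, 8)), "symmetry undefined")
  # name and lipidoid interfaces agree
  expect_equal(tail_descriptors("1-10-8")$symmetry, 1)
  expect_equal(tail_descriptors(fx_lead_11_10_8())$total_carbons, 18L)
})

test_that("the deviation grows with tail imbalance at fixed m", {
  for (m in c(6, 8, 10, 12, 14)) {
    ns <- seq(2, 20)
    d <- abs(symmetry(m, ns) - 1)
    imb <- abs(ns - (m - 2))
    expect_true(all(diff(d[order(imb)]) >= -1e-12), info = paste("m =", m))
  }
})

test_that("(m, n) can be recovered from the structure alone", {
  reg <- fx_registry()
  for (nm in c("1-6-14", "1-10-8", "11-12-6")) {
    p <- parse_lipidoid_name(nm)
    lip <- acylate(open_epoxide(get_block(reg, paste0("amine-", p["x"])),
                                get_block(reg, paste0("epoxide-", p["m"])),
                                2),
                   get_block(reg, paste0("acyl-", p["n"])), 2)
    mn <- infer_tails_from_structure(lip$mol)
    expect_equal(unname(mn), unname(p[c("m", "n")]), info = nm)
  }
})

test_that("headgroup classes follow the published structure-activity reading", {
  reg <- fx_registry()
  expected <- list(
    `amine-1` = list(eff = TRUE, kind = "dimethylamino", spacer = 3L),
    `amine-2` = list(eff = FALSE, kind = "none"),
    `amine-4` = list(eff = FALSE, hydrazine = TRUE),
    `amine-5` = list(eff = FALSE, hydrazine = TRUE),
    `amine-6` = list(eff = FALSE, kind = "none"),
    `amine-7` = list(eff = TRUE, kind = "dimethylamino", spacer = 2L),
    `amine-8` = list(eff = FALSE, kind = "dimethylamino", spacer = 4L),
    `amine-9` = list(eff = TRUE, kind = "diethylamino", spacer = 2L),
    `amine-10` = list(eff = TRUE, kind = "diethylamino", spacer = 3L),
    `amine-11` = list(eff = TRUE, kind = "pyrrolidinyl", spacer = 2L),
    `amine-12` = list(eff = TRUE, kind = "pyrrolidinyl", spacer = 3L),
    `amine-13` = list(eff = FALSE),
    `amine-14` = list(eff = FALSE, kind = "other"),
    `amine-15` = list(eff = FALSE, kind = "other"),
    `amine-16` = list(eff = FALSE, n_sec = 2L),
    `amine-19` = list(eff = FALSE, n_sec = 2L))
  for (id in names(expected)) {
    hg <- classify_headgroup(get_block(reg, id))
    e <- expected[[id]]
    expect_equal(hg$is_efficacious_class, e$eff, info = id)
    if (!is.null(e$kind)) expect_equal(hg$tertiary_kind, e$kind, info = id)
    if (!is.null(e$spacer)) expect_equal(hg$spacer, e$spacer, info = id)
    if (!is.null(e$hydrazine)) expect_true(hg$has_hydrazine, info = id)
    if (!is.null(e$n_sec)) expect_equal(hg$n_secondary, e$n_sec, info = id)
  }
  # exactly the six published efficacious headgroups
  eff_ids <- Filter(function(id) {
    classify_headgroup(get_block(reg, id))$is_efficacious_class
  }, vapply(reg$amines, `[[`, character(1), "id"))
  expect_setequal(eff_ids, paste0("amine-", c(1, 7, 9, 10, 11, 12)))
})

test_that("non-ideal tertiary forms are rejected", {
  # piperidinyl and morpholino rings are not among the three ideal forms
  expect_equal(classify_headgroup("NCCN1CCCCC1")$tertiary_kind, "other")
  expect_equal(classify_headgroup("NCCN1CCOCC1")$tertiary_kind, "other")
  expect_false(classify_headgroup("NCCN1CCCCC1")$is_efficacious_class)
  # a heteroatom on the N-N path disqualifies the spacer
  hg <- classify_headgroup("NCOCN(C)C")
  expect_true(is.na(hg$spacer))
  expect_false(hg$is_efficacious_class)
})

test_that("classification is invariant to atom order and salt form", {
  variants <- c("NCCN1CCCC1", "C1CCN(CCN)C1", "C(N)CN1CCCC1",
                "[NH3+]CCN1CCCC1.[Cl-]")
  ref <- classify_headgroup(variants[1])
  for (v in variants[-1]) {
    expect_equal(unclass(classify_headgroup(v)), unclass(ref), info = v)
  }
})

test_that("amine counts cross-check against SMARTS matching", {
  reg <- fx_registry()
  for (id in c("amine-1", "amine-9", "amine-11", "amine-13", "amine-16")) {
    mol <- mol_from_smiles(get_block(reg, id)$structure)
    hg <- classify_headgroup(get_block(reg, id))
    expect_equal(hg$n_primary,
                 mol_smarts_count(mol, "[NX3;H2;!$(NC=O);!$(NN)]"),
                 info = id)
    expect_equal(hg$n_tertiary,
                 mol_smarts_count(mol, "[NX3;H0;!$(NC=O);!$(N=*)]"),
                 info = id)
  }
})

test_that("metabolite mass depends on amine and body tail only", {
  reg <- fx_registry()
  lip <- function(nm) {
    p <- parse_lipidoid_name(nm)
    acylate(open_epoxide(get_block(reg, paste0("amine-", p["x"])),
                         get_block(reg, paste0("epoxide-", p["m"])), 2),
            get_block(reg, paste0("acyl-", p["n"])), 2)
  }
  mm <- metabolite_mass(lip("1-10-8"))
  # average-mass oracle: C25H54N2O2 with conventional atomic weights
  expect_equal(mm$mass, 25 * 12.011 + 54 * 1.008 + 2 * 14.007 + 2 * 15.999,
               tolerance = 1e-9)
  expect_equal(round(mm$mass, 1), 414.7)
  expect_true(mm$under_500)

  # branch-independence
  expect_equal(metabolite_mass(lip("1-6-12"))$mass,
               metabolite_mass(lip("1-6-6"))$mass)

  # C14 body tails push the metabolite over 500 Da
  mm14 <- metabolite_mass(lip("1-14-8"))
  expect_equal(mm14$mass, 33 * 12.011 + 70 * 1.008 + 2 * 14.007 +
                 2 * 15.999, tolerance = 1e-9)
  expect_false(mm14$under_500)
})

test_that("the library descriptor table is complete and consistent", {
  reg <- fx_registry()
  lib <- enumerate_library(reg, library1_design(reg), structures = FALSE)
  desc <- describe_library(lib, reg)
  expect_equal(nrow(desc), 25)
  expect_equal(desc$total_carbons, desc$m + desc$n)
  expect_true(all(desc$headgroup_efficacious)) # amine 1 throughout
  expect_equal(desc$metabolite_under_500, desc$m <= 12)
})
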