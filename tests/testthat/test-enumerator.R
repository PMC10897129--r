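# Virtual three-component synthesis: ring-opening, acylation, naming,
# mass bookkeeping and degradation.

test_that("double ring-opening yields the expected aminoalcohol", {
  reg <- fx_registry()
  aa <- open_epoxide(get_block(reg, "amine-1"), get_block(reg, "epoxide-10"),
                     2)
  # element bookkeeping oracle: C5H14N2 + 2 x C10H20O, no leaving group
  expect_equal(formula_string(aa$formula), "C25H54N2O2")
  expect_equal(aa$stage, "aminoalcohol")
  expect_equal(count_hydroxyls(aa$mol), 2)
  expect_equal(count_esters(aa$mol), 0)
})

test_that("ring-opening respects N-H capacity and identity at count 0", {
  reg <- fx_registry()
  amine <- get_block(reg, "amine-1")
  untouched <- open_epoxide(amine, get_block(reg, "epoxide-10"), 0)
  expect_equal(formula_string(untouched$formula), "C5H14N2")

  # a di-secondary diamine takes one tail on each nitrogen
  disec <- get_block(reg, "amine-16")
  aa <- open_epoxide(disec, get_block(reg, "epoxide-6"), 2)
  expect_equal(count_hydroxyls(aa$mol), 2)
  ns <- which(aa$mol$elem == "N")
  expect_true(all(mol_implicit_h(aa$mol)[ns] == 0))

  # capacity exceeded: a mono-secondary amine cannot take two tails
  one_nh <- building_block("amine-t", "amine", "CCNCC", 4)
  expect_error(open_epoxide(one_nh, get_block(reg, "epoxide-6"), 2),
               "insufficient N-H")
})

test_that("acylation reproduces the published product characterization", {
  lead <- fx_lead_11_10_8()
  expect_equal(formula_string(lead$formula), "C42H82N2O4")
  expect_equal(round(lead$monoisotopic_mass, 2), 678.63)
  expect_equal(lead$formula[["H"]], 82L)
  expect_equal(lead$stage, "two_branch")
  expect_equal(lead$name, "11-10-8")
  # [M + H]+ from the proton mass
  expect_equal(round(protonated_mass(lead), 2), 679.63)
})

test_that("partial acylation leaves a one-branch intermediate", {
  reg <- fx_registry()
  aa <- open_epoxide(get_block(reg, "amine-11"), get_block(reg, "epoxide-10"),
                     2)
  one <- acylate(aa, get_block(reg, "acyl-8"), 1)
  expect_equal(one$stage, "one_branch")
  expect_equal(count_esters(one$mol), 1)
  expect_equal(count_hydroxyls(one$mol), 1)
  expect_identical(acylate(aa, get_block(reg, "acyl-8"), 0), aa)
  expect_error(acylate(acylate(aa, get_block(reg, "acyl-8"), 2),
                       get_block(reg, "acyl-8"), 1),
               "no free hydroxyl")
})

test_that("library enumeration returns the designed cross products in order", {
  reg <- fx_registry()
  lib1 <- enumerate_library(reg, library1_design(reg), structures = FALSE)
  expect_length(lib1, 25)
  singleton <- enumerate_library(reg, list(amines = "amine-1",
                                           epoxides = "epoxide-10",
                                           acyls = "acyl-8"),
                                 structures = FALSE)
  expect_length(singleton, 1)
  expect_equal(singleton[[1]]$name, "1-10-8")
  empty <- enumerate_library(reg, list(amines = character(0),
                                       epoxides = character(0),
                                       acyls = character(0)))
  expect_length(empty, 0)
  full <- fx_screen_factorial()
  expect_equal(full$n_candidates, 500)
  # deterministic ordering: amine number, then m, then n, ascending
  df <- as.data.frame(enumerate_library(reg, library1_design(reg),
                                        structures = FALSE))
  expect_equal(df$m, rep(c(6L, 8L, 10L, 12L, 14L), each = 5))
  expect_equal(df$n, rep(c(6L, 8L, 10L, 12L, 14L), times = 5))
})

test_that("amines that cannot carry exactly two body tails are skipped with a warning", {
  reg <- fx_registry()
  blocks <- c(registry_blocks(reg),
              list(building_block("amine-99", "amine", "NCCCCCCCCN", 8,
                                  "diprimary diamine: four N-H")))
  reg2 <- registry(blocks)
  expect_warning(
    lib <- enumerate_library(reg2, list(amines = c("amine-1", "amine-99"),
                                        epoxides = "epoxide-10",
                                        acyls = "acyl-8"),
                             structures = FALSE),
    "amine-99")
  expect_length(lib, 1)
})

test_that("naming is bijective over the full factorial", {
  full <- fx_screen_factorial()$table
  expect_false(anyDuplicated(full$name) > 0)
  for (i in seq_len(nrow(full))) {
    p <- parse_lipidoid_name(full$name[i])
    expect_equal(unname(p), c(full$x[i], full$m[i], full$n[i]))
  }
  expect_error(parse_lipidoid_name("1-10"), "x-m-n")
})

test_that("element balance holds for every registry combination", {
  reg <- fx_registry()
  full <- enumerate_library(reg, full_factorial_design(reg),
                            structures = FALSE)
  hcl <- parse_formula("HCl")
  add_f <- function(a, b, mult = 1L) {
    els <- union(names(a), names(b))
    av <- stats::setNames(rep(0L, length(els)), els)
    av[names(a)] <- av[names(a)] + a
    av[names(b)] <- av[names(b)] + mult * b
    av
  }
  forms <- new.env(parent = emptyenv())
  block_formula <- function(id) {
    if (is.null(forms[[id]])) {
      forms[[id]] <- mol_formula(mol_from_smiles(get_block(reg,
                                                           id)$structure))
    }
    forms[[id]]
  }
  for (l in full) {
    lhs <- add_f(add_f(block_formula(l$amine_id),
                       block_formula(l$epoxide_id), 2L),
                 block_formula(l$acyl_id), 2L)
    rhs <- add_f(l$formula, hcl, 2L)
    expect_equal(hill_order(lhs), hill_order(rhs), info = l$name)
  }
})

test_that("ester hydrolysis releases fatty acids and inverts acylation", {
  reg <- fx_registry()
  lead <- fx_lead_11_10_8()
  ms <- degrade(lead, 2)
  expect_equal(ms$remnant$stage, "aminoalcohol")
  expect_length(ms$fatty_acids, 2)
  for (fa in ms$fatty_acids) {
    expect_equal(formula_string(fa$formula), "C8H16O2") # octanoic acid
  }
  # element conservation with two waters consumed
  lhs <- c(C = 42L + 0L, H = 82L + 4L, N = 2L, O = 4L + 2L) # lead + 2 H2O
  rhs <- ms$remnant$formula
  for (fa in ms$fatty_acids) {
    for (el in names(fa$formula)) {
      rhs[el] <- (if (el %in% names(rhs)) rhs[[el]] else 0L) +
        fa$formula[[el]]
    }
  }
  expect_equal(hill_order(lhs), hill_order(rhs))

  # identity and error paths
  expect_identical(degrade(lead, 0)$remnant, lead)
  expect_error(degrade(lead, 3), "only 2 present")
})

test_that("degradation round-trips to the aminoalcohol by canonical structure", {
  reg <- fx_registry()
  aa <- open_epoxide(get_block(reg, "amine-1"), get_block(reg, "epoxide-8"),
                     2)
  acyl <- get_block(reg, "acyl-12")
  aa_can <- mol_canonical_smiles(aa$mol)
  for (k in 1:2) {
    prod <- acylate(aa, acyl, k)
    back <- degrade(prod, k)
    expect_equal(mol_canonical_smiles(back$remnant$mol), aa_can)
  }
  # single cleavage of the full product equals direct mono-acylation
  two <- acylate(aa, acyl, 2)
  one_via_degrade <- degrade(two, 1)$remnant
  one_direct <- acylate(aa, acyl, 1)
  expect_equal(mol_canonical_smiles(one_via_degrade$mol),
               mol_canonical_smiles(one_direct$mol))
})

test_that("libraries write to CSV and SDF", {
  reg <- fx_registry()
  lib <- enumerate_library(reg, list(amines = "amine-1",
                                     epoxides = c("epoxide-6", "epoxide-8"),
                                     acyls = "acyl-8"))
  csv <- tempfile(fileext = ".csv")
  write_library(lib, csv)
  df <- utils::read.csv(csv)
  expect_equal(nrow(df), 2)
  expect_true(all(c("name", "m", "n", "formula", "smiles") %in% names(df)))
  sdf <- tempfile(fileext = ".sdf")
  write_library(lib, sdf)
  expect_length(ChemmineR::read.SDFset(sdf), 2)
})
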