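# Virtual one-pot, two-step, three-component synthesis of DB-lipidoids.
#
# Step 1: a primary (or di-secondary) amine opens two terminal alkyl
# epoxides at the less hindered CH2 carbon, giving an aminoalcohol
# lipidoid with two body tails and two secondary hydroxyls.
# Step 2: the hydroxyls are acylated by acyl chlorides, attaching two
# branch tails through ester bonds with formal loss of HCl.
# The reverse transform (ester hydrolysis) models enzymatic degradation
# back to fatty acids and the non-degradable aminoalcohol metabolite.

LIPIDOID_STAGES <- c("aminoalcohol", "one_branch", "two_branch")

new_lipidoid <- function(mol, name = NA_character_, amine_id = NA_character_,
                         epoxide_id = NA_character_, acyl_id = NA_character_,
                         x = NA_integer_, m = NA_integer_, n = NA_integer_,
                         structure = NULL) {
  esters <- count_esters(mol)
  stage <- if (esters >= 2L) "two_branch" else if (esters == 1L) "one_branch"
  else "aminoalcohol"
  f <- mol_formula(mol)
  structure(list(name = name, mol = mol,
                 structure = structure, # canonical SMILES, filled lazily
                 amine_id = amine_id, epoxide_id = epoxide_id,
                 acyl_id = acyl_id, x = x, m = m, n = n,
                 stage = stage, formula = f,
                 monoisotopic_mass = formula_mass(f, "monoisotopic"),
                 average_mass = formula_mass(f, "average")),
            class = "lipidoid")
}

#' Canonical SMILES of a lipidoid
#'
#' @param lipidoid a `lipidoid`.
#' @return Canonical SMILES string.
#' @export
lipidoid_structure <- function(lipidoid) {
  if (is.null(lipidoid$structure)) {
    lipidoid$structure <- mol_canonical_smiles(lipidoid$mol)
  }
  lipidoid$structure
}

#' @export
print.lipidoid <- function(x, ...) {
  cat("<lipidoid> ", if (is.na(x$name)) "(unnamed)" else x$name,
      " [", x$stage, "] ", formula_string(x$formula),
      sprintf(" (monoisotopic %.2f Da)\n", x$monoisotopic_mass), sep = "")
  invisible(x)
}

#' Compose and parse the x-m-n lipidoid naming convention
#'
#' A DB-lipidoid is named `x-m-n`: amine number x, body-tail carbons m
#' (from the epoxide), branch-tail carbons n (from the acyl chloride,
#' counting the carbonyl carbon).
#'
#' @param x,m,n integers.
#' @return `lipidoid_name()` a string; `parse_lipidoid_name()` a named
#'   integer vector with elements `x`, `m`, `n`.
#' @export
lipidoid_name <- function(x, m, n) sprintf("%d-%d-%d", x, m, n)

#' @rdname lipidoid_name
#' @param name a name in the `x-m-n` convention.
#' @export
parse_lipidoid_name <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  if (length(parts) != 3L || anyNA(suppressWarnings(as.integer(parts)))) {
    stop("not an x-m-n lipidoid name: ", name, call. = FALSE)
  }
  stats::setNames(as.integer(parts), c("x", "m", "n"))
}

amine_number <- function(id) {
  n <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", id)))
  if (is.na(n)) stop("cannot extract amine number from id '", id, "'",
                     call. = FALSE)
  n
}

as_block_mol <- function(block) mol_from_smiles(block$structure)

#' Epoxide ring-opening on an amine
#'
#' Attaches `count` body tails to the amine by SN2 ring-opening of a
#' terminal 1,2-epoxide at its terminal CH2 carbon, so each tail is
#' joined as N-CH2-CH(OH)-alkyl with a secondary alcohol. All atoms are
#' conserved (no leaving group). Tails fill N-H sites in order:
#' nitrogens with more substitutable hydrogens first (a primary amine
#' takes both tails; two secondary amines take one each).
#'
#' @param amine an amine `building_block`.
#' @param epoxide an epoxide `building_block` with a terminal epoxide.
#' @param count number of tails to attach (0, 1 or 2).
#' @return A `lipidoid`; with `count = 2` and no esters present its
#'   stage is `"aminoalcohol"`.
#' @export
open_epoxide <- function(amine, epoxide, count = 2L) {
  stopifnot(count %in% 0:2)
  mol <- as_block_mol(amine)
  if (count == 0L) {
    return(new_lipidoid(mol, amine_id = amine$id,
                        x = amine_number(amine$id)))
  }
  epo <- as_block_mol(epoxide)
  ep <- find_epoxides(epo)
  if (length(ep) != 1L || is.na(ep[[1]]$c_term)) {
    stop("epoxide block must contain exactly one terminal 1,2-epoxide",
         call. = FALSE)
  }
  for (k in seq_len(count)) {
    sites <- amine_sites(mol)
    # secondary hydroxyls formed by earlier ring-openings are not amine
    # sites, so `sites` always tracks remaining N-H capacity
    if (!nrow(sites)) {
      stop("cannot attach ", count, " body tails: amine has insufficient N-H",
           call. = FALSE)
    }
    sites <- sites[order(-sites$h, sites$atom), , drop = FALSE]
    n_at <- sites$atom[1]
    mg <- mol_merge(mol, epo)
    mol <- mg$mol
    c_term <- ep[[1]]$c_term + mg$offset
    o_at <- ep[[1]]$o + mg$offset
    mol <- mol_remove_bond(mol, o_at, c_term) # open the ring
    mol <- mol_add_bond(mol, n_at, c_term)    # N attacks terminal CH2
  }
  new_lipidoid(mol, amine_id = amine$id, epoxide_id = epoxide$id,
               x = amine_number(amine$id), m = epoxide$carbon_count)
}

#' Acylation of an aminoalcohol lipidoid
#'
#' Converts `count` free hydroxyls to esters with an acyl chloride,
#' formally eliminating one HCl per acylation. The stage of the product
#' follows its ester count (`one_branch`, `two_branch`).
#'
#' @param aminoalcohol a `lipidoid` with free hydroxyls.
#' @param acyl an acyl-chloride `building_block`.
#' @param count number of acylations (0, 1 or 2).
#' @return A `lipidoid`.
#' @export
acylate <- function(aminoalcohol, acyl, count = 2L) {
  stopifnot(inherits(aminoalcohol, "lipidoid"), count %in% 0:2)
  mol <- aminoalcohol$mol
  if (count == 0L) return(aminoalcohol)
  acmol <- as_block_mol(acyl)
  ac <- find_acyl_chlorides(acmol)
  if (length(ac) != 1L) {
    stop("acyl block must contain exactly one -C(=O)Cl group", call. = FALSE)
  }
  acmol_noCl <- mol_remove_atoms(acmol, ac[[1]]$cl)
  # carbonyl carbon index after Cl removal (indices above cl shift down)
  c_acyl0 <- ac[[1]]$c - (ac[[1]]$c > ac[[1]]$cl)
  for (k in seq_len(count)) {
    ohs <- find_hydroxyls(mol)
    if (!length(ohs)) {
      stop("cannot acylate: no free hydroxyl remaining", call. = FALSE)
    }
    o_at <- min(ohs)
    mg <- mol_merge(mol, acmol_noCl)
    mol <- mg$mol
    mol <- mol_add_bond(mol, o_at, c_acyl0 + mg$offset)
  }
  name <- NA_character_
  if (!is.na(aminoalcohol$x) && !is.na(aminoalcohol$m)) {
    name <- lipidoid_name(aminoalcohol$x, aminoalcohol$m, acyl$carbon_count)
  }
  new_lipidoid(mol, name = name, amine_id = aminoalcohol$amine_id,
               epoxide_id = aminoalcohol$epoxide_id, acyl_id = acyl$id,
               x = aminoalcohol$x, m = aminoalcohol$m,
               n = acyl$carbon_count)
}

#' Enumerate a DB-lipidoid library
#'
#' Builds the full cross product of the design's amines, epoxides and
#' acyl chlorides through the two-step virtual synthesis. Amines that
#' cannot attach exactly two body tails (total substitutable N-H not
#' equal to 2) are skipped with a warning. Products are ordered by amine
#' number, then m, then n, ascending.
#'
#' @param reg a `bb_registry`.
#' @param design list with character vectors `amines`, `epoxides`,
#'   `acyls` of block ids.
#' @param structures compute canonical SMILES for every product (one
#'   batched call); set `FALSE` to skip when only formulas are needed.
#' @return A list of `lipidoid` objects (class `lipidoid_library`).
#' @export
enumerate_library <- function(reg, design, structures = TRUE) {
  stopifnot(is.list(design))
  amines <- lapply(design$amines, get_block, reg = reg)
  epoxides <- lapply(design$epoxides, get_block, reg = reg)
  acyls <- lapply(design$acyls, get_block, reg = reg)
  keep <- vapply(amines, function(a) {
    ok <- amine_nh_capacity(as_block_mol(a)) == 2L
    if (!ok) warning("skipping amine '", a$id,
                     "': cannot attach exactly two body tails",
                     call. = FALSE)
    ok
  }, logical(1))
  amines <- amines[keep]
  ord_a <- order(vapply(amines, function(a) amine_number(a$id), integer(1)))
  ord_e <- order(vapply(epoxides, `[[`, integer(1), "carbon_count"))
  ord_c <- order(vapply(acyls, `[[`, integer(1), "carbon_count"))
  out <- list()
  for (a in amines[ord_a]) {
    for (e in epoxides[ord_e]) {
      aa <- open_epoxide(a, e, count = 2L)
      for (cl in acyls[ord_c]) {
        out[[length(out) + 1L]] <- acylate(aa, cl, count = 2L)
      }
    }
  }
  if (structures && length(out)) {
    smis <- mol_canonical_smiles_batch(lapply(out, `[[`, "mol"))
    for (i in seq_along(out)) out[[i]]$structure <- smis[i]
  }
  class(out) <- c("lipidoid_library", "list")
  out
}

#' @export
as.data.frame.lipidoid_library <- function(x, ...) {
  data.frame(name = vapply(x, `[[`, character(1), "name"),
             x = vapply(x, `[[`, integer(1), "x"),
             m = vapply(x, `[[`, integer(1), "m"),
             n = vapply(x, `[[`, integer(1), "n"),
             stage = vapply(x, `[[`, character(1), "stage"),
             formula = vapply(x, function(l) formula_string(l$formula),
                              character(1)),
             monoisotopic_mass = vapply(x, `[[`, numeric(1),
                                        "monoisotopic_mass"),
             average_mass = vapply(x, `[[`, numeric(1), "average_mass"),
             smiles = vapply(x, function(l)
               if (is.null(l$structure)) NA_character_ else l$structure,
               character(1)),
             stringsAsFactors = FALSE)
}

#' Write a lipidoid library to CSV or SDF
#'
#' @param lib a `lipidoid_library`.
#' @param path output path (`.csv` or `.sdf`).
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(as.data.frame(lib), path, sep = ",",
                       row.names = FALSE, quote = TRUE)
  } else if (ext == "sdf") {
    con <- file(path, "w")
    on.exit(close(con))
    for (l in lib) {
      writeLines(mol_molblock(l$mol, title = l$name), con)
      writeLines(c(">  <name>", l$name, "",
                   ">  <formula>", formula_string(l$formula), "",
                   ">  <monoisotopic_mass>",
                   sprintf("%.4f", l$monoisotopic_mass), "",
                   ">  <average_mass>", sprintf("%.4f", l$average_mass), "",
                   "$$$$"), con)
    }
  } else {
    stop("unsupported library format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Monoisotopic, average and protonated masses
#'
#' `monoisotopic_mass()` sums principal-isotope masses; `average_mass()`
#' uses conventional atomic weights; `protonated_mass()` is the
#' monoisotopic mass plus one proton, i.e. the expected m/z of the
#' singly protonated ion.
#'
#' @param x a `lipidoid`, a named element-count vector, or a formula
#'   string such as `"C42H82N2O4"`.
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(x) formula_mass(as_formula(x), "monoisotopic")

#' @rdname monoisotopic_mass
#' @export
average_mass <- function(x) formula_mass(as_formula(x), "average")

#' @rdname monoisotopic_mass
#' @export
protonated_mass <- function(x) monoisotopic_mass(x) + PROTON_MASS

as_formula <- function(x) {
  if (inherits(x, "lipidoid")) return(x$formula)
  if (is.character(x)) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) {
    return(hill_order(stats::setNames(as.integer(x), names(x))))
  }
  stop("cannot interpret as a molecular formula", call. = FALSE)
}

#' Ester hydrolysis of a DB-lipidoid
#'
#' Cleaves `esters_cleaved` ester linkages. Each cleavage consumes one
#' water, releases one fatty acid (the acyl fragment plus OH) and
#' regenerates a hydroxyl on the lipidoid remnant; cleaving both esters
#' returns the non-degradable aminoalcohol metabolite.
#'
#' @param lipidoid a `lipidoid`.
#' @param esters_cleaved number of ester bonds to hydrolyse.
#' @return An object of class `metabolite_set` with fields `remnant`
#'   (a `lipidoid`; the aminoalcohol when all esters are cleaved),
#'   `fatty_acids` (list of `list(structure, formula)`), and
#'   `esters_cleaved`.
#' @export
degrade <- function(lipidoid, esters_cleaved = 2L) {
  stopifnot(inherits(lipidoid, "lipidoid"))
  esters_cleaved <- as.integer(esters_cleaved)
  available <- count_esters(lipidoid$mol)
  if (esters_cleaved > available) {
    stop("cannot cleave ", esters_cleaved, " ester(s): only ", available,
         " present", call. = FALSE)
  }
  mol <- lipidoid$mol
  acids <- list()
  if (esters_cleaved > 0L) {
    for (k in seq_len(esters_cleaved)) {
      es <- find_esters(mol)[[1L]]
      mol <- mol_remove_bond(mol, es$o_bridge, es$c_acyl)
      # hydrate the acyl carbon to a carboxylic acid
      mol <- mol_add_atom(mol, "O")
      mol <- mol_add_bond(mol, es$c_acyl, n_atoms(mol))
      comps <- mol_components(mol)
      acid_comp <- NULL
      for (cp in comps) {
        if (!any(mol$elem[cp] == "N")) acid_comp <- cp
      }
      acid <- mol_subset(mol, acid_comp)
      acids[[length(acids) + 1L]] <-
        list(structure = mol_canonical_smiles(acid),
             formula = mol_formula(acid))
      remnant_atoms <- setdiff(seq_len(n_atoms(mol)), acid_comp)
      mol <- mol_subset(mol, remnant_atoms)
    }
  }
  remnant <- new_lipidoid(mol, amine_id = lipidoid$amine_id,
                          epoxide_id = lipidoid$epoxide_id,
                          acyl_id = if (esters_cleaved < available)
                            lipidoid$acyl_id else NA_character_,
                          x = lipidoid$x, m = lipidoid$m,
                          n = if (esters_cleaved < available) lipidoid$n
                          else NA_integer_)
  if (esters_cleaved == 0L) remnant <- lipidoid
  structure(list(remnant = remnant, fatty_acids = acids,
                 esters_cleaved = esters_cleaved),
            class = "metabolite_set")
}

#' @export
print.metabolite_set <- function(x, ...) {
  cat("<metabolite_set> remnant stage ", x$remnant$stage, ", ",
      length(x$fatty_acids), " fatty acid(s) released\n", sep = "")
  invisible(x)
}

#' Canonical library designs
#'
#' `library1_design()` is the tail-optimization design: amine 1 crossed
#' with all five epoxides and all five acyl chlorides (25 lipidoids).
#' `library2_design()` is the headgroup-optimization design: all 20
#' amines with the optimal C10 body / C8 branch tails (20 lipidoids,
#' overlapping Library 1 in 1-10-8). `full_factorial_design()` crosses
#' everything (500 lipidoids).
#'
#' @param reg a `bb_registry` (defaults to [default_registry()]).
#' @return A design list with `amines`, `epoxides`, `acyls` id vectors.
#' @export
library1_design <- function(reg = default_registry()) {
  list(amines = "amine-1",
       epoxides = vapply(reg$epoxides, `[[`, character(1), "id"),
       acyls = vapply(reg$acyl_chlorides, `[[`, character(1), "id"))
}

#' @rdname library1_design
#' @export
library2_design <- function(reg = default_registry()) {
  list(amines = vapply(reg$amines, `[[`, character(1), "id"),
       epoxides = "epoxide-10",
       acyls = "acyl-8")
}

#' @rdname library1_design
#' @export
full_factorial_design <- function(reg = default_registry()) {
  list(amines = vapply(reg$amines, `[[`, character(1), "id"),
       epoxides = vapply(reg$epoxides, `[[`, character(1), "id"),
       acyls = vapply(reg$acyl_chlorides, `[[`, character(1), "id"))
}
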