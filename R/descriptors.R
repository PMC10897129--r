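# Structural descriptors of DB-lipidoids: tail carbon counts, total
# carbon number, tail symmetry, headgroup classification, and the mass
# of the non-degradable aminoalcohol metabolite.

#' Tail symmetry of a DB-lipidoid
#'
#' The tail-balance statistic s = n / (m - 2) compares the branch tail
#' (n carbons, acyl) with the body tail beyond its two linker-proximal
#' carbons (m - 2). s = 1 marks a symmetric tail pair; the deviation
#' d = |s - 1| measures the imbalance.
#'
#' @param m body-tail carbons (>= 3 for s to be defined).
#' @param n branch-tail carbons.
#' @return `symmetry()`: s (unrounded). `symmetry_deviation()`: d.
#' @export
symmetry <- function(m, n) {
  if (any(m <= 2)) {
    stop("symmetry undefined (division by <=0): m = ",
         paste(m[m <= 2], collapse = ", "), call. = FALSE)
  }
  n / (m - 2)
}

#' @rdname symmetry
#' @export
symmetry_deviation <- function(m, n) abs(symmetry(m, n) - 1)

#' Tail descriptors of a lipidoid
#'
#' Computes (m, n, TC, s, d) where TC = m + n is the total carbon number
#' per tail pair, s = n/(m-2) the tail symmetry and d = |s - 1| its
#' deviation. m and n are taken from the lipidoid's provenance when
#' available, otherwise recovered from the structure via
#' [infer_tails_from_structure()]. `s_display` is s rounded to one
#' decimal for reporting; all downstream comparisons use the unrounded
#' value.
#'
#' @param lipidoid a `lipidoid`, a name string like `"1-10-8"`, or a
#'   numeric vector `c(m, n)`.
#' @return A list with `m`, `n`, `total_carbons`, `symmetry`,
#'   `s_display`, `deviation`.
#' @export
tail_descriptors <- function(lipidoid) {
  if (inherits(lipidoid, "lipidoid")) {
    m <- lipidoid$m
    n <- lipidoid$n
    if (is.na(m) || is.na(n)) {
      mn <- infer_tails_from_structure(lipidoid$mol)
      m <- mn[["m"]]
      n <- mn[["n"]]
    }
  } else if (is.character(lipidoid)) {
    p <- parse_lipidoid_name(lipidoid)
    m <- p[["m"]]
    n <- p[["n"]]
  } else {
    stopifnot(is.numeric(lipidoid), length(lipidoid) == 2L)
    m <- lipidoid[1]
    n <- lipidoid[2]
  }
  s <- symmetry(m, n)
  list(m = as.integer(m), n = as.integer(n),
       total_carbons = as.integer(m + n),
       symmetry = s, s_display = round(s, 1), deviation = abs(s - 1))
}

#' Recover (m, n) from a two-branch lipidoid structure
#'
#' Structure-only fallback when provenance is absent: the molecule is
#' cut at every amine nitrogen and every ester O-C(=O) bond; the
#' fragment containing an ester bridging oxygen contributes its carbon
#' count as m (the epoxide-derived unit), the acyl fragment its carbon
#' count as n. Ties across multiple ester arms are broken by taking the
#' largest m and n (longest chains from the ester outward).
#'
#' @param mol internal molecule of a lipidoid.
#' @return Named integer vector `c(m = ..., n = ...)`.
#' @export
#' @keywords internal
infer_tails_from_structure <- function(mol) {
  esters <- find_esters(mol)
  if (!length(esters)) stop("no ester linkage: cannot infer (m, n)",
                            call. = FALSE)
  cut <- mol
  for (es in esters) cut <- mol_remove_bond(cut, es$o_bridge, es$c_acyl)
  ns <- which(cut$elem == "N")
  for (nb in ns) {
    for (x in mol_neighbors(cut, nb)) cut <- mol_remove_bond(cut, nb, x)
  }
  comps <- mol_components(cut)
  m_cand <- integer(0)
  n_cand <- integer(0)
  bridge_os <- vapply(esters, `[[`, integer(1), "o_bridge")
  acyl_cs <- vapply(esters, `[[`, integer(1), "c_acyl")
  for (cp in comps) {
    ncarb <- sum(cut$elem[cp] == "C")
    if (any(bridge_os %in% cp)) m_cand <- c(m_cand, ncarb)
    if (any(acyl_cs %in% cp)) n_cand <- c(n_cand, ncarb)
  }
  c(m = max(m_cand), n = max(n_cand))
}

TERTIARY_KINDS <- c("dimethylamino", "diethylamino", "pyrrolidinyl",
                    "other", "none")

#' Classify an amine headgroup
#'
#' Counts primary, secondary and tertiary amine nitrogens (sp3,
#' non-amide), identifies the form of the tertiary amine (dimethylamino,
#' diethylamino, pyrrolidinyl, or other), measures the carbon spacer
#' between the primary and the tertiary nitrogen (heteroatoms on the
#' path disqualify it), and flags hydrazines (any N-N bond). The class
#' is efficacious when the headgroup is a diamine with exactly one
#' primary and one tertiary amine of one of the three ideal forms,
#' spaced by two or three carbons, and carries no hydrazine.
#'
#' @param amine a `building_block`, a SMILES string, or an internal
#'   molecule.
#' @return An object of class `headgroup_class`: list with `n_primary`,
#'   `n_secondary`, `n_tertiary`, `tertiary_kind`, `spacer`,
#'   `has_hydrazine`, `is_efficacious_class`.
#' @export
classify_headgroup <- function(amine) {
  mol <- if (inherits(amine, "building_block")) {
    as_block_mol(amine)
  } else if (is.character(amine)) {
    mol_from_smiles(canonical_smiles(amine))
  } else {
    amine
  }
  hs <- mol_implicit_h(mol)
  sp3 <- mol_is_sp3(mol)
  cc <- carbonyl_carbons(mol)
  ns <- which(mol$elem == "N")
  amine_ns <- ns[vapply(ns, function(i) {
    sp3[i] && !any(mol_neighbors(mol, i) %in% cc)
  }, logical(1))]
  deg <- mol_heavy_degree(mol)
  prim <- amine_ns[deg[amine_ns] == 1L & hs[amine_ns] == 2L]
  sec <- amine_ns[deg[amine_ns] == 2L & hs[amine_ns] == 1L]
  tert <- amine_ns[deg[amine_ns] == 3L & hs[amine_ns] == 0L]
  has_hydrazine <- nrow(mol$bonds) > 0L &&
    any(mol$elem[mol$bonds[, 1L]] == "N" & mol$elem[mol$bonds[, 2L]] == "N")
  kind <- "none"
  if (length(tert) >= 1L) {
    kind <- tertiary_amine_kind(mol, tert[1])
  }
  spacer <- NA_integer_
  if (length(prim) == 1L && length(tert) >= 1L) {
    g <- mol_graph(mol)
    best <- Inf
    best_path <- NULL
    for (t in tert) {
      sp <- igraph::shortest_paths(g, from = as.character(prim),
                                   to = as.character(t))$vpath[[1]]
      path <- as.integer(names(sp))
      if (length(path) - 2L < best) {
        best <- length(path) - 2L
        best_path <- path
      }
    }
    interior <- best_path[-c(1, length(best_path))]
    if (all(mol$elem[interior] == "C")) spacer <- length(interior)
  }
  eff <- length(prim) == 1L && length(tert) == 1L &&
    kind %in% c("dimethylamino", "diethylamino", "pyrrolidinyl") &&
    !is.na(spacer) && spacer %in% c(2L, 3L) && !has_hydrazine
  structure(list(n_primary = length(prim), n_secondary = length(sec),
                 n_tertiary = length(tert), tertiary_kind = kind,
                 spacer = spacer, has_hydrazine = has_hydrazine,
                 is_efficacious_class = eff),
            class = "headgroup_class")
}

# Form of one tertiary amine nitrogen.
tertiary_amine_kind <- function(mol, t) {
  ring <- mol_min_ring_through(mol, t)
  if (is.finite(ring)) {
    if (ring == 5) {
      # pyrrolidinyl: 5-ring, all-carbon apart from N, saturated
      nb <- mol_neighbors(mol, t)
      ring_ok <- ring_is_saturated_carbon(mol, t, 5L)
      if (ring_ok) return("pyrrolidinyl")
    }
    return("other")
  }
  hs <- mol_implicit_h(mol)
  deg <- mol_heavy_degree(mol)
  nb <- mol_neighbors(mol, t)
  is_methyl <- vapply(nb, function(i) {
    mol$elem[i] == "C" && deg[i] == 1L && hs[i] == 3L
  }, logical(1))
  is_ethyl <- vapply(nb, function(i) {
    if (mol$elem[i] != "C" || deg[i] != 2L) return(FALSE)
    nxt <- setdiff(mol_neighbors(mol, i), t)
    mol$elem[nxt] == "C" && deg[nxt] == 1L && hs[nxt] == 3L
  }, logical(1))
  if (sum(is_methyl) == 2L) return("dimethylamino")
  if (sum(is_ethyl) == 2L) return("diethylamino")
  "other"
}

# TRUE if the smallest ring through atom t has size `size`, contains no
# heteroatom besides t, and is fully saturated.
ring_is_saturated_carbon <- function(mol, t, size) {
  g <- mol_graph(mol)
  nb <- mol_neighbors(mol, t)
  pairs <- utils::combn(nb, 2L)
  g2 <- igraph::delete_vertices(g, as.character(t))
  for (k in seq_len(ncol(pairs))) {
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = as.character(pairs[1, k]),
                             to = as.character(pairs[2, k]))$vpath[[1]])
    if (!length(sp)) next
    path <- as.integer(names(sp))
    if (length(path) + 1L != size) next
    if (!all(mol$elem[path] == "C")) next
    atoms <- c(t, path)
    ok <- TRUE
    for (i in seq_along(atoms)) {
      j <- atoms[i]
      jn <- atoms[if (i == length(atoms)) 1L else i + 1L]
      b <- mol_bond_between(mol, j, jn)
      if (!length(b) || mol$bonds[b, 3L] != 1L) ok <- FALSE
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Mass of the non-degradable aminoalcohol metabolite
#'
#' Average molecular mass of the aminoalcohol obtained by hydrolysing
#' all ester linkages of the lipidoid. Small metabolites (< 500 Da)
#' are preferred for rapid elimination, so the under-500 flag is
#' reported alongside.
#'
#' @param lipidoid a `lipidoid`.
#' @return List with `mass` (Da, average), `formula`, and `under_500`.
#' @export
metabolite_mass <- function(lipidoid) {
  ms <- degrade(lipidoid, count_esters(lipidoid$mol))
  f <- ms$remnant$formula
  mass <- formula_mass(f, "average")
  list(mass = mass, formula = f, under_500 = mass < 500)
}

#' Descriptor table for a lipidoid library
#'
#' @param lib a `lipidoid_library`.
#' @param reg the registry the library was enumerated from (for
#'   headgroup classification; classes are computed once per amine).
#' @return A data.frame with one row per lipidoid: name, m, n,
#'   total_carbons, symmetry (and `s_display`), deviation, headgroup
#'   fields, metabolite mass and the under-500 flag.
#' @export
describe_library <- function(lib, reg) {
  amine_ids <- unique(vapply(lib, `[[`, character(1), "amine_id"))
  hg <- lapply(amine_ids, function(id) classify_headgroup(get_block(reg, id)))
  names(hg) <- amine_ids
  meta_cache <- new.env(parent = emptyenv())
  rows <- lapply(lib, function(l) {
    td <- tail_descriptors(l)
    h <- hg[[l$amine_id]]
    key <- paste(l$amine_id, l$epoxide_id)
    if (is.null(meta_cache[[key]])) {
      meta_cache[[key]] <- metabolite_mass(l)
    }
    mm <- meta_cache[[key]]
    data.frame(name = l$name, x = l$x, m = td$m, n = td$n,
               total_carbons = td$total_carbons, symmetry = td$symmetry,
               s_display = td$s_display, deviation = td$deviation,
               n_primary = h$n_primary, n_secondary = h$n_secondary,
               n_tertiary = h$n_tertiary, tertiary_kind = h$tertiary_kind,
               spacer = h$spacer, has_hydrazine = h$has_hydrazine,
               headgroup_efficacious = h$is_efficacious_class,
               metabolite_mass = mm$mass, metabolite_under_500 = mm$under_500,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
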