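# Internal molecular-graph layer.
#
# Molecules are held as a minimal hydrogen-suppressed graph ("lipmol"):
# a character vector of heavy-atom element symbols plus an integer bond
# matrix with columns (a1, a2, order). Parsing, canonicalization and
# SMARTS matching are delegated to Open Babel through
# ChemmineR/ChemmineOB; the graph edits that implement the virtual
# chemistry live here.

STD_VALENCE <- c(C = 4L, N = 3L, O = 2L, F = 1L, Cl = 1L, Br = 1L,
                 I = 1L, S = 2L, P = 3L, B = 3L, Si = 4L)

# Monoisotopic masses of the principal isotopes (IUPAC 2021) and
# conventional average atomic weights.
MONO_MASS <- c(H = 1.00782503, C = 12.0, N = 14.00307401, O = 15.99491462,
               F = 18.99840316, Cl = 34.96885268, Br = 78.9183376,
               I = 126.9044719, S = 31.97207117, P = 30.97376200)
AVG_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
              Cl = 35.45, Br = 79.904, I = 126.904, S = 32.06, P = 30.974)
PROTON_MASS <- 1.00727646

empty_bonds <- function() {
  matrix(integer(0), ncol = 3, dimnames = list(NULL, c("a1", "a2", "order")))
}

new_lipmol <- function(elem, bonds = empty_bonds()) {
  if (is.data.frame(bonds)) bonds <- as.matrix(bonds)
  if (!nrow(bonds)) bonds <- empty_bonds()
  storage.mode(bonds) <- "integer"
  colnames(bonds) <- c("a1", "a2", "order")
  structure(list(elem = as.character(elem), bonds = bonds), class = "lipmol")
}

n_atoms <- function(mol) length(mol$elem)

#' @noRd
mol_from_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  sdf <- try(suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"))),
    silent = TRUE)
  if (inherits(sdf, "try-error") || !nzchar(trimws(sdf))) {
    stop("unparseable structure: ", smiles, call. = FALSE)
  }
  lines <- strsplit(sdf, "\n")[[1]]
  n_at <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  n_bd <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(n_at) || n_at == 0L) {
    stop("unparseable structure: ", smiles, call. = FALSE)
  }
  atom_lines <- lines[5:(4 + n_at)]
  elem <- trimws(substr(atom_lines, 32, 34))
  bonds <- empty_bonds()
  if (!is.na(n_bd) && n_bd > 0L) {
    bond_lines <- lines[(5 + n_at):(4 + n_at + n_bd)]
    bonds <- cbind(a1 = as.integer(substr(bond_lines, 1, 3)),
                   a2 = as.integer(substr(bond_lines, 4, 6)),
                   order = as.integer(substr(bond_lines, 7, 9)))
  }
  new_lipmol(elem, bonds)
}

# Sum of bond orders incident on each atom.
mol_bond_order_sum <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(integer(n_atoms(mol)))
  ends <- c(b[, 1L], b[, 2L])
  w <- c(b[, 3L], b[, 3L])
  tabulate(rep.int(ends, w), nbins = n_atoms(mol))
}

# Implicit hydrogen count per heavy atom, from standard valences.
mol_implicit_h <- function(mol) {
  val <- STD_VALENCE[mol$elem]
  h <- val - mol_bond_order_sum(mol)
  h[is.na(h)] <- 0L
  pmax(as.integer(h), 0L)
}

# Named element-count vector including implicit hydrogens, Hill order.
mol_formula <- function(mol) {
  counts <- table(mol$elem)
  f <- stats::setNames(as.integer(counts), names(counts))
  hn <- sum(mol_implicit_h(mol))
  f["H"] <- (if ("H" %in% names(f)) f[["H"]] else 0L) + hn
  hill_order(f)
}

hill_order <- function(f) {
  f <- f[f > 0L]
  els <- names(f)
  rest <- sort(setdiff(els, c("C", "H")))
  ord <- c(intersect(c("C", "H"), els), rest)
  f[ord]
}

#' Format an element-count vector as a molecular formula string
#'
#' @param f named integer vector of element counts (e.g. `c(C = 42, H = 82,
#'   N = 2, O = 4)`).
#' @return A single string such as `"C42H82N2O4"`.
#' @export
formula_string <- function(f) {
  f <- hill_order(f)
  paste0(names(f), ifelse(f > 1L, f, ""), collapse = "")
}

#' Parse a molecular formula string into element counts
#'
#' @param s formula string, e.g. `"C25H54N2O2"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(s) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  parts <- regmatches(s, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  els <- sub("[0-9]*$", "", parts)
  ns <- sub("^[A-Z][a-z]?", "", parts)
  ns <- ifelse(nzchar(ns), as.integer(ns), 1L)
  hill_order(stats::setNames(ns, els))
}

# Mass of a formula from the isotope/atomic-weight tables.
formula_mass <- function(f, type = c("monoisotopic", "average")) {
  type <- match.arg(type)
  tab <- if (type == "monoisotopic") MONO_MASS else AVG_MASS
  if (!all(names(f) %in% names(tab))) {
    stop("unknown element symbol: ",
         paste(setdiff(names(f), names(tab)), collapse = ", "), call. = FALSE)
  }
  sum(tab[names(f)] * f)
}

# V2000 molfile text for a lipmol; coords default to zero (connectivity
# only) or can be an n x 3 matrix.
mol_molblock <- function(mol, coords = NULL, title = "") {
  n <- n_atoms(mol)
  if (is.null(coords)) coords <- matrix(0, n, 3)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    n, nrow(mol$bonds))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   coords[, 1], coords[, 2], coords[, 3], mol$elem)
  bonds <- character(0)
  if (nrow(mol$bonds)) {
    bonds <- sprintf("%3d%3d%3d  0  0  0  0", mol$bonds[, 1L],
                     mol$bonds[, 2L], mol$bonds[, 3L])
  }
  paste(c(title, "  dblipidoid", "", counts, atoms, bonds, "M  END"),
        collapse = "\n")
}

# Canonical SMILES of one lipmol via Open Babel.
mol_canonical_smiles <- function(mol) {
  sdf <- paste0(mol_molblock(mol), "\n$$$$\n")
  out <- ChemmineOB::convertFormat("SDF", "CAN", sdf)
  strsplit(trimws(out), "[\t ]")[[1]][1]
}

# Batched canonical SMILES for a list of lipmols (one Open Babel call).
mol_canonical_smiles_batch <- function(mols) {
  if (!length(mols)) return(character(0))
  sdf <- paste0(vapply(mols, mol_molblock, character(1)),
                collapse = "\n$$$$\n")
  sdf <- paste0(sdf, "\n$$$$\n")
  out <- ChemmineOB::convertFormat("SDF", "CAN", sdf)
  lines <- strsplit(out, "\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  vapply(strsplit(trimws(lines), "[\t ]"), `[`, character(1), 1)
}

#' Canonicalize a SMILES string
#'
#' Returns the Open Babel canonical SMILES. With `neutralize = TRUE`
#' (the default) +1/-1 formal charges are neutralized and, if the input
#' is multi-component (a salt), only the largest component is kept, so a
#' hydrochloride is reduced to its free base.
#'
#' @param smiles a SMILES string.
#' @param neutralize neutralize charges and strip counter-ions.
#' @return Canonical SMILES string.
#' @export
canonical_smiles <- function(smiles, neutralize = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  args <- list("SMI", "CAN", paste0(smiles, "\n"))
  if (neutralize) {
    args$options <- data.frame(names = "neutralize", args = "",
                               stringsAsFactors = FALSE)
  }
  out <- try(suppressWarnings(
    do.call(ChemmineOB::convertFormat, args)), silent = TRUE)
  if (inherits(out, "try-error") || !nzchar(trimws(out))) {
    stop("unparseable structure: ", smiles, call. = FALSE)
  }
  can <- strsplit(trimws(out), "[\t ]")[[1]][1]
  parts <- strsplit(can, ".", fixed = TRUE)[[1]]
  if (neutralize && length(parts) > 1L) {
    sizes <- vapply(parts, function(p) n_atoms(mol_from_smiles(p)), integer(1))
    can <- canonical_smiles(parts[which.max(sizes)], neutralize = FALSE)
  }
  can
}

# igraph view of the heavy-atom skeleton; vertices named "1".."n".
mol_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  if (nrow(mol$bonds)) {
    g <- igraph::add_edges(g, as.vector(t(mol$bonds[, 1:2, drop = FALSE])))
  }
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n_atoms(mol))))
}

mol_neighbors <- function(mol, i) {
  b <- mol$bonds
  c(b[b[, 1L] == i, 2L], b[b[, 2L] == i, 1L])
}

mol_heavy_degree <- function(mol) {
  tabulate(c(mol$bonds[, 1L], mol$bonds[, 2L]), nbins = n_atoms(mol))
}

# TRUE for atoms participating only in single bonds.
mol_is_sp3 <- function(mol) {
  out <- rep(TRUE, n_atoms(mol))
  b <- mol$bonds[mol$bonds[, 3L] > 1L, , drop = FALSE]
  out[unique(c(b[, 1L], b[, 2L]))] <- FALSE
  out
}

mol_bond_between <- function(mol, i, j) {
  b <- mol$bonds
  which((b[, 1L] == i & b[, 2L] == j) | (b[, 1L] == j & b[, 2L] == i))
}

# Size of the smallest ring through atom `a`, or Inf if acyclic there.
mol_min_ring_through <- function(mol, a) {
  nb <- mol_neighbors(mol, a)
  if (length(nb) < 2L) return(Inf)
  g <- mol_graph(mol)
  g2 <- igraph::delete_vertices(g, as.character(a))
  best <- Inf
  pairs <- utils::combn(nb, 2L)
  for (k in seq_len(ncol(pairs))) {
    d <- igraph::distances(g2, v = as.character(pairs[1, k]),
                           to = as.character(pairs[2, k]))[1, 1]
    if (is.finite(d)) best <- min(best, d + 2)
  }
  best
}

mol_is_connected <- function(mol) {
  if (n_atoms(mol) <= 1L) return(TRUE)
  igraph::is_connected(mol_graph(mol))
}

mol_components <- function(mol) {
  comp <- igraph::components(mol_graph(mol))
  split(seq_len(n_atoms(mol)), comp$membership)
}

# Extract the sub-molecule induced by `atoms` (renumbered compactly).
mol_subset <- function(mol, atoms) {
  atoms <- sort(atoms)
  b <- mol$bonds
  keep <- b[, 1L] %in% atoms & b[, 2L] %in% atoms
  b <- b[keep, , drop = FALSE]
  b[, 1L] <- match(b[, 1L], atoms)
  b[, 2L] <- match(b[, 2L], atoms)
  new_lipmol(mol$elem[atoms], b)
}

# Disjoint union of two molecules; returns the merged molecule and the
# index offset applied to atoms of `m2`.
mol_merge <- function(m1, m2) {
  off <- n_atoms(m1)
  b2 <- m2$bonds
  b2[, 1L] <- b2[, 1L] + off
  b2[, 2L] <- b2[, 2L] + off
  list(mol = new_lipmol(c(m1$elem, m2$elem), rbind(m1$bonds, b2)),
       offset = off)
}

mol_add_bond <- function(mol, i, j, order = 1L) {
  mol$bonds <- rbind(mol$bonds,
                     c(as.integer(i), as.integer(j), as.integer(order)))
  mol
}

mol_remove_bond <- function(mol, i, j) {
  k <- mol_bond_between(mol, i, j)
  if (!length(k)) stop("no bond between atoms ", i, " and ", j, call. = FALSE)
  mol$bonds <- mol$bonds[-k, , drop = FALSE]
  mol
}

mol_remove_atoms <- function(mol, atoms) {
  keep <- setdiff(seq_len(n_atoms(mol)), atoms)
  mol_subset(mol, keep)
}

mol_add_atom <- function(mol, elem) {
  mol$elem <- c(mol$elem, elem)
  mol
}

# lipmol -> ChemmineR SDFset (for SMARTS matching or SDF export).
mol_to_sdfset <- function(mol, title = "mol") {
  lines <- c(strsplit(mol_molblock(mol, title = title), "\n")[[1]], "$$$$")
  str <- methods::as(lines, "SDFstr")
  methods::as(str, "SDFset")
}

# Count of SMARTS matches via Open Babel (used mostly as a cross-check).
mol_smarts_count <- function(mol, smarts, unique_matches = TRUE) {
  sdf <- mol_to_sdfset(mol)
  as.integer(ChemmineR::smartsSearchOB(sdf, smarts,
                                       uniqueMatches = unique_matches))
}

#' @export
print.lipmol <- function(x, ...) {
  cat("<lipmol> ", formula_string(mol_formula(x)), ": ",
      n_atoms(x), " heavy atoms, ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}
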