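# Functional-group perception on the heavy-atom graph.
#
# These locate the reactive sites the three-component reaction uses:
# terminal 1,2-epoxides, acyl chlorides, substitutable amine N-H sites,
# free hydroxyls and ester linkages.

# Carbons double-bonded to an oxygen.
carbonyl_carbons <- function(mol) {
  b <- mol$bonds[mol$bonds[, 3L] == 2L, , drop = FALSE]
  if (!nrow(b)) return(integer(0))
  e1 <- mol$elem[b[, 1L]]
  e2 <- mol$elem[b[, 2L]]
  unique(c(b[e1 == "C" & e2 == "O", 1L], b[e2 == "C" & e1 == "O", 2L]))
}

# Epoxide groups: list of list(o, c_term, c_sub). `c_term` is the less
# substituted (terminal CH2) ring carbon, the site attacked by the
# nucleophile in an SN2 ring-opening.
find_epoxides <- function(mol) {
  deg <- mol_heavy_degree(mol)
  hs <- mol_implicit_h(mol)
  out <- list()
  for (o in which(mol$elem == "O")) {
    nb <- mol_neighbors(mol, o)
    if (length(nb) != 2L) next
    if (!all(mol$elem[nb] == "C")) next
    ring_bond <- mol_bond_between(mol, nb[1], nb[2])
    if (!length(ring_bond)) next
    if (mol$bonds[ring_bond, 3L] != 1L) next
    term <- nb[hs[nb] == 2L & deg[nb] == 2L]
    sub <- setdiff(nb, term)
    if (length(term) == 2L) { # ethylene oxide: both terminal
      term <- min(nb); sub <- max(nb)
    }
    if (length(term) != 1L) { # internal epoxide: no terminal CH2
      term <- integer(0)
    }
    out[[length(out) + 1L]] <- list(o = o,
                                    c_term = if (length(term)) term else NA_integer_,
                                    c_sub = if (length(term)) sub else NA_integer_)
  }
  out
}

# Acyl chloride groups: list(c = carbonyl carbon, cl = chlorine).
find_acyl_chlorides <- function(mol) {
  cc <- carbonyl_carbons(mol)
  out <- list()
  for (c0 in cc) {
    nb <- mol_neighbors(mol, c0)
    cl <- nb[mol$elem[nb] == "Cl"]
    if (length(cl) == 1L) out[[length(out) + 1L]] <- list(c = c0, cl = cl)
  }
  out
}

# Substitutable amine sites: sp3, non-amide, uncharged N carrying >= 1
# hydrogen. Returns data.frame(atom, h).
amine_sites <- function(mol) {
  hs <- mol_implicit_h(mol)
  sp3 <- mol_is_sp3(mol)
  cc <- carbonyl_carbons(mol)
  ns <- which(mol$elem == "N")
  keep <- vapply(ns, function(n) {
    sp3[n] && hs[n] >= 1L && !any(mol_neighbors(mol, n) %in% cc)
  }, logical(1))
  data.frame(atom = ns[keep], h = hs[ns[keep]])
}

# Free hydroxyl oxygens (one C neighbour, not part of a carboxyl/ester).
find_hydroxyls <- function(mol) {
  hs <- mol_implicit_h(mol)
  cc <- carbonyl_carbons(mol)
  out <- integer(0)
  for (o in which(mol$elem == "O")) {
    nb <- mol_neighbors(mol, o)
    if (length(nb) == 1L && mol$elem[nb] == "C" && hs[o] == 1L &&
        !(nb %in% cc)) {
      out <- c(out, o)
    }
  }
  out
}

# Ester linkages: list(o_bridge, c_acyl, c_alkyl) for every
# C(=O)-O-C bridge.
find_esters <- function(mol) {
  cc <- carbonyl_carbons(mol)
  out <- list()
  for (o in which(mol$elem == "O")) {
    nb <- mol_neighbors(mol, o)
    if (length(nb) != 2L || !all(mol$elem[nb] == "C")) next
    ords <- vapply(nb, function(x) {
      mol$bonds[mol_bond_between(mol, o, x), 3L]
    }, integer(1))
    if (any(ords != 1L)) next
    acyl <- nb[nb %in% cc]
    alkyl <- nb[!nb %in% cc]
    if (length(acyl) == 1L && length(alkyl) == 1L) {
      out[[length(out) + 1L]] <- list(o_bridge = o, c_acyl = acyl,
                                      c_alkyl = alkyl)
    }
  }
  out
}

count_esters <- function(mol) length(find_esters(mol))
count_hydroxyls <- function(mol) length(find_hydroxyls(mol))

# Total substitutable N-H hydrogens (capacity for body tails).
amine_nh_capacity <- function(mol) {
  s <- amine_sites(mol)
  if (!nrow(s)) 0L else sum(s$h)
}

# TRUE if the molecule is a single, linear, saturated, acyclic alkyl
# chain apart from the acyl chloride carbonyl.
is_linear_saturated_acyl <- function(mol) {
  acyl <- find_acyl_chlorides(mol)
  if (length(acyl) != 1L) return(FALSE)
  if (!mol_is_connected(mol)) return(FALSE)
  # acyclic <=> tree
  if (nrow(mol$bonds) != n_atoms(mol) - 1L) return(FALSE)
  # only allowed double bond is the carbonyl
  dbl <- mol$bonds[mol$bonds[, 3L] > 1L, , drop = FALSE]
  if (nrow(dbl) != 1L) return(FALSE)
  if (!acyl[[1]]$c %in% dbl[, 1:2]) return(FALSE)
  # unbranched: every carbon has at most two carbon neighbours
  for (c0 in which(mol$elem == "C")) {
    nb <- mol_neighbors(mol, c0)
    if (sum(mol$elem[nb] == "C") > 2L) return(FALSE)
  }
  TRUE
}
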