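# Lipid packing-parameter estimation P = V / (A * L).
#
# A single low-energy conformer is built deterministically for a given
# seed: heavy atoms are grown as a seeded self-avoiding walk on a
# tetrahedral (diamond) lattice — which gives ideal sp3 bond lengths and
# angles and, through the seeded choice among free lattice directions, a
# reproducible sample of torsional space — hydrogens are added on the
# remaining lattice directions, and the structure is relaxed with up to
# 4000 steps of MMFF94 minimization (Open Babel), which is
# deterministic for a fixed starting geometry. From the conformer:
#   V  = van der Waals molecular volume (union of atomic spheres,
#        evaluated on a grid),
#   A  = cross-section area of the polar head (convex hull of the head
#        atoms' vdW circles projected on the plane perpendicular to the
#        principal tail axis),
#   L  = average tail length (through-space distance from each tail
#        attachment atom to its terminal carbon).
# P > 1 indicates a cone-shaped lipid (bulky tails, small head), the
# geometry associated with efficient endosomal escape.

VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
               Cl = 1.75, Br = 1.85, I = 1.98, S = 1.80, P = 1.80)

# Tetrahedral unit vectors of the diamond lattice.
TET_DIRS <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
  sqrt(3)

#' Build and minimize a 3D conformer
#'
#' Deterministically embeds a molecule for a given seed (seeded
#' self-avoiding walk on a tetrahedral lattice, see the package
#' vignette) and relaxes it by MMFF94 energy minimization. The same
#' structure, seed and step count always yield identical coordinates.
#'
#' @param structure SMILES string or `lipidoid`.
#' @param seed integer seed selecting the torsional sample.
#' @param steps maximal minimization steps (default 4000).
#' @return Object of class `conformer`: `elem` and `coords` (all atoms,
#'   hydrogens appended after the heavy atoms), `mol` (heavy-atom
#'   graph), `n_heavy`, `seed`, `steps`.
#' @export
embed_and_minimize <- function(structure, seed = 0L, steps = 4000L) {
  mol <- if (inherits(structure, "lipidoid")) structure$mol
  else mol_from_smiles(structure)
  raw <- embed_on_lattice(mol, seed = seed)
  minimized <- minimize_mmff94(mol, raw$elem, raw$coords, steps = steps)
  structure(list(elem = raw$elem, coords = minimized, mol = mol,
                 n_heavy = n_atoms(mol), seed = as.integer(seed),
                 steps = as.integer(steps)),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer> ", length(x$elem), " atoms (", x$n_heavy,
      " heavy), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Seeded self-avoiding placement of heavy atoms on a diamond lattice,
# plus hydrogens on the free lattice directions. Runs inside a private
# RNG stream so the caller's RNG state is untouched.
embed_on_lattice <- function(mol, seed, bond_len = 1.54, h_len = 1.09,
                             max_restarts = 50L) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  for (attempt in seq_len(max_restarts)) {
    set.seed(as.integer(seed) * 1000L + attempt)
    res <- try(lattice_walk(mol, bond_len), silent = TRUE)
    if (!inherits(res, "try-error")) {
      return(add_lattice_hydrogens(mol, res, bond_len, h_len))
    }
  }
  stop("embedding failed after ", max_restarts, " restarts", call. = FALSE)
}

lattice_walk <- function(mol, bond_len) {
  n <- n_atoms(mol)
  coords <- matrix(NA_real_, n, 3)
  parity <- integer(n)
  coords[1, ] <- 0
  parity[1] <- 1L
  placed <- 1L
  queue <- 1L
  while (length(queue)) {
    p <- queue[1]
    queue <- queue[-1]
    nb <- mol_neighbors(mol, p)
    todo <- nb[is.na(coords[nb, 1])]
    if (!length(todo)) next
    for (a in todo[sample.int(length(todo))]) {
      placed_nb <- nb[!is.na(coords[nb, 1])]
      used <- used_directions(coords, p, placed_nb, parity[p], bond_len)
      free <- setdiff(seq_len(4L), used)
      cand <- free[sample.int(length(free))]
      pos <- NULL
      for (relax in c(2.0, 1.8)) {
        for (k in cand) {
          trial <- coords[p, ] + parity[p] * bond_len * TET_DIRS[k, ]
          others <- setdiff(which(!is.na(coords[, 1])), p)
          if (!length(others)) {
            pos <- trial
            break
          }
          d2 <- colSums((t(coords[others, , drop = FALSE]) - trial)^2)
          if (min(d2) >= relax^2) {
            pos <- trial
            break
          }
        }
        if (!is.null(pos)) break
      }
      if (is.null(pos)) stop("walk stuck", call. = FALSE)
      coords[a, ] <- pos
      parity[a] <- -parity[p]
      placed <- placed + 1L
      queue <- c(queue, a)
    }
  }
  if (anyNA(coords)) stop("disconnected input", call. = FALSE)
  list(coords = coords, parity = parity)
}

# Which of the four lattice directions around atom p are taken by its
# already-placed neighbours.
used_directions <- function(coords, p, placed_nb, par, bond_len) {
  if (!length(placed_nb)) return(integer(0))
  used <- integer(0)
  for (q in placed_nb) {
    v <- (coords[q, ] - coords[p, ]) / (par * bond_len)
    k <- which.max(TET_DIRS %*% v)
    used <- c(used, k)
  }
  unique(used)
}

add_lattice_hydrogens <- function(mol, walk, bond_len, h_len) {
  hs <- mol_implicit_h(mol)
  coords <- walk$coords
  elem <- mol$elem
  h_coords <- NULL
  for (a in seq_len(n_atoms(mol))) {
    if (hs[a] == 0L) next
    nb <- mol_neighbors(mol, a)
    used <- used_directions(coords, a, nb, walk$parity[a], bond_len)
    free <- setdiff(seq_len(4L), used)
    need <- min(hs[a], length(free))
    for (k in utils::head(free, need)) {
      h_coords <- rbind(h_coords,
                        coords[a, ] + walk$parity[a] * h_len * TET_DIRS[k, ])
    }
  }
  if (!is.null(h_coords)) {
    coords <- rbind(coords, h_coords)
    elem <- c(elem, rep("H", nrow(h_coords)))
  }
  list(elem = elem, coords = coords)
}

# MMFF94 relaxation through Open Babel; deterministic for fixed input.
minimize_mmff94 <- function(mol, elem, coords, steps) {
  full <- new_lipmol(elem, grow_bonds_with_h(mol, elem, coords))
  sdf_in <- paste0(mol_molblock(full, coords = coords, title = "conf"),
                   "\n$$$$\n")
  out <- ChemmineOB::convertFormat(
    "SDF", "SDF", sdf_in,
    options = data.frame(names = c("minimize", "ff", "steps"),
                         args = c("", "MMFF94", as.character(steps)),
                         stringsAsFactors = FALSE))
  parse_molblock_coords(out, length(elem))
}

# Bond matrix extended with the explicit X-H bonds implied by the
# hydrogen block appended to `elem`.
grow_bonds_with_h <- function(mol, elem, coords) {
  n_h <- length(elem) - n_atoms(mol)
  if (n_h == 0L) return(mol$bonds)
  h_idx <- n_atoms(mol) + seq_len(n_h)
  heavy <- seq_len(n_atoms(mol))
  extra <- t(vapply(h_idx, function(h) {
    d2 <- colSums((t(coords[heavy, , drop = FALSE]) - coords[h, ])^2)
    c(which.min(d2), h, 1L)
  }, numeric(3)))
  storage.mode(extra) <- "integer"
  colnames(extra) <- c("a1", "a2", "order")
  rbind(mol$bonds, extra)
}

parse_molblock_coords <- function(sdf_text, n) {
  lines <- strsplit(sdf_text, "\n")[[1]]
  atom_lines <- lines[5:(4 + n)]
  xyz <- matrix(NA_real_, n, 3)
  xyz[, 1] <- as.numeric(substr(atom_lines, 1, 10))
  xyz[, 2] <- as.numeric(substr(atom_lines, 11, 20))
  xyz[, 3] <- as.numeric(substr(atom_lines, 21, 30))
  xyz
}

#' Default polar-head atom selection
#'
#' The ionizable amine nitrogens, every heavy atom within two bonds of
#' them, and the ester oxygens (bridging and carbonyl). Exposed so other
#' head conventions can be passed to [packing_parameter()] directly.
#'
#' @param mol heavy-atom molecule of a conformer (`conf$mol`).
#' @return Integer vector of heavy-atom indices.
#' @export
auto_head_atoms <- function(mol) {
  ns <- amine_like_nitrogens(mol)
  g <- mol_graph(mol)
  near <- integer(0)
  if (length(ns)) {
    d <- igraph::distances(g, v = as.character(ns))
    near <- which(apply(d, 2, min) <= 2)
  }
  est <- find_esters(mol)
  e_at <- unlist(lapply(est, function(e) {
    co <- mol_neighbors(mol, e$c_acyl)
    co <- co[mol$elem[co] == "O" &
               vapply(co, function(o)
                 mol$bonds[mol_bond_between(mol, e$c_acyl, o), 3L] == 2L,
                 logical(1))]
    c(e$o_bridge, co)
  }))
  sort(unique(c(ns, near, e_at)))
}

# sp3 nitrogens not adjacent to a carbonyl (the protonatable amines).
amine_like_nitrogens <- function(mol) {
  sp3 <- mol_is_sp3(mol)
  cc <- carbonyl_carbons(mol)
  ns <- which(mol$elem == "N")
  ns[vapply(ns, function(i) {
    sp3[i] && !any(mol_neighbors(mol, i) %in% cc)
  }, logical(1))]
}

#' Default tail definitions
#'
#' Removes the head atoms from the heavy-atom graph; each remaining
#' component attached to the head contributes one tail per terminal
#' carbon at graph distance >= 4 from the attachment atom (short linker
#' remnants produce none).
#'
#' @param mol heavy-atom molecule.
#' @param head_atoms head selection (default [auto_head_atoms()]).
#' @return List of `c(attach, terminal)` index pairs.
#' @export
auto_tails <- function(mol, head_atoms = auto_head_atoms(mol)) {
  rest <- setdiff(seq_len(n_atoms(mol)), head_atoms)
  if (!length(rest)) return(list())
  sub_map <- rest
  sub <- mol_subset(mol, rest)
  comps <- mol_components(sub)
  g <- mol_graph(sub)
  deg_full <- mol_heavy_degree(mol)
  tails <- list()
  for (cp in comps) {
    orig <- sub_map[cp]
    attach <- orig[vapply(orig, function(a) {
      any(mol_neighbors(mol, a) %in% head_atoms)
    }, logical(1))]
    if (!length(attach)) next
    attach <- min(attach)
    a_sub <- match(attach, sub_map)
    d <- igraph::distances(g, v = as.character(a_sub))[1, ]
    term_sub <- cp[mol$elem[orig] == "C" & deg_full[orig] == 1L]
    for (t in term_sub) {
      if (is.finite(d[as.character(t)]) && d[as.character(t)] >= 4) {
        tails[[length(tails) + 1L]] <- c(attach = attach,
                                         terminal = sub_map[t])
      }
    }
  }
  tails
}

#' Packing parameter of a conformer
#'
#' Computes P = V / (A * L) from a 3D conformer: the van der Waals
#' volume V on a grid, the projected cross-section area A of the polar
#' head, and the mean tail length L. See the package vignette for the
#' conventions.
#'
#' @param conf a `conformer` from [embed_and_minimize()].
#' @param head_atoms heavy-atom indices of the polar head (default
#'   [auto_head_atoms()]).
#' @param tails list of `c(attach, terminal)` pairs (default
#'   [auto_tails()]).
#' @param grid grid spacing in Angstrom for the volume integration
#'   (default 0.2).
#' @return Object of class `packing_result` with `P`, `V` (A^3), `A`
#'   (A^2), `L` (A), `seed`, `shape_class` (cone / cylinder-like /
#'   inverted-cone), and the atom selections used.
#' @export
packing_parameter <- function(conf, head_atoms = NULL, tails = NULL,
                              grid = 0.2) {
  mol <- conf$mol
  if (is.null(head_atoms)) head_atoms <- auto_head_atoms(mol)
  if (is.null(tails)) tails <- auto_tails(mol, head_atoms)
  if (!length(head_atoms)) stop("empty head atom set", call. = FALSE)
  if (!length(tails)) stop("no tails identified", call. = FALSE)
  tail_atoms <- setdiff(seq_len(n_atoms(mol)), head_atoms)
  if (!length(tail_atoms)) stop("head and tail sets must be disjoint",
                                call. = FALSE)
  V <- vdw_volume(conf$elem, conf$coords, grid = grid)
  A <- head_cross_section(conf, head_atoms, tail_atoms)
  L <- mean(vapply(tails, function(t) {
    sqrt(sum((conf$coords[t[1], ] - conf$coords[t[2], ])^2))
  }, numeric(1)))
  P <- V / (A * L)
  shape <- if (P > 1.05) "cone" else if (P < 0.95) "inverted-cone"
  else "cylinder-like"
  structure(list(P = P, V = V, A = A, L = L, seed = conf$seed,
                 shape_class = shape, head_atoms = head_atoms,
                 tails = tails, grid = grid),
            class = "packing_result")
}

#' @export
print.packing_result <- function(x, ...) {
  cat(sprintf("<packing_result> P = %.2f (%s): V = %.1f A^3, A = %.1f A^2, L = %.1f A, seed %d\n",
              x$P, x$shape_class, x$V, x$A, x$L, x$seed))
  invisible(x)
}

# Union-of-spheres volume on a regular grid.
vdw_volume <- function(elem, coords, grid = 0.2) {
  r <- VDW_RADII[elem]
  if (anyNA(r)) stop("no van der Waals radius for: ",
                     paste(unique(elem[is.na(r)]), collapse = ", "),
                     call. = FALSE)
  lo <- apply(coords, 2, min) - max(r) - grid
  hi <- apply(coords, 2, max) + max(r) + grid
  nx <- ceiling((hi - lo) / grid) + 1L
  occ <- array(FALSE, dim = nx)
  ax <- lo[1] + (seq_len(nx[1]) - 1L) * grid
  ay <- lo[2] + (seq_len(nx[2]) - 1L) * grid
  az <- lo[3] + (seq_len(nx[3]) - 1L) * grid
  for (i in seq_along(elem)) {
    ri <- r[i]
    ix <- which(abs(ax - coords[i, 1]) <= ri)
    iy <- which(abs(ay - coords[i, 2]) <= ri)
    iz <- which(abs(az - coords[i, 3]) <= ri)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (ax[ix] - coords[i, 1])^2
    dy2 <- (ay[iy] - coords[i, 2])^2
    dz2 <- (az[iz] - coords[i, 3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= ri^2
    occ[ix, iy, iz] <- occ[ix, iy, iz] | inside
  }
  sum(occ) * grid^3
}

# Area of the polar head: convex hull of the head atoms' vdW circles
# projected on the plane perpendicular to the first principal axis of
# the tail atoms.
head_cross_section <- function(conf, head_atoms, tail_atoms,
                               n_circle = 24L) {
  tail_xyz <- conf$coords[tail_atoms, , drop = FALSE]
  axis <- stats::prcomp(tail_xyz, center = TRUE)$rotation[, 1]
  basis <- plane_basis(axis)
  pts <- conf$coords[head_atoms, , drop = FALSE] %*% basis
  r <- VDW_RADII[conf$elem[head_atoms]]
  theta <- seq(0, 2 * pi, length.out = n_circle + 1L)[-1L]
  circ <- cbind(cos(theta), sin(theta))
  all_pts <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
    sweep(circ * r[i], 2, pts[i, ], "+")
  }))
  hull <- grDevices::chull(all_pts)
  if (length(hull) < 3L) {
    stop("degenerate head projection; enlarge the head atom set",
         call. = FALSE)
  }
  polygon_area(all_pts[hull, , drop = FALSE])
}

# Orthonormal basis of the plane perpendicular to `axis`.
plane_basis <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * axis) * axis
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(axis[2] * e2[3] - axis[3] * e2[2],
          axis[3] * e2[1] - axis[1] * e2[3],
          axis[1] * e2[2] - axis[2] * e2[1])
  cbind(e2, e3)
}

# Shoelace formula.
polygon_area <- function(p) {
  x <- p[, 1]
  y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Median packing parameter over several seeds
#'
#' @param structure SMILES or `lipidoid`.
#' @param seeds integer vector of embedding seeds.
#' @param steps minimization steps per conformer.
#' @param ... passed to [packing_parameter()].
#' @return List with `median_P`, `P` (per seed) and `results`.
#' @export
packing_profile <- function(structure, seeds = 0:4, steps = 4000L, ...) {
  results <- lapply(seeds, function(s) {
    packing_parameter(embed_and_minimize(structure, seed = s,
                                         steps = steps), ...)
  })
  P <- vapply(results, `[[`, numeric(1), "P")
  list(median_P = stats::median(P), P = P, results = results)
}

#' Reference SMILES of the benchmark lipid DLin-MC3-DMA
#'
#' Stereochemistry-free SMILES of MC3 (dilinoleylmethanol esterified
#' with 4-(dimethylamino)butanoic acid), the clinically approved
#' benchmark ionizable lipid.
#'
#' @return SMILES string.
#' @export
mc3_smiles <- function() {
  "CCCCCC=CCC=CCCCCCCCCC(CCCCCCCCC=CCC=CCCCCC)OC(=O)CCCN(C)C"
}
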