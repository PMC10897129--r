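# Building-block registries: amines (headgroups), alkyl epoxides (body
# tails) and acyl chlorides (branch tails) that parameterize a lipidoid
# library design.

BLOCK_KINDS <- c("amine", "epoxide", "acyl_chloride")

#' Create a building block
#'
#' A building block is an amine, a terminal alkyl epoxide, or an acyl
#' chloride, held with its canonicalized structure and declared carbon
#' count. Structures are stored stereochemistry-free and as the free
#' base: salt forms (e.g. hydrochlorides) are neutralized and stripped
#' of counter-ions on construction.
#'
#' @param id short unique identifier, e.g. `"amine-1"`, `"epoxide-10"`.
#' @param kind one of `"amine"`, `"epoxide"`, `"acyl_chloride"`.
#' @param structure SMILES string.
#' @param carbon_count declared total carbon count. For an epoxide this
#'   is the body-tail length m; for an acyl chloride the branch-tail
#'   length n, which includes the carbonyl carbon.
#' @param label free-text chemical name.
#' @param salt_form logical; `TRUE` if the input structure was a salt.
#' @return An object of class `building_block`.
#' @export
building_block <- function(id, kind, structure, carbon_count,
                           label = "", salt_form = FALSE) {
  kind <- match.arg(kind, BLOCK_KINDS)
  structure <- canonical_smiles(structure, neutralize = TRUE)
  obj <- structure(list(id = as.character(id), kind = kind,
                        structure = structure,
                        carbon_count = as.integer(carbon_count),
                        label = as.character(label),
                        salt_form = isTRUE(as.logical(salt_form))),
                   class = "building_block")
  obj
}

#' Validate a building block
#'
#' Checks the structural invariants of a block: the structure must parse
#' to a single connected molecule; an epoxide must carry exactly one
#' terminal 1,2-epoxide and its declared carbon count must equal the
#' parsed carbon total; an acyl chloride must carry exactly one -C(=O)Cl
#' on a linear saturated chain; an amine must have at least one
#' substitutable N-H.
#'
#' @param block a `building_block`.
#' @return Character vector of violations; empty if the block is valid.
#' @export
validate_block <- function(block) {
  out <- character(0)
  mol <- try(mol_from_smiles(block$structure), silent = TRUE)
  if (inherits(mol, "try-error")) {
    return("unparseable structure")
  }
  if (!mol_is_connected(mol)) {
    out <- c(out, "structure is not a single connected molecule")
  }
  n_c <- sum(mol$elem == "C")
  if (block$kind == "epoxide") {
    ep <- find_epoxides(mol)
    if (length(ep) != 1L) {
      out <- c(out, sprintf("expected exactly one epoxide group, found %d",
                            length(ep)))
    } else if (is.na(ep[[1]]$c_term)) {
      out <- c(out, "epoxide is not terminal (no 1,2-CH2 ring carbon)")
    }
    if (n_c != block$carbon_count) {
      out <- c(out, sprintf("carbon_count %d disagrees with structure (%d C)",
                            block$carbon_count, n_c))
    }
  } else if (block$kind == "acyl_chloride") {
    ac <- find_acyl_chlorides(mol)
    if (length(ac) != 1L) {
      out <- c(out, sprintf("expected exactly one acyl chloride group, found %d",
                            length(ac)))
    } else if (!is_linear_saturated_acyl(mol)) {
      out <- c(out, "acyl chain is not linear and saturated")
    }
    if (n_c != block$carbon_count) {
      out <- c(out, sprintf("carbon_count %d disagrees with structure (%d C)",
                            block$carbon_count, n_c))
    }
  } else { # amine
    if (amine_nh_capacity(mol) < 1L) {
      out <- c(out, "no nitrogen bearing a substitutable hydrogen")
    }
  }
  out
}

#' Assemble a registry of building blocks
#'
#' @param blocks list of `building_block` objects.
#' @param provenance free-text provenance note.
#' @return An object of class `bb_registry` with fields `amines`,
#'   `epoxides`, `acyl_chlorides`, `provenance`.
#' @export
registry <- function(blocks = list(), provenance = "") {
  ids <- vapply(blocks, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate block id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  kinds <- vapply(blocks, `[[`, character(1), "kind")
  structure(list(amines = blocks[kinds == "amine"],
                 epoxides = blocks[kinds == "epoxide"],
                 acyl_chlorides = blocks[kinds == "acyl_chloride"],
                 provenance = provenance),
            class = "bb_registry")
}

registry_blocks <- function(reg) {
  c(reg$amines, reg$epoxides, reg$acyl_chlorides)
}

#' Look up a block by id
#'
#' @param reg a `bb_registry`.
#' @param id block identifier.
#' @return The matching `building_block`.
#' @export
get_block <- function(reg, id) {
  blocks <- registry_blocks(reg)
  ids <- vapply(blocks, `[[`, character(1), "id")
  hit <- which(ids == id)
  if (!length(hit)) stop("no building block with id '", id, "'", call. = FALSE)
  blocks[[hit]]
}

#' Load a building-block registry from a CSV/TSV file
#'
#' The file must have columns `id`, `kind`, `structure`, `carbon_count`
#' and may have `label` and `salt_form`. Every block is validated; any
#' violation is reported with the offending row.
#'
#' @param path file path; tab-separated if the extension is `.tsv`.
#' @param provenance provenance note attached to the registry.
#' @return A `bb_registry`.
#' @export
load_registry <- function(path, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  need <- c("id", "kind", "structure", "carbon_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("registry file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"label" %in% names(df)) df$label <- ""
  if (!"salt_form" %in% names(df)) df$salt_form <- FALSE
  blocks <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    blk <- try(building_block(df$id[i], df$kind[i], df$structure[i],
                              df$carbon_count[i], df$label[i],
                              df$salt_form[i]), silent = TRUE)
    if (inherits(blk, "try-error")) {
      stop(sprintf("row %d (id '%s'): %s", i, df$id[i],
                   trimws(attr(blk, "condition")$message)), call. = FALSE)
    }
    viol <- validate_block(blk)
    if (length(viol)) {
      stop(sprintf("row %d (id '%s'): %s", i, df$id[i],
                   paste(viol, collapse = "; ")), call. = FALSE)
    }
    blocks[[i]] <- blk
  }
  registry(blocks, provenance = provenance)
}

#' Write a registry to CSV/TSV, SMILES or SDF
#'
#' @param reg a `bb_registry`.
#' @param path output path; format chosen by extension (`.csv`, `.tsv`,
#'   `.smi`, `.sdf`).
#' @return `path`, invisibly.
#' @export
write_registry <- function(reg, path) {
  blocks <- registry_blocks(reg)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv")) {
    df <- as.data.frame(reg)
    utils::write.table(df, path, sep = if (ext == "tsv") "\t" else ",",
                       row.names = FALSE, quote = TRUE)
  } else if (ext == "smi") {
    lines <- vapply(blocks, function(b) paste(b$structure, b$id, sep = "\t"),
                    character(1))
    writeLines(lines, path)
  } else if (ext == "sdf") {
    con <- file(path, "w")
    on.exit(close(con))
    for (b in blocks) {
      mol <- mol_from_smiles(b$structure)
      writeLines(mol_molblock(mol, title = b$id), con)
      writeLines(c(">  <kind>", b$kind, "", ">  <carbon_count>",
                   as.character(b$carbon_count), "", "$$$$"), con)
    }
  } else {
    stop("unsupported registry format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' @export
as.data.frame.bb_registry <- function(x, ...) {
  blocks <- registry_blocks(x)
  data.frame(id = vapply(blocks, `[[`, character(1), "id"),
             kind = vapply(blocks, `[[`, character(1), "kind"),
             structure = vapply(blocks, `[[`, character(1), "structure"),
             carbon_count = vapply(blocks, `[[`, integer(1), "carbon_count"),
             label = vapply(blocks, `[[`, character(1), "label"),
             salt_form = vapply(blocks, `[[`, logical(1), "salt_form"),
             stringsAsFactors = FALSE)
}

#' @export
print.bb_registry <- function(x, ...) {
  cat("<bb_registry> ", length(x$amines), " amines, ",
      length(x$epoxides), " epoxides, ", length(x$acyl_chlorides),
      " acyl chlorides\n", sep = "")
  invisible(x)
}

#' The default DB-lipidoid building-block registry
#'
#' Returns the registry behind the two canonical DB-lipidoid screening
#' libraries: 20 amine headgroups, five linear alkyl epoxides (6 to 14
#' carbons, even) and five linear acyl chlorides (6 to 14 carbons, even,
#' counting the carbonyl carbon). Amine 1 is
#' 3-(dimethylamino)-1-propylamine and amine 11 is
#' 1-(2-aminoethyl)pyrrolidine. The remaining amines are curator-provided
#' synthetic stand-ins consistent with the published class structure
#' (monoamines, diamines with varied tertiary-amine form and spacer,
#' hydrazines, a polyamine, and di-secondary diamines), shipped in
#' `inst/extdata/amines_2_20_synthetic.csv`; each can attach exactly two
#' body tails.
#'
#' @param include_supplementary include the stand-in amines 2-20 (if
#'   `FALSE`, only amine 1 plus the tail blocks are returned).
#' @return A `bb_registry`.
#' @export
default_registry <- function(include_supplementary = TRUE) {
  core <- load_registry(system.file("extdata", "building_blocks.csv",
                                    package = "dblipidoid"),
                        provenance = "main-text building blocks")
  if (!include_supplementary) return(core)
  supp <- load_registry(system.file("extdata", "amines_2_20_synthetic.csv",
                                    package = "dblipidoid"),
                        provenance = "synthetic stand-in amines 2-20")
  registry(c(registry_blocks(core), registry_blocks(supp)),
           provenance = "default DB-lipidoid registry")
}
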