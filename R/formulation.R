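# Formulation arithmetic for lipid nanoparticle (LNP) recipes: weight
# ratios <-> mole percentages for the ionizable lipidoid, helper lipid,
# cholesterol and PEG-lipid components.

#' Reference molecular weights of common LNP components
#'
#' Average molecular weights (Da) of the helper components used in
#' DB-lipidoid LNP recipes: DOPE and DSPC phospholipids, cholesterol,
#' and DMG-PEG 2000 (nominal average including the PEG chain).
#'
#' @return Named numeric vector.
#' @export
lnp_component_mw <- function() {
  c(DOPE = 744.03, DSPC = 790.15, cholesterol = 386.65,
    `DMG-PEG2000` = 2509.2)
}

#' Convert component weights to mole percentages
#'
#' Percentages proportional to weight / molecular weight, normalized to
#' sum to 100.
#'
#' @param weights positive weights (any common unit).
#' @param molecular_weights matching molecular weights in Da.
#' @return Numeric vector of mole percentages summing to 100.
#' @export
weight_to_molar <- function(weights, molecular_weights) {
  if (length(weights) != length(molecular_weights)) {
    stop("weights and molecular_weights must have the same length",
         call. = FALSE)
  }
  if (any(weights <= 0) || any(molecular_weights <= 0)) {
    stop("weights and molecular weights must be positive", call. = FALSE)
  }
  moles <- weights / molecular_weights
  100 * moles / sum(moles)
}

#' Convert mole percentages to weight fractions
#'
#' Inverse of [weight_to_molar()]: weight fractions proportional to
#' mole-fraction x molecular weight, normalized to sum to 100.
#'
#' @param molar mole percentages.
#' @param molecular_weights matching molecular weights in Da.
#' @return Numeric vector of weight percentages summing to 100.
#' @export
molar_to_weight <- function(molar, molecular_weights) {
  if (length(molar) != length(molecular_weights)) {
    stop("molar and molecular_weights must have the same length",
         call. = FALSE)
  }
  w <- molar * molecular_weights
  100 * w / sum(w)
}

#' Define and validate an LNP formulation
#'
#' A formulation names its components with molecular weights and gives
#' either a weight ratio or a molar ratio (mole percentages). Molar
#' ratios must sum to 100 within 0.1.
#'
#' @param components named numeric vector of molecular weights (Da),
#'   ionizable lipidoid first by convention.
#' @param weight_ratio weights, same order (optional).
#' @param molar_ratio mole percentages, same order (optional).
#' @param lipidoid_to_rna_weight lipidoid:RNA weight ratio (optional).
#' @return List of class `formulation_spec` with both representations
#'   filled in.
#' @export
formulation_spec <- function(components, weight_ratio = NULL,
                             molar_ratio = NULL,
                             lipidoid_to_rna_weight = NA_real_) {
  if (is.null(weight_ratio) && is.null(molar_ratio)) {
    stop("provide weight_ratio or molar_ratio", call. = FALSE)
  }
  k <- length(components)
  if (!is.null(weight_ratio) && length(weight_ratio) != k ||
      !is.null(molar_ratio) && length(molar_ratio) != k) {
    stop("ratio length does not match the number of components",
         call. = FALSE)
  }
  if (!is.null(molar_ratio) && abs(sum(molar_ratio) - 100) > 0.1) {
    stop(sprintf("molar ratio sums to %.2f, not 100", sum(molar_ratio)),
         call. = FALSE)
  }
  if (is.null(molar_ratio)) {
    molar_ratio <- weight_to_molar(weight_ratio, components)
  }
  if (is.null(weight_ratio)) {
    weight_ratio <- molar_to_weight(molar_ratio, components)
  }
  structure(list(components = components, weight_ratio = weight_ratio,
                 molar_ratio = molar_ratio,
                 lipidoid_to_rna_weight = lipidoid_to_rna_weight),
            class = "formulation_spec")
}

#' @export
print.formulation_spec <- function(x, ...) {
  cat("<formulation_spec>\n")
  df <- data.frame(component = names(x$components), MW = x$components,
                   weight = round(x$weight_ratio, 2),
                   molar_pct = round(x$molar_ratio, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Canonical DB-lipidoid LNP formulations
#'
#' `screening_formulation()` is the pipette-mixing recipe used for
#' library screening: lipidoid/DOPE/cholesterol/DMG-PEG at a weight
#' ratio of 16:10:10:3 (with mRNA at 1.6 relative weight, i.e. a 10:1
#' lipidoid:mRNA weight ratio). `optimized_formulation()` is the
#' microfluidic lead recipe with a molar ratio of 40/10/48.5/1.5.
#' Two cholesterol percentages circulate for the optimized recipe (48.5
#' and 48.8); only 48.5 sums to 100 with the other components and is
#' used here.
#'
#' @param lipidoid_mw average molecular weight of the ionizable
#'   lipidoid in Da (default: the C42H82N2O4 lead).
#' @return A [formulation_spec()].
#' @export
screening_formulation <- function(lipidoid_mw = average_mass("C42H82N2O4")) {
  mw <- lnp_component_mw()
  formulation_spec(
    components = c(lipidoid = lipidoid_mw, DOPE = mw[["DOPE"]],
                   cholesterol = mw[["cholesterol"]],
                   `DMG-PEG2000` = mw[["DMG-PEG2000"]]),
    weight_ratio = c(16, 10, 10, 3),
    lipidoid_to_rna_weight = 16 / 1.6)
}

#' @rdname screening_formulation
#' @export
optimized_formulation <- function(lipidoid_mw = average_mass("C42H82N2O4")) {
  mw <- lnp_component_mw()
  formulation_spec(
    components = c(lipidoid = lipidoid_mw, DOPE = mw[["DOPE"]],
                   cholesterol = mw[["cholesterol"]],
                   `DMG-PEG2000` = mw[["DMG-PEG2000"]]),
    molar_ratio = c(40, 10, 48.5, 1.5),
    lipidoid_to_rna_weight = 10)
}
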