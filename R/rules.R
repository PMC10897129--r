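# Rule-based potency classifier and ranker for DB-lipidoids.
#
# The three validated structural criteria for a potent DB-lipidoid:
#   (1) total carbon number per tail pair TC = m + n equals 18;
#   (2) tail symmetry close to 1 (deviation d = |n/(m-2) - 1| <= d_max);
#   (3) an efficacious headgroup: a diamine with one primary amine and
#       one dimethylamino-, diethylamino- or pyrrolidinyl-type tertiary
#       amine spaced by two or three carbons, and no hydrazine.
# Candidates are also ordered by a continuous rank score in which any
# criterion violation outranks any compliant candidate.

#' Rule configuration
#'
#' @param d_max maximal admitted symmetry deviation (default 1.0: admits
#'   the near-symmetric tail pairs, d up to 1, and rejects strongly
#'   imbalanced ones such as d = 2).
#' @param penalty score added per unit |TC - 18| and for a failed
#'   headgroup; large enough that any violation outranks any compliant
#'   candidate.
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(d_max = 1.0, penalty = 100) {
  stopifnot(d_max > 0, penalty > 0)
  structure(list(d_max = d_max, penalty = penalty), class = "rule_config")
}

#' Evaluate the potency rules for one lipidoid
#'
#' @param descriptors one row of [describe_library()] output, or a list
#'   with at least `total_carbons`, `deviation` and
#'   `headgroup_efficacious` (`deviation` may be `NA` when the symmetry
#'   is undefined, m <= 2).
#' @param config a [rule_config()].
#' @return A list of class `rule_verdict`: booleans `c1_total18`,
#'   `c2_symmetry`, `c3_headgroup`, `predicted_potent`, the continuous
#'   `rank_score` (lower is better) and `notes` naming violated
#'   criteria.
#' @export
evaluate_rules <- function(descriptors, config = rule_config()) {
  tc <- descriptors$total_carbons
  d <- descriptors$deviation
  hg <- isTRUE(descriptors$headgroup_efficacious)
  c1 <- tc == 18L
  c2 <- !is.na(d) && d <= config$d_max
  notes <- character(0)
  if (!c1) notes <- c(notes, sprintf("total carbons %d != 18", tc))
  if (is.na(d)) {
    notes <- c(notes, "undefined symmetry")
  } else if (!c2) {
    notes <- c(notes, sprintf("symmetry deviation %.2f > %.2f", d,
                              config$d_max))
  }
  if (!hg) notes <- c(notes, "headgroup not efficacious")
  d_term <- if (is.na(d)) config$penalty else d
  score <- d_term + config$penalty * abs(tc - 18L) + config$penalty * !hg
  structure(list(c1_total18 = c1, c2_symmetry = c2, c3_headgroup = hg,
                 predicted_potent = c1 && c2 && hg,
                 rank_score = score, notes = notes),
            class = "rule_verdict")
}

#' Verdict table for a described library
#'
#' @param descriptors data.frame from [describe_library()].
#' @param config a [rule_config()].
#' @return The input with verdict columns appended: `c1_total18`,
#'   `c2_symmetry`, `c3_headgroup`, `predicted_potent`, `rank_score`.
#' @export
evaluate_library <- function(descriptors, config = rule_config()) {
  vs <- lapply(seq_len(nrow(descriptors)), function(i) {
    evaluate_rules(descriptors[i, ], config)
  })
  descriptors$c1_total18 <- vapply(vs, `[[`, logical(1), "c1_total18")
  descriptors$c2_symmetry <- vapply(vs, `[[`, logical(1), "c2_symmetry")
  descriptors$c3_headgroup <- vapply(vs, `[[`, logical(1), "c3_headgroup")
  descriptors$predicted_potent <- vapply(vs, `[[`, logical(1),
                                         "predicted_potent")
  descriptors$rank_score <- vapply(vs, `[[`, numeric(1), "rank_score")
  descriptors
}

#' Rank lipidoids by rule compliance
#'
#' Stable ascending sort on the rank score (compliant, symmetric
#' candidates first); ties are broken by name, lexicographically.
#'
#' @param verdicts data.frame from [evaluate_library()].
#' @return The same data.frame, reordered.
#' @export
rank_lipidoids <- function(verdicts) {
  verdicts[order(verdicts$rank_score, verdicts$name), , drop = FALSE]
}

#' Enumerate, describe and classify one or more library designs
#'
#' Runs the full candidate pipeline for a design (or a list of designs
#' whose candidates are pooled), deduplicates products by name, and
#' summarizes the screen: number of unique candidates, number predicted
#' potent, and the hit rate as a rounded percentage.
#'
#' @param reg a `bb_registry`.
#' @param designs a design list (`amines`/`epoxides`/`acyls`) or a list
#'   of such designs.
#' @param config a [rule_config()].
#' @return List of class `screen_result`: `table` (ranked verdict
#'   data.frame), `n_candidates`, `n_predicted_potent`, `hit_rate`
#'   (percentage, `NULL` when there are no candidates).
#' @export
screen_library <- function(reg, designs, config = rule_config()) {
  if (!is.null(designs$amines)) designs <- list(designs)
  libs <- lapply(designs, function(d) enumerate_library(reg, d,
                                                        structures = FALSE))
  all_lip <- do.call(c, lapply(libs, unclass))
  if (!length(all_lip)) {
    return(structure(list(table = NULL, n_candidates = 0L,
                          n_predicted_potent = 0L, hit_rate = NULL),
                     class = "screen_result"))
  }
  names_all <- vapply(all_lip, `[[`, character(1), "name")
  keep <- !duplicated(names_all)
  lib <- all_lip[keep]
  class(lib) <- c("lipidoid_library", "list")
  desc <- describe_library(lib, reg)
  verd <- rank_lipidoids(evaluate_library(desc, config))
  n_cand <- nrow(verd)
  n_hit <- sum(verd$predicted_potent)
  structure(list(table = verd, n_candidates = n_cand,
                 n_predicted_potent = n_hit,
                 hit_rate = round(100 * n_hit / n_cand)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> ", x$n_candidates, " candidates, ",
      x$n_predicted_potent, " predicted potent",
      if (!is.null(x$hit_rate)) sprintf(" (hit rate %d%%)", x$hit_rate),
      "\n", sep = "")
  if (!is.null(x$table)) {
    top <- utils::head(x$table[x$table$predicted_potent,
                               c("name", "total_carbons", "s_display",
                                 "rank_score")], 10)
    if (nrow(top)) print(top, row.names = FALSE)
  }
  invisible(x)
}
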