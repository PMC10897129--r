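# Structure-activity analysis of screening records: tail heat maps,
# marginal tail-activity profiles, total-carbon x symmetry contour
# statistics, in vitro / in vivo correlation and threshold-necessity
# analysis.

screen_channel <- function(records, channel = c("invivo", "invitro")) {
  channel <- match.arg(channel)
  if (channel == "invivo") records$invivo_flux else records$invitro_rlu
}

#' Heat map of median log10 readout over (m, n)
#'
#' @param records data.frame from [simulate_screen()] (or a real screen
#'   with the same columns).
#' @param descriptors descriptor table mapping `name` to `m` and `n`.
#' @param channel `"invivo"` (total flux) or `"invitro"` (RLU).
#' @return Matrix of median log10 readouts, rows = body-tail m,
#'   columns = branch-tail n (ascending); combinations never screened
#'   are `NA`.
#' @export
build_heatmap <- function(records, descriptors,
                          channel = c("invivo", "invitro")) {
  df <- merge(records, descriptors[, c("name", "m", "n")], by = "name")
  df$value <- log10(screen_channel(df, channel))
  ms <- sort(unique(df$m))
  ns <- sort(unique(df$n))
  out <- matrix(NA_real_, length(ms), length(ns),
                dimnames = list(m = ms, n = ns))
  counts <- matrix(0L, length(ms), length(ns),
                   dimnames = list(m = ms, n = ns))
  agg <- stats::aggregate(value ~ m + n, data = df, FUN = stats::median)
  cnt <- stats::aggregate(value ~ m + n, data = df, FUN = length)
  for (i in seq_len(nrow(agg))) {
    out[as.character(agg$m[i]), as.character(agg$n[i])] <- agg$value[i]
    counts[as.character(cnt$m[i]), as.character(cnt$n[i])] <- cnt$value[i]
  }
  attr(out, "counts") <- counts
  out
}

#' Marginal tail-activity profiles
#'
#' Median log10 readout by body-tail length m and by branch-tail
#' length n.
#'
#' @inheritParams build_heatmap
#' @return List with data.frames `by_m` and `by_n`.
#' @export
tail_profiles <- function(records, descriptors,
                          channel = c("invivo", "invitro")) {
  df <- merge(records, descriptors[, c("name", "m", "n")], by = "name")
  df$value <- log10(screen_channel(df, channel))
  list(by_m = stats::aggregate(value ~ m, data = df, FUN = stats::median),
       by_n = stats::aggregate(value ~ n, data = df, FUN = stats::median))
}

#' Binned medians over total carbons and symmetry deviation
#'
#' Contour-style summary: per (TC bin, d bin) count and median log10
#' flux, plus the argmax bin. The default d bins separate the
#' characteristic deviations 0, 0.4, 0.7 and 2 of the canonical tail
#' pairs.
#'
#' @param records screen records.
#' @param descriptors descriptor table with `total_carbons` and
#'   `deviation`.
#' @param tc_bins numeric breaks for total carbons.
#' @param d_bins numeric breaks for the symmetry deviation.
#' @return data.frame (class `contour_table`) with columns `tc_bin`,
#'   `d_bin`, `count`, `median_log10_flux`; the argmax bin is stored in
#'   `attr(, "argmax")`.
#' @export
contour_stats <- function(records, descriptors,
                          tc_bins = seq(10, 30, by = 2),
                          d_bins = c(0, 0.25, 0.5, 1, 2, Inf)) {
  df <- merge(records,
              descriptors[, c("name", "total_carbons", "deviation")],
              by = "name")
  df$value <- log10(df$invivo_flux)
  df$tc_bin <- cut(df$total_carbons, tc_bins, include.lowest = TRUE,
                   right = FALSE)
  df$d_bin <- cut(df$deviation, d_bins, include.lowest = TRUE, right = FALSE)
  agg <- stats::aggregate(value ~ tc_bin + d_bin, data = df,
                          FUN = stats::median, drop = TRUE)
  cnt <- stats::aggregate(value ~ tc_bin + d_bin, data = df, FUN = length,
                          drop = TRUE)
  out <- data.frame(tc_bin = as.character(agg$tc_bin),
                    d_bin = as.character(agg$d_bin),
                    count = cnt$value,
                    median_log10_flux = agg$value,
                    stringsAsFactors = FALSE)
  best <- which.max(out$median_log10_flux)
  attr(out, "argmax") <- out[best, , drop = FALSE]
  class(out) <- c("contour_table", "data.frame")
  out
}

#' Pearson correlation between the two screening channels
#'
#' Pearson r on log10-transformed in vitro and in vivo readouts, with
#' the two-tailed p-value from the t distribution on n - 2 degrees of
#' freedom (via [stats::cor.test()]).
#'
#' @param records screen records with both channels.
#' @return List with `r`, `p`, `n`.
#' @export
correlation_test <- function(records) {
  x <- log10(records$invitro_rlu)
  y <- log10(records$invivo_flux)
  if (length(x) < 3L) stop("need at least 3 paired readouts", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a channel", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Threshold-necessity analysis
#'
#' Fraction of in vivo hits whose in vitro readout reaches `threshold`
#' (necessity) and, conversely, the fraction of threshold-passing
#' records that are hits (sufficiency), with the 2x2 contingency
#' counts. A necessity fraction of 1 with a low sufficiency fraction
#' reproduces the necessary-but-not-sufficient structure of the
#' baseline transfection threshold.
#'
#' @param records screen records with `is_hit`.
#' @param threshold RLU threshold (default 10^4).
#' @return List with `fraction_hits_above` (`NULL` when there are no
#'   hits), `fraction_above_are_hits`, and `counts` (2x2 table).
#' @export
threshold_necessity <- function(records, threshold = 1e4) {
  above <- records$invitro_rlu >= threshold
  hit <- records$is_hit
  counts <- table(above = factor(above, c(FALSE, TRUE)),
                  hit = factor(hit, c(FALSE, TRUE)))
  frac_necess <- if (!sum(hit)) NULL else sum(above & hit) / sum(hit)
  frac_suffic <- if (!sum(above)) NULL else sum(above & hit) / sum(above)
  list(fraction_hits_above = frac_necess,
       fraction_above_are_hits = frac_suffic,
       counts = counts)
}

#' Full SAR report
#'
#' Bundles the heat maps (both channels), marginal profiles, contour
#' table, correlation test and threshold-necessity analysis for one
#' screen.
#'
#' @inheritParams contour_stats
#' @param threshold RLU threshold for the necessity analysis.
#' @return List of class `sar_report`.
#' @export
sar_report <- function(records, descriptors,
                       tc_bins = seq(10, 30, by = 2),
                       d_bins = c(0, 0.25, 0.5, 1, 2, Inf),
                       threshold = 1e4) {
  structure(list(
    heatmap_invivo = build_heatmap(records, descriptors, "invivo"),
    heatmap_invitro = build_heatmap(records, descriptors, "invitro"),
    profiles = tail_profiles(records, descriptors, "invivo"),
    contour = contour_stats(records, descriptors, tc_bins, d_bins),
    correlation = correlation_test(records),
    necessity = threshold_necessity(records, threshold)),
    class = "sar_report")
}

#' @export
print.sar_report <- function(x, ...) {
  cat("<sar_report>\n")
  cat("  correlation: r =", round(x$correlation$r, 3),
      "p =", signif(x$correlation$p, 3), "n =", x$correlation$n, "\n")
  am <- attr(x$contour, "argmax")
  cat("  contour argmax: TC", am$tc_bin, ", d", am$d_bin,
      sprintf("(median log10 flux %.2f)\n", am$median_log10_flux))
  fh <- x$necessity$fraction_hits_above
  cat("  necessity fraction:", if (is.null(fh)) "no hits" else round(fh, 3),
      "\n")
  invisible(x)
}
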