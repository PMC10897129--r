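# Synthetic two-channel screening readouts.
#
# Emulates the statistical structure of a DB-lipidoid screen without
# cell or animal data: log-normal in vitro luciferase expression (RLU)
# and in vivo hepatic bioluminescence (total flux, photons/s), with
#   - an in vivo background below 10^7 p/s for inefficacious molecules,
#   - a structure-dependent boost of one to three orders of magnitude
#     for rule-compliant lipidoids,
#   - graded loss of potency with symmetry deviation and departure from
#     18 total tail carbons,
#   - no built-in in vitro / in vivo correlation, and
#   - the necessity property: every in vivo hit clears a baseline
#     in vitro transfection threshold (10,000 RLU).

#' Parameters of the synthetic screen generator
#'
#' @param log10_bg_flux in vivo background, log10 photons/s (default
#'   6.7, i.e. below 10^7 p/s).
#' @param boost_range orders of magnitude gained by a rule-compliant
#'   lipidoid, drawn uniformly per lipidoid (default `c(1, 3)`).
#' @param deviation_slope log10-flux lost per unit symmetry deviation d.
#' @param carbon_penalty log10-flux lost per unit |TC - 18|.
#' @param invitro_threshold baseline transfection threshold in RLU
#'   (default 10^4); every hit is guaranteed to exceed it.
#' @param invitro_log10_bg baseline log10 RLU of an aminoalcohol-stage
#'   lipidoid.
#' @param invitro_branch_boost log10 RLU gained by carrying two branch
#'   tails (branch attachment boosts transfection in both channels).
#' @param invitro_noise_sd,invivo_noise_sd log10-scale Gaussian noise.
#' @param rho latent coupling between the two channels' noise (default
#'   0: no correlation).
#' @param mc3_margin log10 margin above background defining the MC3
#'   benchmark reference level for hit calling (default 2.5).
#' @param seed integer seed.
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(log10_bg_flux = 6.7, boost_range = c(1, 3),
                          deviation_slope = 0.8, carbon_penalty = 0.5,
                          invitro_threshold = 1e4, invitro_log10_bg = 2.5,
                          invitro_branch_boost = 1.8,
                          invitro_noise_sd = 0.5, invivo_noise_sd = 0.3,
                          rho = 0, mc3_margin = 2.5, seed = 1L) {
  stopifnot(boost_range[1] <= boost_range[2],
            invitro_noise_sd >= 0, invivo_noise_sd >= 0, abs(rho) <= 1)
  structure(list(log10_bg_flux = log10_bg_flux, boost_range = boost_range,
                 deviation_slope = deviation_slope,
                 carbon_penalty = carbon_penalty,
                 invitro_threshold = invitro_threshold,
                 invitro_log10_bg = invitro_log10_bg,
                 invitro_branch_boost = invitro_branch_boost,
                 invitro_noise_sd = invitro_noise_sd,
                 invivo_noise_sd = invivo_noise_sd, rho = rho,
                 mc3_margin = mc3_margin, seed = as.integer(seed)),
            class = "screen_params")
}

#' Simulate a two-channel lipidoid screen
#'
#' Generates one `ScreenRecord` per candidate from its rule verdict:
#' log10 in vivo flux is background plus a uniform compliance boost,
#' minus graded symmetry-deviation and total-carbon penalties, plus
#' log-normal noise; log10 in vitro RLU is an independent latent
#' (optionally coupled through `rho`) raised by branch attachment. Hits
#' are records at or above the MC3 reference level; their in vitro
#' latent is rejection-resampled until it clears the transfection
#' threshold, which realizes the observed necessary-but-not-sufficient
#' threshold structure. Fully reproducible for a given seed.
#'
#' @param verdicts data.frame from [evaluate_library()] (needs columns
#'   `name`, `deviation`, `total_carbons`, `predicted_potent`; a `stage`
#'   column is used for the branch boost when present).
#' @param params a [screen_params()].
#' @return data.frame with columns `name`, `invitro_rlu`, `invivo_flux`,
#'   `is_hit`.
#' @export
simulate_screen <- function(verdicts, params = screen_params()) {
  n <- nrow(verdicts)
  if (is.null(n) || n == 0L) {
    return(data.frame(name = character(0), invitro_rlu = numeric(0),
                      invivo_flux = numeric(0), is_hit = logical(0)))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(params$seed)
  two_branch <- if ("stage" %in% names(verdicts)) {
    verdicts$stage == "two_branch"
  } else {
    rep(TRUE, n)
  }
  boost <- stats::runif(n, params$boost_range[1], params$boost_range[2])
  z_vivo <- stats::rnorm(n)
  e_vitro <- stats::rnorm(n)
  z_vitro <- params$rho * z_vivo + sqrt(1 - params$rho^2) * e_vitro
  d <- ifelse(is.na(verdicts$deviation), 2, verdicts$deviation)
  log_flux <- params$log10_bg_flux +
    boost * as.numeric(verdicts$predicted_potent) -
    params$deviation_slope * pmin(d, 2) -
    params$carbon_penalty * abs(verdicts$total_carbons - 18) +
    params$invivo_noise_sd * z_vivo
  log_flux <- pmax(log_flux, 0)
  ref <- params$log10_bg_flux + params$mc3_margin
  is_hit <- log_flux >= ref
  mu_vitro <- params$invitro_log10_bg +
    params$invitro_branch_boost * as.numeric(two_branch)
  log_rlu <- mu_vitro + params$invitro_noise_sd * z_vitro
  thr <- log10(params$invitro_threshold)
  for (i in which(is_hit)) {
    tries <- 0L
    while (log_rlu[i] < thr) {
      log_rlu[i] <- mu_vitro[i] + params$invitro_noise_sd * stats::rnorm(1)
      tries <- tries + 1L
      if (tries > 10000L) {
        stop("rejection resampling failed to clear the in vitro threshold",
             call. = FALSE)
      }
    }
  }
  data.frame(name = verdicts$name, invitro_rlu = 10^log_rlu,
             invivo_flux = 10^log_flux, is_hit = is_hit,
             stringsAsFactors = FALSE)
}

#' Recover generator slopes from simulated records
#'
#' Least-squares fit of log10 in vivo flux on compliance, symmetry
#' deviation and |TC - 18|, returning point estimates of the
#' deviation slope and carbon penalty (as losses, sign-matched to
#' [screen_params()]) with percentile bootstrap confidence intervals.
#'
#' @param records data.frame from [simulate_screen()].
#' @param descriptors matching descriptor table (by `name`).
#' @param n_boot bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed seed for the bootstrap.
#' @return List with `deviation_slope`, `carbon_penalty` (each a list
#'   `estimate`, `ci`), and `fit` (the `lm` object).
#' @export
recover_parameters <- function(records, descriptors, n_boot = 1000L,
                               level = 0.95, seed = 1L) {
  df <- merge(records, descriptors, by = "name")
  if (nrow(df) < 20L) stop("need >= 20 records spanning d and TC",
                           call. = FALSE)
  df$y <- log10(df$invivo_flux)
  df$compliant <- as.numeric(df$predicted_potent)
  df$tc_dev <- abs(df$total_carbons - 18)
  df$d <- pmin(ifelse(is.na(df$deviation), 2, df$deviation), 2)
  X <- stats::model.matrix(~ compliant + d + tc_dev, data = df)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design: records do not span d and TC", call. = FALSE)
  }
  fit <- stats::lm(y ~ compliant + d + tc_dev, data = df)
  est <- -stats::coef(fit)[c("d", "tc_dev")]
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(df), replace = TRUE)
    cf <- try(stats::lm.fit(X[idx, , drop = FALSE], df$y[idx])$coefficients,
              silent = TRUE)
    if (!inherits(cf, "try-error")) boots[b, ] <- -cf[c("d", "tc_dev")]
  }
  alpha <- (1 - level) / 2
  ci <- apply(boots, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  list(deviation_slope = list(estimate = unname(est["d"]),
                              ci = unname(ci[, 1])),
       carbon_penalty = list(estimate = unname(est["tc_dev"]),
                             ci = unname(ci[, 2])),
       fit = fit)
}
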