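# Competition-EMSA analysis: percent inhibition, exact ternary mass-action
# competitive-binding fit for relative Kd, and normalization to the
# highest-affinity reference. All concentrations are molar.

#' Percent inhibition of the shifted band
#'
#' `100 * (F0 - Fc) / F0`, where `F0` is the shifted-band fluorescence with no
#' competitor and `Fc` the fluorescence at a given competitor concentration.
#' Scale-invariant: multiplying both by any positive constant leaves the
#' result unchanged.
#'
#' @param F0 No-competitor fluorescence (> 0).
#' @param Fc Fluorescence at the competitor concentration(s) (>= 0),
#'   vectorized.
#' @return Percent inhibition (can exceed 0-100 for noisy data).
#' @export
percent_inhibition <- function(F0, Fc) {
  if (!is.finite(F0) || F0 <= 0) stop("F0 must be > 0", call. = FALSE)
  if (any(!is.finite(Fc)) || any(Fc < 0))
    stop("Fc must be finite and >= 0", call. = FALSE)
  100 * (F0 - Fc) / F0
}

#' Competition-EMSA titration series
#'
#' @param competitor_concs Strictly increasing competitor concentrations
#'   (molar, >= 0; do not include the no-competitor point).
#' @param shifted_fluorescence Shifted-band fluorescence at each competitor
#'   concentration.
#' @param F0 Shifted-band fluorescence with no competitor (> 0).
#' @param probe_conc Labeled probe concentration (molar).
#' @param protein_conc Active protein (dimer) concentration (molar).
#' @return Object of class `competition_series`.
#' @export
competition_series <- function(competitor_concs, shifted_fluorescence, F0,
                               probe_conc, protein_conc) {
  if (length(competitor_concs) != length(shifted_fluorescence))
    stop("competitor_concs and shifted_fluorescence lengths differ",
         call. = FALSE)
  if (any(competitor_concs < 0) || is.unsorted(competitor_concs,
                                               strictly = TRUE))
    stop("competitor concentrations must be >= 0 and strictly increasing",
         call. = FALSE)
  if (!is.finite(F0) || F0 <= 0) stop("F0 must be > 0", call. = FALSE)
  if (any(shifted_fluorescence < 0))
    stop("shifted fluorescence must be >= 0", call. = FALSE)
  if (probe_conc <= 0 || protein_conc <= 0)
    stop("probe and protein concentrations must be > 0", call. = FALSE)
  structure(list(competitor_concs = as.numeric(competitor_concs),
                 shifted_fluorescence = as.numeric(shifted_fluorescence),
                 F0 = F0, probe_conc = probe_conc,
                 protein_conc = protein_conc),
            class = "competition_series")
}

# Free-protein concentration under ternary mass action:
#   Rt = Rf * (1 + Pt/(Kp + Rf) + Ct/(Kc + Rf)),
# solved per competitor concentration by vectorized bisection on (0, Rt).
solve_free_protein <- function(Rt, Pt, Ct, Kp, Kc, iters = 60L) {
  lo <- rep(0, length(Ct))
  hi <- rep(Rt, length(Ct))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    f <- mid * (1 + Pt / (Kp + mid) + Ct / (Kc + mid)) - Rt
    below <- f < 0
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

# Bound labeled probe at each competitor concentration.
predict_bound <- function(kd_competitor, series, kd_probe, Ct = NULL) {
  Ct <- Ct %||% series$competitor_concs
  Rf <- solve_free_protein(series$protein_conc, series$probe_conc, Ct,
                           kd_probe, kd_competitor)
  series$probe_conc * Rf / (kd_probe + Rf)
}

# Model-predicted percent inhibition (0 at zero competitor by construction).
predict_inhibition <- function(kd_competitor, series, kd_probe) {
  bound0 <- predict_bound(kd_competitor, series, kd_probe, Ct = 0)
  bound <- predict_bound(kd_competitor, series, kd_probe)
  100 * (1 - bound / bound0)
}

#' Fit a competitor Kd from a competition-EMSA series
#'
#' Least-squares fit of the exact competitive mass-action equilibrium model
#' (free protein solved numerically per competitor concentration) to the
#' observed percent-inhibition curve, over log10(Kd). The 95% confidence
#' interval is normal-theory on log(Kd) -- Kd estimates are positive with a
#' near-lognormal sampling distribution -- with the standard error taken from
#' residual-resampling bootstrap refits.
#'
#' @param series A [competition_series()].
#' @param kd_probe Known Kd of the labeled probe (molar, > 0).
#' @param n_boot Bootstrap resamples for the CI (default 200).
#' @param rng_seed Integer seed for the bootstrap.
#' @param kd_range log10 search interval for Kd in molar units
#'   (default 1e-12 to 1e-2 M).
#' @return Object of class `kd_estimate`: `kd`, `ci_low`, `ci_high`,
#'   `relative_kd` (NA until [relative_kd()]), `fitted`, `residuals`.
#' @export
fit_competition_kd <- function(series, kd_probe, n_boot = 200L,
                               rng_seed = NULL, kd_range = c(-12, -2)) {
  stopifnot(inherits(series, "competition_series"))
  if (kd_probe <= 0) stop("kd_probe must be > 0", call. = FALSE)
  if (length(series$competitor_concs) < 4L)
    stop("need >= 4 competitor concentrations spanning the transition",
         call. = FALSE)
  obs <- percent_inhibition(series$F0, series$shifted_fluorescence)
  if (max(obs) - min(obs) < 5)
    stop("no transition observed: percent inhibition spans only ",
         sprintf("%.1f", max(obs) - min(obs)), " points", call. = FALSE)

  fit_one <- function(y) {
    sse <- function(lk) sum((y - predict_inhibition(10^lk, series, kd_probe))^2)
    stats::optimize(sse, kd_range, tol = 1e-5)$minimum
  }
  lk <- fit_one(obs)
  if (lk <= kd_range[1L] + 0.01 || lk >= kd_range[2L] - 0.01)
    stop("fit did not converge: Kd estimate pinned at the search boundary (",
         sprintf("1e%.1f M", lk), "); check concentrations and kd_probe",
         call. = FALSE)
  fitted <- predict_inhibition(10^lk, series, kd_probe)
  res <- obs - fitted

  boot <- numeric(0)
  if (n_boot > 0L) {
    boot <- with_rng(rng_seed, vapply(seq_len(n_boot), function(i) {
      yb <- fitted + sample(res, length(res), replace = TRUE)
      10^fit_one(yb)
    }, 0))
  }
  kd <- 10^lk
  ci <- if (length(boot)) {
    se <- stats::sd(log(boot))
    exp(log(kd) + c(-1.96, 1.96) * se)
  } else c(kd, kd)
  structure(list(kd = kd, ci_low = min(ci[1L], kd), ci_high = max(ci[2L], kd),
                 relative_kd = NA_real_, fitted = fitted, residuals = res),
            class = "kd_estimate")
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat(sprintf("<kd_estimate> Kd = %.3g M [%.3g, %.3g]%s\n",
              x$kd, x$ci_low, x$ci_high,
              if (is.na(x$relative_kd)) ""
              else sprintf("  relative Kd = %.2f", x$relative_kd)))
  invisible(x)
}

#' Relative Kd, normalized to the highest-affinity sequence
#'
#' Divides every Kd by the smallest Kd in the set, so the reference
#' (highest-affinity) entry is exactly 1.0 and order is preserved.
#'
#' @param estimates List of [fit_competition_kd()] results, or a numeric
#'   vector of Kd values.
#' @return Same shape as the input with `relative_kd` filled in (list input)
#'   or the numeric relative values (numeric input).
#' @export
relative_kd <- function(estimates) {
  if (is.numeric(estimates)) {
    if (!length(estimates)) stop("need >= 1 estimate", call. = FALSE)
    return(estimates / min(estimates))
  }
  kds <- vapply(estimates, function(e) e$kd, 0)
  if (!length(kds)) stop("need >= 1 estimate", call. = FALSE)
  ref <- min(kds)
  lapply(estimates, function(e) { e$relative_kd <- e$kd / ref; e })
}

#' Simulate a competition-EMSA titration
#'
#' Generates shifted-band fluorescence from the same mass-action model the
#' fitter uses, with optional multiplicative lognormal noise; the default
#' concentration ladder matches a standard 0.2 nM - 2 uM competition series.
#'
#' @param kd_competitor,kd_probe Dissociation constants (molar).
#' @param probe_conc,protein_conc Assay concentrations (molar; defaults 2 nM
#'   probe, 4 nM dimer).
#' @param competitor_concs Competitor ladder (molar).
#' @param F0 No-competitor shifted-band fluorescence (arbitrary units).
#' @param sigma Lognormal noise sd on fluorescence (0 = noise-free).
#' @param rng_seed Integer seed.
#' @return A [competition_series()].
#' @export
simulate_competition <- function(kd_competitor, kd_probe,
                                 probe_conc = 2e-9, protein_conc = 4e-9,
                                 competitor_concs = c(0.2, 0.63, 2, 6.3, 20,
                                                      63, 200, 630, 2000) * 1e-9,
                                 F0 = 1000, sigma = 0, rng_seed = NULL) {
  skeleton <- competition_series(competitor_concs,
                                 rep(1, length(competitor_concs)),
                                 F0, probe_conc, protein_conc)
  bound0 <- predict_bound(kd_competitor, skeleton, kd_probe, Ct = 0)
  bound <- predict_bound(kd_competitor, skeleton, kd_probe)
  fc <- F0 * bound / bound0
  if (sigma > 0)
    fc <- with_rng(rng_seed,
                   fc * stats::rlnorm(length(fc), 0, sigma))
  competition_series(competitor_concs, fc, F0, probe_conc, protein_conc)
}
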