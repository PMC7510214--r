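#' Simulation and analysis configuration
#'
#' Bundles every tunable parameter of the synthetic melt-curve / MLPA
#' generator and of the downstream analysis (derivative filter, peak windows,
#' referral rules, copy-number banding) into one validated list. All
#' temperatures are degrees Celsius, DNA amounts are nanograms per reaction,
#' and fluorescence is expressed in units of `amplitude_total`.
#'
#' The three melting transitions sit at the assay's design temperatures:
#' SMN1 at 63, SMN2 at 56 and the DNA-quantity (Q) fragment at 49. The Q
#' fragment competes with genomic template through a Michaelis-type term
#' `D / (D + q_competition_k)`, so its peak dominates only at very low input
#' DNA; `q_competition_k = 0.7` ng places that crossover near 10% of the
#' nominal saturated-punch yield of 10 ng. Blood quenching of the Cy5 signal
#' is `exp(-quench_coefficient * max(0, blood_load - 1))`.
#'
#' @param tm_smn1_c,tm_smn2_c,tm_q_c Melting temperatures of the three
#'   transitions. Must satisfy `tm_q_c < tm_smn2_c < tm_smn1_c`.
#' @param transition_width_c Logistic width of each melt transition.
#' @param amplitude_total Total probe-bound fluorescence amplitude at
#'   saturating input DNA; the unit of all fluorescence values.
#' @param baseline_fluorescence Constant fluorescence offset.
#' @param q_competition_k Half-saturation constant (ng) of the Q-fragment
#'   competition term.
#' @param quench_coefficient Exponential rate of signal quenching per unit of
#'   blood over-saturation.
#' @param curve_noise_sd Additive Gaussian noise sd on each fluorescence
#'   reading, as a fraction of `amplitude_total`.
#' @param temp_min_c,temp_max_c,temp_step_c Acquisition temperature grid.
#' @param dna_meanlog,dna_sdlog Lognormal parameters of the per-punch DNA
#'   yield (ng) for specimens.
#' @param blood_load_min,blood_load_max Uniform range of relative spot
#'   saturation for specimens (1 = saturated).
#' @param control_dna_ng Fixed input DNA for the synthetic SD074/SD075
#'   control reactions.
#' @param smoothing_window_c Support of the Savitzky-Golay derivative filter.
#' @param sg_order Polynomial order of the Savitzky-Golay filter.
#' @param windows Named list `SMN1`, `SMN2`, `Q` of `c(lo, hi)` temperature
#'   windows for peak calling. The SMN1 window is asymmetric (tight lower
#'   edge) so that variant-shifted SMN1 transitions fall out of the window
#'   and fail safe towards referral.
#' @param presence_factor Multiple of the noise floor a windowed maximum must
#'   exceed to be called present.
#' @param rel_presence_frac Fraction of the tallest windowed peak a maximum
#'   must additionally exceed to be called present; rejects cross-window
#'   leakage of logistic tails, which scales with signal rather than noise.
#' @param max_retest_rounds Retest rounds before a stubborn well escalates,
#'   fail-safe, to second-tier referral.
#' @param mlpa_cv Multiplicative coefficient of variation of MLPA probe
#'   heights.
#' @param mlpa_scale_sdlog Lognormal sd of the per-sample MLPA scale factor.
#' @param mlpa_probe_sdlog Lognormal sd of the fixed per-probe efficiencies.
#' @param mlpa_band_halfwidth Half-width, on the normalized-ratio scale, of
#'   the acceptance band around each copy-number value; combined ratios
#'   outside every band are flagged ambiguous.
#'
#' @return An object of class `smn_config`: a named list of parameters.
#' @examples
#' cfg <- sim_config()
#' cfg$tm_smn1_c
#' noiseless <- sim_config(curve_noise_sd = 0)
#' @export
sim_config <- function(tm_smn1_c = 63,
                       tm_smn2_c = 56,
                       tm_q_c = 49,
                       transition_width_c = 1.2,
                       amplitude_total = 1,
                       baseline_fluorescence = 0.1,
                       q_competition_k = 0.7,
                       quench_coefficient = 0.7,
                       curve_noise_sd = 0.005,
                       temp_min_c = 45,
                       temp_max_c = 75,
                       temp_step_c = 0.2,
                       dna_meanlog = log(10),
                       dna_sdlog = 0.3,
                       blood_load_min = 0.85,
                       blood_load_max = 1.05,
                       control_dna_ng = 10,
                       smoothing_window_c = 4.4,
                       sg_order = 5,
                       windows = list(SMN1 = c(61, 65),
                                      SMN2 = c(54, 58),
                                      Q = c(47, 51)),
                       presence_factor = 5,
                       rel_presence_frac = 0.12,
                       max_retest_rounds = 2,
                       mlpa_cv = 0.05,
                       mlpa_scale_sdlog = 0.15,
                       mlpa_probe_sdlog = 0.2,
                       mlpa_band_halfwidth = 0.2) {
  cfg <- list(
    tm_smn1_c = tm_smn1_c, tm_smn2_c = tm_smn2_c, tm_q_c = tm_q_c,
    transition_width_c = transition_width_c,
    amplitude_total = amplitude_total,
    baseline_fluorescence = baseline_fluorescence,
    q_competition_k = q_competition_k,
    quench_coefficient = quench_coefficient,
    curve_noise_sd = curve_noise_sd,
    temp_min_c = temp_min_c, temp_max_c = temp_max_c,
    temp_step_c = temp_step_c,
    dna_meanlog = dna_meanlog, dna_sdlog = dna_sdlog,
    blood_load_min = blood_load_min, blood_load_max = blood_load_max,
    control_dna_ng = control_dna_ng,
    smoothing_window_c = smoothing_window_c, sg_order = sg_order,
    windows = windows,
    presence_factor = presence_factor,
    rel_presence_frac = rel_presence_frac,
    max_retest_rounds = max_retest_rounds,
    mlpa_cv = mlpa_cv,
    mlpa_scale_sdlog = mlpa_scale_sdlog,
    mlpa_probe_sdlog = mlpa_probe_sdlog,
    mlpa_band_halfwidth = mlpa_band_halfwidth
  )
  validate_config(cfg)
  structure(cfg, class = "smn_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$tm_q_c < cfg$tm_smn2_c, cfg$tm_smn2_c < cfg$tm_smn1_c,
    cfg$transition_width_c > 0,
    cfg$amplitude_total > 0,
    cfg$q_competition_k > 0,
    cfg$quench_coefficient > 0,
    cfg$curve_noise_sd >= 0,
    cfg$temp_step_c > 0, cfg$temp_step_c <= 0.5,
    cfg$temp_min_c <= 45, cfg$temp_max_c >= 72,
    cfg$presence_factor > 0,
    cfg$rel_presence_frac >= 0,
    cfg$max_retest_rounds >= 1,
    cfg$mlpa_cv >= 0,
    cfg$mlpa_band_halfwidth > 0, cfg$mlpa_band_halfwidth <= 0.25
  )
  w <- cfg$windows
  stopifnot(setequal(names(w), c("SMN1", "SMN2", "Q")))
  edges <- do.call(rbind, w[order(vapply(w, `[`, 1, 1))])
  if (any(edges[-1, 1] < edges[-nrow(edges), 2]))
    abort("peak windows must be disjoint")
  invisible(cfg)
}

#' @export
print.smn_config <- function(x, ...) {
  cat("<smn_config>\n")
  cat(sprintf("  transitions: SMN1 %.1f C, SMN2 %.1f C, Q %.1f C (width %.2f C)\n",
              x$tm_smn1_c, x$tm_smn2_c, x$tm_q_c, x$transition_width_c))
  cat(sprintf("  grid: %.1f-%.1f C by %.2f C; noise sd %.3f x amplitude\n",
              x$temp_min_c, x$temp_max_c, x$temp_step_c, x$curve_noise_sd))
  cat(sprintf("  derivative: SG order %d over %.1f C; presence > max(%g x floor, %g x tallest)\n",
              x$sg_order, x$smoothing_window_c, x$presence_factor,
              x$rel_presence_frac))
  cat(sprintf("  MLPA: cv %.3f, band half-width %.2f\n",
              x$mlpa_cv, x$mlpa_band_halfwidth))
  invisible(x)
}

temperature_grid <- function(cfg) {
  seq(cfg$temp_min_c, cfg$temp_max_c, by = cfg$temp_step_c)
}

# Deterministic sub-seed derivation so that every stage of a run draws from
# its own stream; a plain string hash keeps seeds below 2^31.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483587) + 1L
}
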