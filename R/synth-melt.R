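# Melt-curve generative model.
#
# Asymmetric PCR drives probe-bound product to a plateau, so noiseless
# curves encode only the SMN1:SMN2 copy RATIO, never absolute copy number:
# the genomic amplitude amp * D/(D+k) is split between SMN1 and SMN2 in
# proportion to their copies, and the competing Q oligonucleotide takes the
# complementary amp * k/(D+k). Each bound species melts as a logistic
# transition, so -dF/dT is a logistic density with peak height A/(4w).

melt_amplitudes <- function(smn1, smn2, input_dna_ng, config) {
  d <- input_dna_ng
  genomic <- config$amplitude_total * d / (d + config$q_competition_k)
  total_copies <- smn1 + smn2
  frac1 <- ifelse(d > 0 & total_copies > 0, smn1 / pmax(total_copies, 1), 0)
  frac2 <- ifelse(d > 0 & total_copies > 0, smn2 / pmax(total_copies, 1), 0)
  tibble::tibble(
    a_smn1 = ifelse(d > 0, genomic * frac1, 0),
    a_smn2 = ifelse(d > 0, genomic * frac2, 0),
    a_q = config$amplitude_total * config$q_competition_k /
      (d + config$q_competition_k)
  )
}

quench_factor <- function(blood_load, config) {
  exp(-config$quench_coefficient * pmax(0, blood_load - 1))
}

melt_model <- function(temps, a_smn1, a_smn2, a_q, tm_shift_c, quench,
                       config) {
  w <- config$transition_width_c
  f <- config$baseline_fluorescence +
    a_smn1 * plogis((config$tm_smn1_c + tm_shift_c - temps) / w) +
    a_smn2 * plogis((config$tm_smn2_c - temps) / w) +
    a_q * plogis((config$tm_q_c - temps) / w)
  quench * f
}

#' Simulate melt curves for a set of wells
#'
#' Generates one fluorescence-versus-temperature curve per sample row. The
#' model is a sum of up to three logistic melt transitions (SMN1, SMN2,
#' Q-fragment) whose amplitudes follow the copy-ratio contract of the
#' asymmetric-PCR assay, scaled by a blood-quenching factor and overlaid
#' with additive Gaussian reading noise.
#'
#' Sequence variants under the probe are modelled by `tm_shift_c <= 0`,
#' which lowers the SMN1 transition temperature (a probe mismatch always
#' destabilizes the duplex).
#'
#' @param samples Tibble of sample specifications ([generate_cohort()] or
#'   [build_plates()] rows).
#' @param config An [sim_config()] object.
#' @param seed Integer seed for the reading noise.
#'
#' @return A long tibble: `sample_id`, `temperature_c`, `fluorescence`.
#' @examples
#' curves <- simulate_melt_curves(generate_cohort(seed = 1)[1:2, ], seed = 1)
#' dplyr::count(curves, sample_id)
#' @export
simulate_melt_curves <- function(samples, config = sim_config(), seed = 1L) {
  stopifnot(all(c("sample_id", "smn1_copies", "smn2_copies",
                  "input_dna_ng", "blood_load") %in% names(samples)))
  if (any(samples$input_dna_ng < 0)) abort("input_dna_ng must be >= 0")
  if (any(samples$blood_load < 0)) abort("blood_load must be >= 0")
  tm_shift <- if ("tm_shift_c" %in% names(samples)) samples$tm_shift_c else
    rep(0, nrow(samples))
  if (any(tm_shift > 0))
    abort("tm_shift_c must be <= 0: probe-region variants only lower the melting temperature")
  with_dna <- samples$input_dna_ng > 0
  check_genotypes(samples$smn1_copies[with_dna], samples$smn2_copies[with_dna])
  if ("role" %in% names(samples) &&
      any(samples$role == "BLANK" & samples$input_dna_ng != 0))
    abort("BLANK wells must have input_dna_ng = 0")

  temps <- temperature_grid(config)
  amp <- melt_amplitudes(samples$smn1_copies, samples$smn2_copies,
                         samples$input_dna_ng, config)
  q <- quench_factor(samples$blood_load, config)
  withr::with_seed(derive_seed(seed, "melt"), {
    purrr::pmap_dfr(
      list(samples$sample_id, amp$a_smn1, amp$a_smn2, amp$a_q, tm_shift, q),
      function(id, a1, a2, aq, shift, qf) {
        f <- melt_model(temps, a1, a2, aq, shift, qf, config)
        if (config$curve_noise_sd > 0)
          f <- f + rnorm(length(temps),
                         sd = config$curve_noise_sd * config$amplitude_total)
        tibble::tibble(sample_id = id, temperature_c = temps,
                       fluorescence = f)
      })
  })
}
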